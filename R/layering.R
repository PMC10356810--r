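# Exclude-and-retest layering: remove already-explained mutation
# categories from both null and observed, renormalise, and test again.

#' Exclude a mutation category from null and observed
#'
#' Removes every catalogue entry matching the predicate from the null
#' model (renormalising the remaining probabilities to one) and every
#' observed mutation on those entries, appending an exclusion label to
#' the catalogue's provenance. This is the core of the exclude-and-retest
#' procedure: once a selected category is established, excluding it from
#' both sides lets weaker selection underneath be tested on the
#' remainder.
#'
#' @param catalogue an [SnvCatalogue-class].
#' @param observed an [ObservedMutationSet-class] mapped onto it.
#' @param predicate expression string over feature columns (comparisons
#'   and Boolean operators only), e.g. `"ddg > 2"` or
#'   `"destabilising | interface"`. `NA` feature values never match.
#' @param label exclusion label recorded in provenance (defaults to the
#'   predicate text).
#' @return list with elements `catalogue` and `observed`.
#' @examples
#' tx <- simulateTranscript(60, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, ddg = simulateDdg(cat, seed = 4))
#' obs <- simulateMutations(cat, selectionScenario(
#'   list(list(feature = "ddg > 2", factor = 3)), 100), seed = 2)
#' out <- excludeEntries(cat, obs, "ddg > 2")
#' exclusionLabels(out$catalogue)
#' @export
excludeEntries <- function(catalogue, observed, predicate,
                           label = predicate) {
  e <- catalogue@entries
  hit <- evalPredicate(predicate, e) & e$included
  if (!any(hit)) {
    catalogue@exclusions <- c(catalogue@exclusions, as.character(label))
    return(list(catalogue = catalogue, observed = observed))
  }
  inc <- e$included & !hit
  tot <- sum(e$prob[inc])
  if (!any(inc) || tot <= 0)
    stop(sprintf("exclusion '%s' empties the null model", label),
         call. = FALSE)
  e$included <- inc
  e$prob <- ifelse(inc, e$prob / tot, 0)
  catalogue@entries <- e
  catalogue@exclusions <- c(catalogue@exclusions, as.character(label))

  keep <- inc[observed@entryIndex]
  if (!any(keep))
    stop(sprintf("exclusion '%s' empties the observed set", label),
         call. = FALSE)
  observed <- new("ObservedMutationSet", regionId = observed@regionId,
                  entryIndex = observed@entryIndex[keep],
                  count = observed@count[keep])
  validObject(catalogue)
  list(catalogue = catalogue, observed = observed)
}

#' Layered exclude-and-retest analysis
#'
#' Runs an ordered sequence of selection tests, excluding each layer's
#' mutation category from both null and observed before testing the
#' next. Strong selection of one category can mask weaker selection of
#' another in the same region; testing the weaker feature only among the
#' mutations not explained by earlier layers restores power. Entries
#' matching several layers are excluded at the first matching layer.
#'
#' Each layer is a list with elements:
#' \describe{
#'   \item{name}{label (defaults to the feature).}
#'   \item{feature}{feature/score column to test.}
#'   \item{test}{`"binomial"` or `"monte_carlo"`.}
#'   \item{exclude_if}{predicate excluded after testing; default is the
#'     feature itself for Boolean features, nothing for numeric scores.}
#' }
#'
#' @param catalogue an [SnvCatalogue-class] with features attached.
#' @param observed an [ObservedMutationSet-class].
#' @param layers ordered list of layer specifications (see Details), or
#'   the path handed to [readLayerSpec()].
#' @param nDraws,seed Monte Carlo settings for `monte_carlo` layers.
#' @param alpha significance level used only in the residual report.
#' @return list with `results` (list of [SelectionTestResult-class], one
#'   per completed layer), `residual` (list: `n` remaining observed
#'   mutations, `fractionExplained`, `catalogue`, `observed`) and
#'   `status` (`"complete"` or the degenerate-layer message when the
#'   analysis halted early with partial results).
#' @examples
#' tx <- simulateTranscript(100, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat,
#'   residueSets = list(strong = residueSet("s", 1:20),
#'                      weak = residueSet("w", 21:40)))
#' obs <- simulateMutations(cat, fig1Scenario(300), seed = 5)
#' la <- layeredAnalysis(cat, obs, list(
#'   list(feature = "strong", test = "binomial"),
#'   list(feature = "weak", test = "binomial")))
#' la$results[[2]]
#' @export
layeredAnalysis <- function(catalogue, observed, layers,
                            nDraws = 100000L, seed = 1L, alpha = 0.05) {
  if (is.character(layers) && length(layers) == 1L)
    layers <- readLayerSpec(layers)
  n0 <- totalMutations(observed)
  results <- list()
  status <- "complete"
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (is.null(ly$feature))
      stop(sprintf("layer %d has no feature", i), call. = FALSE)
    test <- if (is.null(ly$test)) "binomial" else ly$test
    nm <- if (is.null(ly$name)) ly$feature else ly$name
    res <- tryCatch({
      if (test == "binomial")
        binomialFeatureTest(observed, catalogue, ly$feature)
      else if (test == "monte_carlo")
        monteCarloTest(observed, catalogue, ly$feature, nDraws = nDraws,
                       seed = deriveSeed(seed, paste0("layer", i)))
      else stop(sprintf("unknown test type '%s'", test), call. = FALSE)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      status <- sprintf("halted at layer %d (%s): %s", i, nm,
                        conditionMessage(res))
      break
    }
    res@feature <- nm
    results[[nm]] <- res

    exclIf <- ly$exclude_if
    if (is.null(exclIf)) {
      e <- catalogue@entries
      exclIf <- if (is.logical(e[[ly$feature]])) ly$feature else NA
    }
    if (!is.na(exclIf) && i < length(layers)) {
      step <- tryCatch(excludeEntries(catalogue, observed, exclIf,
                                      label = nm),
                       error = function(err) err)
      if (inherits(step, "error")) {
        status <- sprintf("halted after layer %d (%s): %s", i, nm,
                          conditionMessage(step))
        break
      }
      catalogue <- step$catalogue
      observed <- step$observed
    } else if (!is.na(exclIf)) {
      # final layer: still record the exclusion for the residual report
      step <- tryCatch(excludeEntries(catalogue, observed, exclIf,
                                      label = nm),
                       error = function(err) NULL)
      if (!is.null(step)) {
        catalogue <- step$catalogue
        observed <- step$observed
      } else {
        observed <- new("ObservedMutationSet",
                        regionId = observed@regionId,
                        entryIndex = integer(), count = numeric())
      }
    }
  }
  nRes <- totalMutations(observed)
  list(results = results,
       residual = list(n = nRes,
                       fractionExplained = if (n0 > 0) 1 - nRes / n0 else NA,
                       catalogue = catalogue, observed = observed),
       status = status)
}

#' Read a layer specification from YAML
#'
#' The YAML file holds an ordered list of layers, each with keys
#' `feature`, `test` (`binomial` or `monte_carlo`), optional `name` and
#' optional `exclude_if` (a predicate expression over feature columns).
#'
#' @param path YAML file path.
#' @return list of layer specifications for [layeredAnalysis()].
#' @export
readLayerSpec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$layers)) spec <- spec$layers
  if (!is.list(spec) || !length(spec))
    stop(sprintf("no layers found in '%s'", path), call. = FALSE)
  for (i in seq_along(spec)) {
    if (is.null(spec[[i]]$feature))
      stop(sprintf("layer %d in '%s' has no 'feature'", i, path),
           call. = FALSE)
  }
  spec
}
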