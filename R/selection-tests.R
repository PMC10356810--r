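# Statistical comparison of observed mutations against the neutral null:
# exact two-tailed binomial test for Boolean features, two-tailed Monte
# Carlo test for continuous scores, and the CDF-shift statistic.

# exact two-sided binomial p by the minimum-likelihood method: sum of the
# probabilities of all outcomes no more likely than the one observed
# (relative tolerance guards against floating-point ties)
binomTwoTailedP <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

# drop entries with NA in the feature column from both null and observed,
# renormalising the null; returns list(prob, featureValues, obsIdx, obsCnt)
restrictToScored <- function(catalogue, observed, feature) {
  e <- catalogue@entries
  if (!feature %in% names(e))
    stop(sprintf("feature column '%s' not found in catalogue", feature),
         call. = FALSE)
  scored <- e$included & !is.na(e[[feature]])
  nDropNull <- sum(e$included) - sum(scored)
  idx <- observed@entryIndex
  cnt <- observed@count
  keep <- scored[idx]
  if (any(!keep))
    message(sprintf(
      "dropped %g observed mutation(s) unscored for '%s' from the test",
      sum(cnt[!keep]), feature))
  if (nDropNull > 0L)
    message(sprintf("dropped %d unscored null entr%s for '%s'",
                    nDropNull, if (nDropNull == 1L) "y" else "ies", feature))
  prob <- e$prob
  prob[!scored] <- 0
  tot <- sum(prob)
  if (tot <= 0)
    stop(sprintf("no scored null mass left for feature '%s'", feature),
         call. = FALSE)
  list(prob = prob / tot, scored = scored,
       obsIdx = idx[keep], obsCnt = cnt[keep],
       values = e[[feature]])
}

#' Exact binomial test for a Boolean feature
#'
#' Tests whether observed mutations carry a Boolean feature more or less
#' often than the neutral null expects. The null proportion is the summed
#' null probability of feature-positive entries; the observed count is
#' the recurrence-weighted number of feature-positive mutations; the
#' two-tailed p-value uses the minimum-likelihood convention (sum of all
#' outcome probabilities no greater than that of the observed count).
#' Unscored (`NA`) entries are removed from both null and observed.
#'
#' @param observed an [ObservedMutationSet-class].
#' @param catalogue the matching [SnvCatalogue-class] with the feature
#'   column attached.
#' @param feature name of a logical feature column.
#' @param level confidence level of the expected-count interval.
#' @return A [SelectionTestResult-class] with `expected` the null
#'   proportion and `observed` the observed proportion.
#' @examples
#' tx <- simulateTranscript(60, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, residueSets = list(site = residueSet("s", 1:12)))
#' obs <- simulateMutations(cat, selectionScenario(
#'   list(list(feature = "site", factor = 3)), 100), seed = 2)
#' binomialFeatureTest(obs, cat, "site")
#' @export
binomialFeatureTest <- function(observed, catalogue, feature, level = 0.95) {
  r <- restrictToScored(catalogue, observed, feature)
  if (!is.logical(r$values))
    stop(sprintf("feature '%s' is not Boolean; use monteCarloTest()", feature),
         call. = FALSE)
  n <- sum(r$obsCnt)
  if (n < 1)
    stop("no observed mutations to test", call. = FALSE)
  p0 <- sum(r$prob[r$values %in% TRUE])
  if (p0 <= 0 || p0 >= 1)
    stop(sprintf("degenerate feature '%s': null proportion is %g",
                 feature, p0), call. = FALSE)
  k <- sum(r$obsCnt[r$values[r$obsIdx] %in% TRUE])
  # recurrence weights are integral clone counts; the binomial needs them so
  n <- as.integer(round(n)); k <- as.integer(round(k))
  p <- binomTwoTailedP(k, n, p0)
  ci <- expectedCountCI(n, p0, level)
  new("SelectionTestResult",
      feature = feature, test = "binomial",
      n = as.numeric(n), expected = p0, observed = k / n,
      p = max(p, .Machine$double.xmin),
      ciLow = ci[1L], ciHigh = ci[2L],
      exclusions = catalogue@exclusions,
      details = list(k = k, p0 = p0,
                     status = if (n < 5) "underpowered" else "ok"))
}

#' Equal-tailed interval for the expected feature count
#'
#' Central (equal-tailed) interval of the Binomial(n, p0) distribution of
#' the feature count expected under the null, used as the error bar on
#' expected counts.
#'
#' @param n number of observed mutations.
#' @param p0 null feature proportion.
#' @param level confidence level (default 0.95).
#' @return integer vector `c(low, high)`.
#' @examples
#' expectedCountCI(100, 0.5)
#' @export
expectedCountCI <- function(n, p0, level = 0.95) {
  stopifnot(p0 >= 0, p0 <= 1, n >= 0)
  a <- (1 - level) / 2
  c(qbinom(a, n, p0), qbinom(1 - a, n, p0))
}

weightedQuantile <- function(x, w, q = 0.5) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= q - 1e-12)[1L]]
}

#' Two-tailed Monte Carlo test for a continuous score
#'
#' Compares a summary statistic (median, or mean of mid-CDF values) of
#' the observed score distribution against its sampling distribution
#' under the neutral null. Null samples of the observed size are drawn
#' with replacement with probabilities equal to the null probabilities;
#' recurrent mutations count as independent draws. The two-tailed p-value
#' is twice the smaller tail proportion with a +1 pseudo-count in
#' numerator and denominator (so p is never 0; the floor is
#' `2/(nDraws+1)`), capped at 1.
#'
#' @param observed an [ObservedMutationSet-class].
#' @param catalogue the matching [SnvCatalogue-class] with the score
#'   column attached.
#' @param feature name of a numeric score column (e.g. `"ddg"`,
#'   `"dist_target"`).
#' @param statistic `"median"` (default, reported in score units) or
#'   `"mean_cdf"` (mean of mid-CDF values; robust to extreme outliers).
#' @param nDraws number of Monte Carlo samples (default 100000).
#' @param seed integer seed; mandatory, recorded in the result.
#' @param level confidence level for the null-statistic interval.
#' @return A [SelectionTestResult-class]; `expected` is the null
#'   statistic (probability-weighted median, or 0.5 for `mean_cdf`),
#'   `observed` the observed statistic.
#' @examples
#' tx <- simulateTranscript(60, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, ddg = simulateDdg(cat, seed = 4))
#' obs <- simulateMutations(cat, selectionScenario(
#'   list(list(feature = "ddg > 2", factor = 3)), 100), seed = 2)
#' monteCarloTest(obs, cat, "ddg", nDraws = 2000, seed = 9)
#' @export
monteCarloTest <- function(observed, catalogue, feature,
                           statistic = c("median", "mean_cdf"),
                           nDraws = 100000L, seed, level = 0.95) {
  statistic <- match.arg(statistic)
  if (missing(seed))
    stop("a seed is required for the Monte Carlo test", call. = FALSE)
  r <- restrictToScored(catalogue, observed, feature)
  if (!is.numeric(r$values))
    stop(sprintf("feature '%s' is not numeric; use binomialFeatureTest()",
                 feature), call. = FALSE)
  n <- as.integer(round(sum(r$obsCnt)))
  if (n < 1)
    stop("no observed mutations to test", call. = FALSE)

  scoredIdx <- which(r$prob > 0)
  vals <- r$values[scoredIdx]
  prob <- r$prob[scoredIdx]
  obsScores <- rep(r$values[r$obsIdx], times = r$obsCnt)

  if (statistic == "mean_cdf") {
    Fv <- midCdf(vals, vals, prob)
    statFun <- function(m) colMeans(m)
    drawPool <- Fv
    obsStat <- mean(midCdf(obsScores, vals, prob))
    nullStat <- 0.5
  } else {
    statFun <- function(m) apply(m, 2L, median)
    drawPool <- vals
    obsStat <- median(obsScores)
    nullStat <- weightedQuantile(vals, prob, 0.5)
  }

  if (length(unique(vals)) == 1L) {
    warning(sprintf("constant score column '%s'; p = 1", feature),
            call. = FALSE)
    return(new("SelectionTestResult",
               feature = feature, test = "monte_carlo", n = as.numeric(n),
               expected = nullStat, observed = obsStat, p = 1,
               ciLow = nullStat, ciHigh = nullStat,
               exclusions = catalogue@exclusions,
               details = list(seed = seed, nDraws = as.integer(nDraws),
                              statistic = statistic, status = "degenerate")))
  }

  set.seed(seed)
  nDraws <- as.integer(nDraws)
  stats <- numeric(nDraws)
  chunk <- max(1L, min(nDraws, as.integer(2e6) %/% n))
  done <- 0L
  while (done < nDraws) {
    m <- min(chunk, nDraws - done)
    draw <- sample.int(length(drawPool), n * m, replace = TRUE, prob = prob)
    stats[done + seq_len(m)] <-
      statFun(matrix(drawPool[draw], nrow = n, ncol = m))
    done <- done + m
  }

  pHi <- (sum(stats >= obsStat) + 1) / (nDraws + 1)
  pLo <- (sum(stats <= obsStat) + 1) / (nDraws + 1)
  p <- min(1, 2 * min(pHi, pLo))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(stats, c(a, 1 - a), type = 1))
  new("SelectionTestResult",
      feature = feature, test = "monte_carlo", n = as.numeric(n),
      expected = nullStat, observed = obsStat, p = p,
      ciLow = ci[1L], ciHigh = ci[2L],
      exclusions = catalogue@exclusions,
      details = list(seed = seed, nDraws = nDraws, statistic = statistic,
                     pFloor = 2 / (nDraws + 1),
                     status = if (n < 5) "underpowered" else "ok"))
}

# mid-distribution CDF of query points x under the discrete null with
# support `support` and probabilities `prob`: F(x) = P(X < x) + P(X = x)/2.
# Guarantees E_null[F(X)] = 0.5 exactly for any discrete distribution.
midCdf <- function(x, support, prob) {
  o <- order(support)
  s <- support[o]
  p <- prob[o] / sum(prob)
  us <- unique(s)
  pu <- as.numeric(rowsum(p, match(s, us)))
  below <- c(0, cumsum(pu))[seq_along(us)]
  i <- findInterval(x, us)            # last support value <= x
  eq <- match(x, us, nomatch = 0L)
  Fx <- ifelse(i == 0L, 0, c(0, cumsum(pu))[i + 1L])
  hasEq <- eq > 0L
  Fx[hasEq] <- below[eq[hasEq]] + pu[eq[hasEq]] / 2
  Fx
}

#' Mid-distribution CDF transform of a score column
#'
#' Maps scores to their mid-distribution CDF values under the
#' probability-weighted null: `F(x) = P(X < x) + P(X = x)/2`. The mean of
#' `F` under the null is exactly 0.5, which anchors the CDF-shift
#' statistic; the transform damps the influence of extreme score
#' outliers.
#'
#' @param x query score value(s).
#' @param catalogue an [SnvCatalogue-class] with the score column.
#' @param feature numeric score column name (default `"ddg"`).
#' @return numeric vector of values in \[0, 1\].
#' @examples
#' tx <- simulateTranscript(30, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, ddg = simulateDdg(cat, seed = 4))
#' e <- catalogueEntries(cat)
#' f <- cdfTransform(e$ddg[e$included], cat)
#' abs(sum(f * e$prob[e$included]) - 0.5) < 1e-12
#' @export
cdfTransform <- function(x, catalogue, feature = "ddg") {
  e <- catalogue@entries
  scored <- e$included & !is.na(e[[feature]])
  if (!any(scored))
    stop(sprintf("no scored entries for feature '%s'", feature),
         call. = FALSE)
  midCdf(x, e[[feature]][scored], e$prob[scored])
}

#' CDF shift of observed scores against the null
#'
#' The difference between the mean of the observed and of the null
#' distributions of mid-CDF score values. Because the null mean of the
#' mid-CDF is exactly 0.5, the shift is the recurrence-weighted mean of
#' the observed entries' CDF values minus 0.5. It lies in \[-0.5, 0.5\]:
#' 0 when the observed distribution matches the null, approaching 0.5
#' (or -0.5) when all observed mutations sit at the maximum (minimum)
#' possible score as that entry's null mass vanishes.
#'
#' @param observed an [ObservedMutationSet-class], or `NULL` when
#'   `weights` is given.
#' @param catalogue an [SnvCatalogue-class] with the score column.
#' @param feature numeric score column (default `"ddg"`).
#' @param weights optional non-negative weight per catalogue entry,
#'   overriding `observed` (e.g. the null probabilities themselves, which
#'   give shift 0 exactly).
#' @param geneId label stored on the result.
#' @return A [CdfShiftResult-class].
#' @examples
#' tx <- simulateTranscript(30, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, ddg = simulateDdg(cat, seed = 4))
#' shiftValue(cdfShift(NULL, cat, weights = nullProbabilities(cat)))  # 0
#' @export
cdfShift <- function(observed, catalogue, feature = "ddg", weights = NULL,
                     geneId = regionId(catalogue)) {
  e <- catalogue@entries
  scored <- e$included & !is.na(e[[feature]])
  if (!any(scored))
    stop(sprintf("no scored entries for feature '%s'", feature),
         call. = FALSE)
  if (is.null(weights)) {
    if (is.null(observed))
      stop("either observed or weights must be supplied", call. = FALSE)
    w <- numeric(nrow(e))
    w[observed@entryIndex] <- observed@count
  } else {
    w <- rep_len(as.numeric(weights), nrow(e))
    if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  }
  w[!scored] <- 0
  tot <- sum(w)
  if (tot <= 0)
    stop("no scored observed mass", call. = FALSE)
  Fv <- midCdf(e[[feature]][scored], e[[feature]][scored], e$prob[scored])
  shift <- sum(w[scored] * Fv) / tot - 0.5
  new("CdfShiftResult", geneId = as.character(geneId),
      shift = shift, perStructure = shift, n = tot)
}

#' Average per-structure CDF shifts into one gene-level shift
#'
#' For genes with several solved structures the shift is computed per
#' structure and the unweighted mean reported.
#'
#' @param shifts list of [CdfShiftResult-class] objects (one per
#'   structure).
#' @param geneId label for the aggregated result (defaults to the first
#'   shift's gene).
#' @return A [CdfShiftResult-class].
#' @examples
#' a <- new("CdfShiftResult", geneId = "G", shift = 0.2,
#'          perStructure = 0.2, n = 10)
#' b <- new("CdfShiftResult", geneId = "G", shift = 0.4,
#'          perStructure = 0.4, n = 12)
#' shiftValue(aggregateGeneShift(list(a, b)))  # 0.3
#' @export
aggregateGeneShift <- function(shifts, geneId = NULL) {
  if (length(shifts) == 0L)
    stop("no per-structure shifts supplied", call. = FALSE)
  per <- vapply(shifts, shiftValue, numeric(1))
  if (is.null(geneId)) geneId <- shifts[[1L]]@geneId
  new("CdfShiftResult", geneId = as.character(geneId),
      shift = mean(per), perStructure = per,
      n = sum(vapply(shifts, function(s) s@n, numeric(1))))
}

#' Correlate gene CDF shifts with truncating dN/dS
#'
#' Pearson correlation of the mean CDF shift against the logarithm of the
#' truncating dN/dS ratio across genes, with a two-tailed p-value from
#' the t-distribution. Genes with non-positive dN/dS are excluded with a
#' warning (the logarithm is undefined).
#'
#' @param shifts data.frame with columns `gene` and `shift` (or a list of
#'   [CdfShiftResult-class] objects).
#' @param dnds data.frame with columns `gene` and `dnds`.
#' @return list with `r`, `p`, `n`.
#' @export
correlateShiftDnds <- function(shifts, dnds) {
  if (is.list(shifts) && !is.data.frame(shifts) &&
      all(vapply(shifts, is, logical(1), "CdfShiftResult")))
    shifts <- data.frame(
      gene = vapply(shifts, function(s) s@geneId, character(1)),
      shift = vapply(shifts, shiftValue, numeric(1)))
  stopifnot(all(c("gene", "shift") %in% names(shifts)),
            all(c("gene", "dnds") %in% names(dnds)))
  m <- merge(shifts, dnds, by = "gene")
  bad <- !is.finite(m$dnds) | m$dnds <= 0
  if (any(bad)) {
    warning(sprintf("%d gene(s) with non-positive dN/dS excluded",
                    sum(bad)), call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 3L)
    stop("need at least 3 genes with both a shift and a positive dN/dS",
         call. = FALSE)
  ct <- cor.test(m$shift, log(m$dnds), method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
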