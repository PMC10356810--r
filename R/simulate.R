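# Synthetic-data generators: transcripts, mutation sets with planted
# selection layers, ddG tables and toy structures. All generators are
# pure functions of (parameters, seed) and write/read the same formats
# as the real-data path, so synthetic and real inputs are
# interchangeable.

#' Simulate a coding transcript
#'
#' Random CDS starting with ATG, free of internal stop codons, with one
#' random flanking base at each end. Base composition is controlled by a
#' GC bias.
#'
#' @param nCodons number of codons (>= 1).
#' @param gcBias probability mass on G+C (default 0.5).
#' @param seed integer seed.
#' @param geneId,transcriptId identifiers.
#' @return A [Transcript-class].
#' @examples
#' tx <- simulateTranscript(100, seed = 7)
#' transcriptLength(tx)  # 300
#' @export
simulateTranscript <- function(nCodons, gcBias = 0.5, seed,
                               geneId = "SYNG1", transcriptId = "SYNT1") {
  stopifnot(nCodons >= 1, gcBias > 0, gcBias < 1)
  set.seed(seed)
  p <- c(A = (1 - gcBias) / 2, C = gcBias / 2, G = gcBias / 2,
         T = (1 - gcBias) / 2)
  stops <- c("TAA", "TAG", "TGA")
  drawCodon <- function(n) {
    paste0(sample(DNA_BASES_, n, TRUE, p), sample(DNA_BASES_, n, TRUE, p),
           sample(DNA_BASES_, n, TRUE, p))
  }
  codons <- if (nCodons > 1L) drawCodon(nCodons - 1L) else character()
  while (any(codons %in% stops))
    codons[codons %in% stops] <- drawCodon(sum(codons %in% stops))
  transcript(geneId, transcriptId,
             paste0("ATG", paste(codons, collapse = "")),
             upstream = sample(DNA_BASES_, 1L, prob = p),
             downstream = sample(DNA_BASES_, 1L, prob = p))
}

#' Simulate observed mutations with planted selection
#'
#' Draws mutations from a catalogue with probability proportional to the
#' null probability times the product of the enrichment factors of every
#' scenario layer whose predicate the entry matches (factor 1 = neutral,
#' 0 = fully negatively selected). Draws are aggregated into recurrence
#' counts per entry, mimicking independent mutant clones.
#'
#' @param catalogue an [SnvCatalogue-class] with the features referenced
#'   by the scenario attached.
#' @param scenario a [SelectionScenario-class].
#' @param seed integer seed.
#' @return An [ObservedMutationSet-class].
#' @examples
#' tx <- simulateTranscript(60, seed = 1)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' cat <- attachFeatures(cat, residueSets = list(site = residueSet("s", 1:12)))
#' obs <- simulateMutations(cat, selectionScenario(
#'   list(list(feature = "site", factor = 3)), 200), seed = 2)
#' totalMutations(obs)
#' @export
simulateMutations <- function(catalogue, scenario, seed) {
  e <- catalogue@entries
  w <- e$prob
  for (ly in scenario@layers) {
    hit <- evalPredicate(ly$feature, e)
    w[hit & e$included] <- w[hit & e$included] * ly$factor
  }
  w[!e$included] <- 0
  if (sum(w) <= 0)
    stop("all sampling weights are zero under this scenario", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(nrow(e), size = scenario@nMutations, replace = TRUE,
                    prob = w)
  tab <- table(idx)
  new("ObservedMutationSet", regionId = catalogue@regionId,
      entryIndex = as.integer(names(tab)), count = as.numeric(tab))
}

#' Two-feature masking scenario
#'
#' The canonical masking configuration: a strongly selected category
#' (enrichment factor 3) and a weakly selected one (factor 2) on
#' disjoint partitions of the region (each holding roughly 20% of the
#' null mass when used with [partitionFeatures()]), remainder neutral.
#' Testing the weak feature without excluding the strong one leaves the
#' observed weak proportion close to the null expectation; excluding the
#' strong category first unmasks the weak selection.
#'
#' @param nMutations number of observed mutations to draw (default 300).
#' @param strongFactor,weakFactor enrichment factors (defaults 3 and 2).
#' @return A [SelectionScenario-class] with layers on features `strong`
#'   and `weak`.
#' @seealso [partitionFeatures()] to attach the matching feature columns.
#' @export
fig1Scenario <- function(nMutations = 300, strongFactor = 3,
                         weakFactor = 2) {
  selectionScenario(
    list(list(feature = "strong", factor = strongFactor),
         list(feature = "weak", factor = weakFactor)),
    nMutations = nMutations)
}

#' Attach disjoint partition features to a catalogue
#'
#' Adds Boolean feature columns splitting the region's residues into
#' disjoint blocks by fraction of residues — by default `strong` on the
#' first 20% and `weak` on the next 20% — for use with masking
#' scenarios.
#'
#' @param catalogue an [SnvCatalogue-class].
#' @param fractions named numeric vector of residue fractions, in order
#'   (remainder is unlabelled/neutral).
#' @return the catalogue with one Boolean column per name.
#' @export
partitionFeatures <- function(catalogue,
                              fractions = c(strong = 0.2, weak = 0.2)) {
  stopifnot(!is.null(names(fractions)), all(fractions >= 0),
            sum(fractions) <= 1)
  e <- catalogue@entries
  res <- sort(unique(e$residue))
  bounds <- c(0, cumsum(fractions))
  for (i in seq_along(fractions)) {
    lo <- floor(bounds[i] * length(res)) + 1L
    hi <- floor(bounds[i + 1L] * length(res))
    block <- if (lo <= hi) res[lo:hi] else integer()
    e[[names(fractions)[i]]] <- e$residue %in% block
  }
  catalogue@entries <- e
  catalogue
}

#' Simulate a ddG table for a catalogue
#'
#' Draws a folding free-energy change for every missense amino-acid
#' substitution in the catalogue from a two-component Gaussian mixture: a
#' near-zero mode (tolerated mutations) and a destabilising tail.
#' Substitutions at designated core residues draw from the tail with
#' higher probability, emulating buried positions. Values are defined at
#' amino-acid level and copied onto every nucleotide-level entry by
#' [attachFeatures()].
#'
#' @param catalogue an [SnvCatalogue-class].
#' @param seed integer seed.
#' @param tailWeight mixture weight of the destabilising tail.
#' @param nearZeroMean,nearZeroSd near-zero component (kcal/mol).
#' @param tailMean,tailSd destabilising component (kcal/mol).
#' @param coreResidues residues biased toward the tail.
#' @param coreTailWeight tail weight at core residues.
#' @param chain chain recorded on the table.
#' @return A [DdgTable-class].
#' @export
simulateDdg <- function(catalogue, seed, tailWeight = 0.25,
                        nearZeroMean = 0.3, nearZeroSd = 0.8,
                        tailMean = 4, tailSd = 1.5,
                        coreResidues = NULL, coreTailWeight = 0.8,
                        chain = "A") {
  e <- catalogue@entries
  mis <- e[e$consequence == "missense",
           c("residue", "aa_ref", "aa_alt")]
  mis <- mis[!duplicated(paste(mis$residue, mis$aa_ref, mis$aa_alt)), ,
             drop = FALSE]
  set.seed(seed)
  wTail <- ifelse(mis$residue %in% coreResidues, coreTailWeight, tailWeight)
  tail <- stats::runif(nrow(mis)) < wTail
  ddg <- ifelse(tail,
                stats::rnorm(nrow(mis), tailMean, tailSd),
                stats::rnorm(nrow(mis), nearZeroMean, nearZeroSd))
  new("DdgTable",
      table = data.frame(chain = chain, residue = mis$residue,
                         aa_ref = mis$aa_ref, aa_alt = mis$aa_alt,
                         ddg = ddg, stringsAsFactors = FALSE),
      sourceStructure = "synthetic")
}

#' Simulate a toy structure with a pseudo-ligand target
#'
#' Builds an idealised alpha-helical C-alpha trace (2.3 Å radius, 1.5 Å
#' rise and 100 degrees of turn per residue) on chain A, randomly
#' oriented, plus a single-atom pseudo-ligand (chain L) placed at a
#' known distance from residue 1 along the outward radial direction, so
#' the minimum-distance ground truth at residue 1 is analytic.
#'
#' @param nResidues number of residues (>= 2).
#' @param seed integer seed (controls the rigid-body orientation).
#' @param targetDistance distance (Å) from residue 1's atom to the
#'   target atom.
#' @return A [StructureModel-class].
#' @examples
#' s <- simulateStructure(5, seed = 1, targetDistance = 5)
#' minDistanceToTarget(s, 1)  # 5
#' @export
simulateStructure <- function(nResidues, seed, targetDistance = 5) {
  stopifnot(nResidues >= 2)
  set.seed(seed)
  i <- seq_len(nResidues) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  # target: radially outward from residue 1, which is therefore nearest
  tgt <- xyz[1L, ] + c(2.3 * cos(theta[1L]), 2.3 * sin(theta[1L]), 0) /
    2.3 * targetDistance
  # random rigid-body rotation + translation (distances unaffected)
  ang <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  shift <- stats::rnorm(3, 0, 10)
  all <- rbind(xyz, tgt) %*% t(Rz %*% Rx)
  all <- sweep(all, 2L, -shift)
  atoms <- data.frame(
    chain = c(rep("A", nResidues), "L"),
    resno = c(seq_len(nResidues), 1L),
    resid = c(rep("ALA", nResidues), "LIG"),
    elety = c(rep("CA", nResidues), "C1"),
    x = all[, 1L], y = all[, 2L], z = all[, 3L],
    isTarget = c(rep(FALSE, nResidues), TRUE),
    stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms, targetSelection = "chain L")
}
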