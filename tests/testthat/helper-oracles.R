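# Shared fixtures and independent oracles, built in code.

# sliding-window oracle for trinucleotide contexts
slidingContexts <- function(tx) {
  full <- paste0(tx@upstream, cdsSequence(tx), tx@downstream)
  vapply(seq_len(transcriptLength(tx)),
         function(i) substr(full, i, i + 2L), character(1))
}

# brute-force consequence oracle: mutate the full CDS, translate the whole
# protein with Biostrings, and classify by comparing protein sequences
bruteForceConsequence <- function(cds, pos, alt) {
  mut <- cds
  substr(mut, pos, pos) <- alt
  aaRef <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                              no.init.codon = TRUE))
  aaMut <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                              no.init.codon = TRUE))
  codon <- (pos - 1L) %/% 3L + 1L
  r <- substr(aaRef, codon, codon)
  m <- substr(aaMut, codon, codon)
  if (r == m) "synonymous"
  else if (m == "*") "nonsense"
  else if (r == "*") "stop-loss"
  else "missense"
}

# build a bare catalogue directly from scores and null probabilities
# (bypasses transcripts; used for closed-form CDF-shift checks)
toyCatalogue <- function(scores, probs = NULL, regionId = "toy") {
  k <- length(scores)
  if (is.null(probs)) probs <- rep(1 / k, k)
  probs <- probs / sum(probs)
  e <- data.frame(
    cds_pos = seq_len(3L * k)[seq_len(k)] * 3L - 2L,
    ref = "A", alt = "C",
    ctx5 = "A", ctx3 = "A",
    codon_index = seq_len(k), residue = seq_len(k),
    aa_ref = "K", aa_alt = "Q", consequence = "missense",
    included = TRUE, prob = probs,
    ddg = scores, stringsAsFactors = FALSE)
  new("SnvCatalogue", regionId = regionId, entries = e,
      classFilter = "missense", exclusions = character())
}

observedFromIndex <- function(catalogue, idx, count = rep(1, length(idx))) {
  agg <- tapply(count, idx, sum)
  new("ObservedMutationSet", regionId = regionId(catalogue),
      entryIndex = as.integer(names(agg)), count = as.numeric(agg))
}

# exhaustive enumeration of the two-tailed Monte Carlo p-value for tiny
# catalogues: all ordered samples of size n, each weighted by its
# probability, statistic = median
enumMonteCarloP <- function(scores, probs, obsStat) {
  n <- length(obsStat$scores)
  idx <- do.call(expand.grid, rep(list(seq_along(scores)), n))
  w <- apply(idx, 1L, function(r) prod(probs[r]))
  st <- apply(idx, 1L, function(r) median(scores[r]))
  obs <- median(obsStat$scores)
  pHi <- sum(w[st >= obs])
  pLo <- sum(w[st <= obs])
  min(1, 2 * min(pHi, pLo))
}

# equal-tailed binomial quantile oracle by direct pmf accumulation
pmfQuantile <- function(n, p0, q) {
  cdf <- cumsum(dbinom(0:n, n, p0))
  min(which(cdf >= q - 1e-12)) - 1L
}

# Kolmogorov statistic against the uniform on [0,1]
ksUniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - (seq_len(n) - 1) / n), abs(p - seq_len(n) / n))
}

# a ready-made annotated catalogue with planted partitions and ddG
maskingCatalogue <- function(nCodons = 100, seed = 11) {
  tx <- simulateTranscript(nCodons, seed = seed)
  cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
  cat <- partitionFeatures(cat)
  attachFeatures(cat, ddg = simulateDdg(cat, seed = seed + 1L))
}

# frozen checksum of the shipped NOTCH residue-set fixture
RESIDUE_SET_FIXTURE_MD5 <- "53ccae73380cae60ee5ec6b1ed004cf0"

readTsv_ <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
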