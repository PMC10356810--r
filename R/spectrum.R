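# Neutral mutational spectrum: strand-specific trinucleotide-context
# substitution rates estimated from observed exonic SNVs.

#' Select the longest transcript of a gene
#'
#' When a gene has several annotated transcripts, the longest CDS is kept
#' and the alternatives discarded. Ties are broken deterministically by
#' the lexicographically smallest transcript identifier.
#'
#' @param transcripts list of [Transcript-class] objects for one gene.
#' @return The selected [Transcript-class].
#' @examples
#' a <- transcript("G", "T2", "ATGAAA")
#' b <- transcript("G", "T1", "ATGAAA")
#' transcriptId(selectLongestTranscript(list(a, b)))  # "T1"
#' @export
selectLongestTranscript <- function(transcripts) {
  if (length(transcripts) == 0L)
    stop("no transcripts supplied", call. = FALSE)
  len <- vapply(transcripts, transcriptLength, integer(1))
  ids <- vapply(transcripts, transcriptId, character(1))
  best <- which(len == max(len))
  transcripts[[best[order(ids[best])][1L]]]
}

#' Trinucleotide context of a CDS position
#'
#' Returns the three bases centred on a CDS position, read in the
#' direction of transcription. Position 1 uses the upstream flank, the
#' last position the downstream flank; internal positions use spliced CDS
#' neighbours.
#'
#' @param tx a [Transcript-class].
#' @param cdsPosition 1-based position(s) within the CDS (vectorised).
#' @return character vector of 3-base contexts.
#' @examples
#' tx <- transcript("G", "T", "ATGC", upstream = "G", downstream = "A")
#' contextOf(tx, 1)  # "GAT"
#' contextOf(tx, 3)  # "TGC"
#' @export
contextOf <- function(tx, cdsPosition) {
  n <- transcriptLength(tx)
  if (any(cdsPosition < 1L | cdsPosition > n))
    stop(sprintf("CDS position out of range 1..%d", n), call. = FALSE)
  full <- paste0(tx@upstream, tx@cds, tx@downstream)
  substring(full, cdsPosition, cdsPosition + 2L)
}

#' Estimate the trinucleotide mutational spectrum
#'
#' For each of the 192 strand-specific channels (5' base, reference base,
#' 3' base, alternate base), the rate is the total number of observed
#' mutations of that trinucleotide change divided by the number of times
#' the context occurs across the selected transcripts. Only genes carrying
#' at least one mutation contribute to the context denominator; for genes
#' with several transcripts the longest is selected
#' (see [selectLongestTranscript()]). Contexts containing non-ACGT bases
#' are excluded from numerator and denominator alike.
#'
#' @param mutations data.frame of observed SNVs with columns `gene`,
#'   `cds_pos` (1-based), `ref`, `alt`, `count` (recurrence; defaults to 1
#'   if absent).
#' @param transcripts list of [Transcript-class] objects (may include
#'   several per gene).
#' @param countWeighted if `TRUE` (default) a mutation merged to k clones
#'   contributes k to the numerator; if `FALSE`, each distinct site
#'   contributes 1.
#' @return A [TrinucleotideSpectrum-class].
#' @examples
#' tx <- simulateTranscript(50, seed = 1)
#' mut <- data.frame(gene = geneId(tx), cds_pos = 5,
#'                   ref = substring(cdsSequence(tx), 5, 5), alt = "T",
#'                   count = 1)
#' mut <- mut[mut$ref != "T", ]
#' if (nrow(mut)) sp <- estimateSpectrum(mut, list(tx))
#' @export
estimateSpectrum <- function(mutations, transcripts, countWeighted = TRUE) {
  if (is.null(mutations$count)) mutations$count <- 1
  stopifnot(all(c("gene", "cds_pos", "ref", "alt") %in% names(mutations)))

  byGene <- split(transcripts,
                  vapply(transcripts, geneId, character(1)))
  selected <- lapply(byGene, selectLongestTranscript)

  genes <- unique(as.character(mutations$gene))
  missing <- setdiff(genes, names(selected))
  if (length(missing))
    stop(sprintf("no transcript supplied for gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  ch <- emptyChannelTable()
  ctxKeys <- contextKey(ch$ctx5, ch$ref, ch$ctx3)

  # denominator: context occurrences in transcripts of mutated genes
  ctxCount <- integer(length(unique(ctxKeys)))
  names(ctxCount) <- unique(ctxKeys)
  for (g in genes) {
    tx <- selected[[g]]
    ctx <- contextOf(tx, seq_len(transcriptLength(tx)))
    ctx <- ctx[!grepl("[^ACGT]", ctx)]
    tab <- table(ctx)
    ctxCount[names(tab)] <- ctxCount[names(tab)] + as.integer(tab)
  }

  # numerator: observed mutations per channel (vectorised per gene)
  mutCount <- numeric(nrow(ch))
  names(mutCount) <- channelKey(ch$ctx5, ch$ref, ch$ctx3, ch$alt)
  mutations$gene <- as.character(mutations$gene)
  rowIdx <- seq_len(nrow(mutations))
  for (g in genes) {
    sel <- mutations$gene == g
    tx <- selected[[g]]
    pos <- as.integer(mutations$cds_pos[sel])
    ctx <- contextOf(tx, pos)
    ref <- toupper(as.character(mutations$ref[sel]))
    alt <- toupper(as.character(mutations$alt[sel]))
    bad <- substring(ctx, 2L, 2L) != ref
    if (any(bad))
      stop(sprintf(
        "mutation row %d: ref '%s' does not match transcript base '%s' at %s:%d",
        rowIdx[sel][bad][1L], ref[bad][1L],
        substring(ctx, 2L, 2L)[bad][1L], g, pos[bad][1L]), call. = FALSE)
    if (any(ref == alt))
      stop(sprintf("mutation row %d: ref equals alt",
                   rowIdx[sel][ref == alt][1L]), call. = FALSE)
    ok <- !grepl("[^ACGT]", ctx) & !grepl("[^ACGT]", alt)  # ambiguous excluded
    w <- if (countWeighted) as.numeric(mutations$count[sel]) else
      rep(1, sum(sel))
    add <- tapply(w[ok], paste0(ctx[ok], alt[ok]), sum)
    mutCount[names(add)] <- mutCount[names(add)] + as.numeric(add)
  }

  ch$context_count <- as.integer(ctxCount[ctxKeys])
  ch$mutation_count <- unname(mutCount)
  ch$rate <- ifelse(ch$context_count > 0,
                    ch$mutation_count / ch$context_count, 0)
  new("TrinucleotideSpectrum", channels = ch)
}

#' Look up a spectrum rate
#'
#' Returns the (unnormalised) per-site rate of one channel; the catalogue
#' module normalises rates into probabilities. A channel whose context was
#' never seen has rate 0 and triggers a warning.
#'
#' @param spectrum a [TrinucleotideSpectrum-class].
#' @param ctx5,ref,ctx3,alt channel coordinates (vectorised).
#' @return numeric vector of rates.
#' @examples
#' sp <- uniformSpectrum()
#' spectrumRate(sp, "A", "C", "G", "T")
#' @export
spectrumRate <- function(spectrum, ctx5, ref, ctx3, alt) {
  ch <- spectrum@channels
  key <- channelKey(ch$ctx5, ch$ref, ch$ctx3, ch$alt)
  q <- channelKey(toupper(ctx5), toupper(ref), toupper(ctx3), toupper(alt))
  idx <- match(q, key)
  if (anyNA(idx))
    stop("undefined channel (check bases are A/C/G/T and ref != alt)",
         call. = FALSE)
  zero <- ch$context_count[idx] == 0L
  if (any(zero))
    warning(sprintf("%d channel(s) with zero context count; returning rate 0",
                    sum(zero)), call. = FALSE)
  ch$rate[idx]
}

#' Flat spectrum with equal rate on every channel
#'
#' A synthetic spectrum assigning the same rate to all 192 channels,
#' useful as an uninformative null and in tests.
#'
#' @param rate per-site rate for each channel.
#' @param contextCount nominal context count stored per context.
#' @return A [TrinucleotideSpectrum-class].
#' @export
uniformSpectrum <- function(rate = 0.01, contextCount = 1000L) {
  ch <- emptyChannelTable()
  ch$context_count <- as.integer(contextCount)
  ch$rate <- rate
  ch$mutation_count <- rate * contextCount
  new("TrinucleotideSpectrum", channels = ch)
}

#' Random spectrum for simulations
#'
#' Draws channel rates from a log-normal distribution (a crude emulation
#' of the skew of real mutational spectra) with fixed context counts.
#'
#' @param seed integer seed.
#' @param meanRate approximate mean per-site rate.
#' @param sdlog log-scale standard deviation of channel-to-channel spread.
#' @param contextCount context count stored per context.
#' @return A [TrinucleotideSpectrum-class].
#' @export
randomSpectrum <- function(seed, meanRate = 0.01, sdlog = 1,
                           contextCount = 1000L) {
  set.seed(seed)
  ch <- emptyChannelTable()
  ch$context_count <- as.integer(contextCount)
  ch$rate <- meanRate * exp(stats::rnorm(nrow(ch), 0, sdlog)) /
    exp(sdlog^2 / 2)
  ch$mutation_count <- ch$rate * ch$context_count
  new("TrinucleotideSpectrum", channels = ch)
}
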