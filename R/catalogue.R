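# Catalogue of every possible coding SNV in a region, with consequence
# annotation and normalised neutral probabilities.

#' Consequence classes used by the catalogue
#'
#' @return character vector of the four consequence classes, in display
#'   order.
#' @export
consequenceClasses <- function() CONSEQUENCE_LEVELS

#' Enumerate every possible SNV of a coding region
#'
#' Lists the three possible single-nucleotide variants of every CDS
#' position in the requested residue interval, annotates each with the
#' reference and alternate amino acid under the standard codon table and
#' the resulting consequence class (synonymous, missense, nonsense,
#' stop-loss), and records the trinucleotide context for the null model.
#' Order is deterministic: by CDS position, then alternate base A<C<G<T.
#'
#' @param tx a [Transcript-class].
#' @param region protein residue interval `c(first, last)` (1-based,
#'   closed); default is the whole transcript.
#' @return data.frame with one row per possible SNV: `cds_pos`, `ref`,
#'   `alt`, `ctx5`, `ctx3`, `codon_index`, `residue`, `aa_ref`, `aa_alt`,
#'   `consequence`.
#' @examples
#' tx <- transcript("G", "T", "ATGTGG")
#' snvs <- enumerateSnvs(tx)
#' subset(snvs, consequence == "nonsense")
#' @export
enumerateSnvs <- function(tx, region = NULL) {
  nCodon <- transcriptLength(tx) %/% 3L
  if (is.null(region)) region <- c(1L, nCodon)
  region <- as.integer(region)
  if (length(region) != 2L || region[1L] < 1L || region[2L] > nCodon ||
      region[1L] > region[2L])
    stop(sprintf("region must lie within residues 1..%d", nCodon),
         call. = FALSE)

  codons <- region[1L]:region[2L]
  pos <- rep((codons - 1L) * 3L, each = 3L) + 1:3
  cds <- strsplit(tx@cds, "")[[1L]]
  ref <- cds[pos]
  ctx <- contextOf(tx, pos)

  alts <- lapply(ref, function(r) setdiff(DNA_BASES_, r))
  k <- lengths(alts)  # always 3 for ACGT refs
  out <- data.frame(
    cds_pos = rep(pos, k),
    ref = rep(ref, k),
    alt = unlist(alts),
    ctx5 = rep(substring(ctx, 1L, 1L), k),
    ctx3 = rep(substring(ctx, 3L, 3L), k),
    stringsAsFactors = FALSE
  )
  out$codon_index <- (out$cds_pos - 1L) %/% 3L + 1L
  out$residue <- out$codon_index

  codonStart <- (out$codon_index - 1L) * 3L + 1L
  refCodon <- paste0(cds[codonStart], cds[codonStart + 1L],
                     cds[codonStart + 2L])
  offset <- out$cds_pos - codonStart  # 0..2 within codon
  altCodon <- refCodon
  substring(altCodon, offset + 1L, offset + 1L) <- out$alt

  out$aa_ref <- translateCodon(refCodon)
  out$aa_alt <- translateCodon(altCodon)
  out$consequence <- ifelse(out$aa_ref == out$aa_alt, "synonymous",
    ifelse(out$aa_alt == "*", "nonsense",
      ifelse(out$aa_ref == "*", "stop-loss", "missense")))
  out[order(out$cds_pos, out$alt), , drop = FALSE]
}

#' Build the neutral null model over a catalogue
#'
#' Combines enumerated SNVs with the mutational spectrum: each entry is
#' assigned a weight equal to the spectrum rate of its context/alternate
#' channel; entries of the requested consequence class(es) are retained
#' and their weights renormalised to probabilities summing to one. Entries
#' outside the class filter remain in the catalogue with `included =
#' FALSE` and probability 0, so observed mutations of excluded classes
#' can still be recognised and tallied.
#'
#' @param entries data.frame from [enumerateSnvs()] (or an
#'   [SnvCatalogue-class], whose entries are re-used).
#' @param spectrum a [TrinucleotideSpectrum-class].
#' @param classFilter consequence classes forming the null
#'   (default "missense", as in within-missense selection analyses).
#' @param regionId label for the catalogue.
#' @return An [SnvCatalogue-class].
#' @examples
#' tx <- simulateTranscript(40, seed = 3)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' sum(nullProbabilities(cat)[catalogueEntries(cat)$included])
#' @export
buildNull <- function(entries, spectrum, classFilter = "missense",
                      regionId = "region") {
  if (is(entries, "SnvCatalogue")) entries <- entries@entries
  stopifnot(all(classFilter %in% CONSEQUENCE_LEVELS))
  rate <- suppressWarnings(
    spectrumRate(spectrum, entries$ctx5, entries$ref, entries$ctx3,
                 entries$alt))
  inc <- entries$consequence %in% classFilter
  tot <- sum(rate[inc])
  if (!any(inc) || tot <= 0)
    stop("degenerate null: no included entry has positive rate",
         call. = FALSE)
  entries$included <- inc
  entries$prob <- ifelse(inc, rate / tot, 0)
  new("SnvCatalogue", regionId = as.character(regionId), entries = entries,
      classFilter = classFilter, exclusions = character())
}

#' Map observed mutations onto a catalogue
#'
#' Matches each observed mutation record to its unique catalogue entry by
#' CDS position, reference and alternate base. Records of consequence
#' classes outside the catalogue's filter (or excluded by layering) are
#' dropped with a tally message; records outside the region are dropped
#' with a warning; reference mismatches are an error.
#'
#' @param mutations data.frame with columns `cds_pos`, `ref`, `alt` and
#'   optional `count` (recurrence; default 1). A `gene` column, if
#'   present, is ignored here — the catalogue defines the region.
#' @param catalogue an [SnvCatalogue-class].
#' @return An [ObservedMutationSet-class].
#' @examples
#' tx <- simulateTranscript(40, seed = 3)
#' cat <- buildNull(enumerateSnvs(tx), uniformSpectrum(), regionId = "toy")
#' e <- catalogueEntries(cat)
#' hit <- which(e$included)[1]
#' obs <- mapObserved(data.frame(cds_pos = e$cds_pos[hit],
#'                               ref = e$ref[hit], alt = e$alt[hit],
#'                               count = 3), cat)
#' totalMutations(obs)
#' @export
mapObserved <- function(mutations, catalogue) {
  e <- catalogue@entries
  if (is.null(mutations$count)) mutations$count <- rep(1, nrow(mutations))
  n0 <- nrow(mutations)
  if (n0 == 0L)
    return(new("ObservedMutationSet", regionId = catalogue@regionId,
               entryIndex = integer(), count = numeric()))

  key <- paste(e$cds_pos, toupper(e$ref), toupper(e$alt))
  q <- paste(as.integer(mutations$cds_pos), toupper(mutations$ref),
             toupper(mutations$alt))
  idx <- match(q, key)

  outside <- is.na(idx)
  if (any(outside)) {
    # distinguish genuine out-of-region from a ref mismatch at a covered pos
    inRegion <- as.integer(mutations$cds_pos) %in% e$cds_pos
    mism <- outside & inRegion
    if (any(mism)) {
      i <- which(mism)[1L]
      trueRef <- e$ref[match(as.integer(mutations$cds_pos[i]), e$cds_pos)]
      stop(sprintf(
        "mutation row %d: ref/alt '%s>%s' at CDS %d inconsistent with catalogue (ref is '%s')",
        i, mutations$ref[i], mutations$alt[i],
        as.integer(mutations$cds_pos[i]), trueRef), call. = FALSE)
    }
    warning(sprintf("%d mutation(s) outside region '%s' dropped",
                    sum(outside), catalogue@regionId), call. = FALSE)
  }

  idx <- idx[!outside]
  cnt <- as.numeric(mutations$count[!outside])

  excl <- !e$included[idx]
  if (any(excl)) {
    tab <- table(e$consequence[idx][excl])
    message(sprintf("dropped %g mutation(s) of excluded class(es): %s",
                    sum(cnt[excl]),
                    paste(sprintf("%s=%g", names(tab), tab), collapse = ", ")))
  }
  idx <- idx[!excl]
  cnt <- cnt[!excl]

  agg <- tapply(cnt, idx, sum)
  new("ObservedMutationSet",
      regionId = catalogue@regionId,
      entryIndex = as.integer(names(agg)),
      count = as.numeric(agg))
}
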