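# Delimited-text readers/writers for the formats the pipeline consumes
# and produces. All writers prepend a '#'-comment provenance header;
# readers skip comments.

provenanceHeader <- function(seed = NULL, inputs = character(),
                             exclusions = character()) {
  h <- c(sprintf("# SomaticSelect %s",
                 as.character(utils::packageVersion("SomaticSelect"))))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%s", seed))
  for (f in inputs)
    if (file.exists(f))
      h <- c(h, sprintf("# input %s md5=%s", basename(f),
                        unname(tools::md5sum(f))))
  if (length(exclusions))
    h <- c(h, sprintf("# exclusions=%s", paste(exclusions, collapse = ";")))
  h
}

writeTsvWithHeader <- function(df, path, header = provenanceHeader()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read an observed mutation table
#'
#' Tab-separated with header columns `gene`, `cds_pos` (1-based), `ref`,
#' `alt`, `count`, optional `aa_change`. Malformed rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
readMutationTable <- function(path) {
  d <- readTsv(path)
  need <- c("gene", "cds_pos", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(d$count)) d$count <- 1L
  if (nrow(d)) {
    pos <- suppressWarnings(as.integer(d$cds_pos))
    cnt <- suppressWarnings(as.numeric(d$count))
    bad <- which(is.na(pos) | pos < 1L | is.na(cnt) | cnt < 1 |
                   !toupper(d$ref) %in% DNA_BASES_ |
                   !toupper(d$alt) %in% DNA_BASES_ |
                   toupper(d$ref) == toupper(d$alt))
    if (length(bad))
      stop(sprintf("%s: malformed mutation row(s) at data line(s) %s",
                   path, paste(utils::head(bad, 10L), collapse = ", ")),
           call. = FALSE)
    d$cds_pos <- pos
    d$count <- cnt
    d$ref <- toupper(d$ref)
    d$alt <- toupper(d$alt)
  }
  d
}

#' Write an observed mutation table
#' @param mutations data.frame with `gene`, `cds_pos`, `ref`, `alt`,
#'   `count`.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeMutationTable <- function(mutations, path, seed = NULL) {
  writeTsvWithHeader(mutations, path, provenanceHeader(seed = seed))
}

#' Convert an ObservedMutationSet back to a mutation table
#'
#' @param observed an [ObservedMutationSet-class].
#' @param catalogue the matching [SnvCatalogue-class].
#' @param gene gene label for the `gene` column.
#' @return data.frame with `gene`, `cds_pos`, `ref`, `alt`, `count`.
#' @export
observedToTable <- function(observed, catalogue,
                            gene = regionId(catalogue)) {
  e <- catalogue@entries[observed@entryIndex, , drop = FALSE]
  data.frame(gene = gene, cds_pos = e$cds_pos, ref = e$ref, alt = e$alt,
             count = observed@count, stringsAsFactors = FALSE)
}

#' Read transcripts from FASTA plus annotation
#'
#' One FASTA record per transcript holding the CDS; flanks and
#' identifiers are carried as `key=value` tags on the header line, e.g.
#' `>T1 gene_id=G1 transcript_id=T1 upstream=G downstream=A`. An optional
#' annotation table (`gene_id`, `transcript_id`, `cds_length`,
#' tab-separated) is cross-checked against the sequences.
#'
#' @param fasta FASTA path.
#' @param annotation optional annotation TSV path.
#' @return list of [Transcript-class] objects.
#' @export
readTranscriptsFasta <- function(fasta, annotation = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  parseTags <- function(header) {
    parts <- strsplit(header, "[ \t]+")[[1L]]
    kv <- parts[grepl("=", parts, fixed = TRUE)]
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(vals, sub("=.*$", "", kv))
  }
  txs <- lapply(seq_along(seqs), function(i) {
    tags <- parseTags(names(seqs)[i])
    id <- strsplit(names(seqs)[i], "[ \t]+")[[1L]][1L]
    transcript(
      geneId = if ("gene_id" %in% names(tags)) tags[["gene_id"]] else id,
      transcriptId = if ("transcript_id" %in% names(tags))
        tags[["transcript_id"]] else id,
      cds = as.character(seqs[[i]]),
      upstream = if ("upstream" %in% names(tags)) tags[["upstream"]] else "N",
      downstream = if ("downstream" %in% names(tags))
        tags[["downstream"]] else "N")
  })
  if (!is.null(annotation)) {
    ann <- readTsv(annotation)
    ids <- vapply(txs, transcriptId, character(1))
    for (j in seq_len(nrow(ann))) {
      k <- match(ann$transcript_id[j], ids)
      if (!is.na(k) && !is.null(ann$cds_length) &&
          transcriptLength(txs[[k]]) != ann$cds_length[j])
        stop(sprintf(
          "annotation mismatch for %s: FASTA CDS is %d nt, annotation says %d",
          ann$transcript_id[j], transcriptLength(txs[[k]]),
          ann$cds_length[j]), call. = FALSE)
    }
  }
  txs
}

#' Write transcripts as FASTA with flank tags
#' @param transcripts list of [Transcript-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeTranscriptsFasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(transcripts, cdsSequence, character(1)))
  names(seqs) <- vapply(transcripts, function(tx) sprintf(
    "%s gene_id=%s transcript_id=%s upstream=%s downstream=%s",
    transcriptId(tx), geneId(tx), transcriptId(tx), tx@upstream,
    tx@downstream), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a spectrum as a 192-row TSV
#' @param spectrum a [TrinucleotideSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  writeTsvWithHeader(spectrum@channels, path)
}

#' Read a spectrum TSV written by [writeSpectrum()]
#' @param path file path.
#' @return A [TrinucleotideSpectrum-class].
#' @export
readSpectrum <- function(path) {
  ch <- readTsv(path)
  canon <- emptyChannelTable()
  idx <- match(channelKey(canon$ctx5, canon$ref, canon$ctx3, canon$alt),
               channelKey(ch$ctx5, ch$ref, ch$ctx3, ch$alt))
  if (anyNA(idx))
    stop(sprintf("%s: not a complete 192-channel spectrum", path),
         call. = FALSE)
  new("TrinucleotideSpectrum", channels = {
    out <- ch[idx, c("ctx5", "ref", "ctx3", "alt", "context_count",
                     "mutation_count", "rate")]
    rownames(out) <- NULL
    out
  })
}

#' Export a catalogue (with features) as TSV
#' @param catalogue an [SnvCatalogue-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCatalogue <- function(catalogue, path) {
  writeTsvWithHeader(catalogue@entries, path,
                     provenanceHeader(exclusions = catalogue@exclusions))
}

#' Re-import a catalogue exported by [writeCatalogue()]
#' @param path file path.
#' @param regionId region label.
#' @param classFilter consequence classes of the stored null.
#' @return An [SnvCatalogue-class].
#' @export
readCatalogue <- function(path, regionId = "region",
                          classFilter = "missense") {
  e <- readTsv(path)
  for (col in names(e))
    if (is.character(e[[col]]) && all(e[[col]] %in% c("TRUE", "FALSE", "NA")))
      e[[col]] <- as.logical(e[[col]])
  new("SnvCatalogue", regionId = regionId, entries = e,
      classFilter = classFilter, exclusions = character())
}

#' Read residue sets from YAML or TSV
#'
#' YAML: a mapping of set names to `residues` (list of integers) and
#' optional `provenance`. TSV: columns `name`, `residue`.
#'
#' @param path file path (`.yaml`/`.yml` or `.tsv`).
#' @return named list of [ResidueSet-class] objects.
#' @export
readResidueSets <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    out <- lapply(names(y), function(nm) {
      el <- y[[nm]]
      if (is.list(el) && !is.null(el$residues))
        residueSet(nm, unlist(el$residues),
                   if (is.null(el$provenance)) "" else el$provenance)
      else residueSet(nm, unlist(el))
    })
    stats::setNames(out, names(y))
  } else {
    d <- readTsv(path)
    if (!all(c("name", "residue") %in% names(d)))
      stop(sprintf("%s: residue-set TSV needs columns 'name' and 'residue'",
                   path), call. = FALSE)
    sets <- split(d$residue, d$name)
    stats::setNames(lapply(names(sets), function(nm)
      residueSet(nm, sets[[nm]])), names(sets))
  }
}

#' Read a per-gene truncating dN/dS table
#'
#' Tab-separated with columns `gene` and `dnds` (upstream estimates, e.g.
#' from dndscv; this package consumes, never computes, dN/dS).
#'
#' @param path file path.
#' @return data.frame with `gene`, `dnds`.
#' @export
readDndsTable <- function(path) {
  d <- readTsv(path)
  if (!all(c("gene", "dnds") %in% names(d)))
    stop(sprintf("%s: needs columns 'gene' and 'dnds'", path), call. = FALSE)
  d$dnds <- as.numeric(d$dnds)
  d
}

#' Write a ddG table as 5-column TSV
#' @param ddg a [DdgTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDdgTable <- function(ddg, path) {
  writeTsvWithHeader(ddg@table, path)
}

#' Read a 5-column ddG TSV written by [writeDdgTable()]
#' @param path file path.
#' @param sourceStructure identifier stored on the table.
#' @return A [DdgTable-class].
#' @export
readDdgTable <- function(path, sourceStructure = "unknown") {
  t <- readTsv(path)
  need <- c("chain", "residue", "aa_ref", "aa_alt", "ddg")
  if (!all(need %in% names(t)))
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  t$chain <- as.character(t$chain)
  new("DdgTable", table = t, sourceStructure = sourceStructure)
}

resultToRow <- function(res) {
  data.frame(
    feature = res@feature, test = res@test, n = res@n,
    expected = res@expected, observed = res@observed, p = res@p,
    ci_low = res@ciLow, ci_high = res@ciHigh,
    exclusions = paste(res@exclusions, collapse = ";"),
    seed = if (is.null(res@details$seed)) NA else res@details$seed,
    n_draws = if (is.null(res@details$nDraws)) NA else res@details$nDraws,
    status = if (is.null(res@details$status)) "" else res@details$status,
    stringsAsFactors = FALSE)
}

#' Export selection test results as TSV plus JSON mirror
#'
#' @param results a [SelectionTestResult-class] or list of them.
#' @param path output TSV path; a `.json` sibling with full precision is
#'   written alongside.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeTestResults <- function(results, path, seed = NULL) {
  if (is(results, "SelectionTestResult")) results <- list(results)
  df <- do.call(rbind, lapply(results, resultToRow))
  writeTsvWithHeader(df, path, provenanceHeader(seed = seed))
  jsonlite::write_json(df, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
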