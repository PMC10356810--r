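# Generics and accessors. Bioconductor convention: slot access only
# through accessors, show() methods give a compact on-screen summary.

#' @rdname Transcript-class
#' @param object,x a package object.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname Transcript-class
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname Transcript-class
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))

#' @rdname Transcript-class
#' @export
setGeneric("transcriptLength", function(x) standardGeneric("transcriptLength"))

#' @rdname TrinucleotideSpectrum-class
#' @export
setGeneric("spectrumChannels", function(x) standardGeneric("spectrumChannels"))

#' @rdname SnvCatalogue-class
#' @export
setGeneric("catalogueEntries", function(x) standardGeneric("catalogueEntries"))

#' @rdname SnvCatalogue-class
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' @rdname SnvCatalogue-class
#' @export
setGeneric("nullProbabilities", function(x) standardGeneric("nullProbabilities"))

#' @rdname SnvCatalogue-class
#' @export
setGeneric("exclusionLabels", function(x) standardGeneric("exclusionLabels"))

#' @rdname ObservedMutationSet-class
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))

#' @rdname ObservedMutationSet-class
#' @export
setGeneric("totalMutations", function(x) standardGeneric("totalMutations"))

#' @rdname CdfShiftResult-class
#' @export
setGeneric("shiftValue", function(x) standardGeneric("shiftValue"))

#' @rdname SelectionTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

setMethod("geneId", "Transcript", function(x) x@geneId)
setMethod("transcriptId", "Transcript", function(x) x@transcriptId)
setMethod("cdsSequence", "Transcript", function(x) x@cds)
setMethod("transcriptLength", "Transcript", function(x) nchar(x@cds))

setMethod("spectrumChannels", "TrinucleotideSpectrum",
          function(x) x@channels)

setMethod("catalogueEntries", "SnvCatalogue", function(x) x@entries)
setMethod("regionId", "SnvCatalogue", function(x) x@regionId)
setMethod("nullProbabilities", "SnvCatalogue", function(x) x@entries$prob)
setMethod("exclusionLabels", "SnvCatalogue", function(x) x@exclusions)
setMethod("regionId", "ObservedMutationSet", function(x) x@regionId)

setMethod("mutationCounts", "ObservedMutationSet",
          function(x) stats::setNames(x@count, x@entryIndex))
setMethod("totalMutations", "ObservedMutationSet", function(x) sum(x@count))

setMethod("shiftValue", "CdfShiftResult", function(x) x@shift)
setMethod("pValue", "SelectionTestResult", function(x) x@p)

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript %s (gene %s): %d nt CDS (%d codons), flanks %s/%s\n",
              object@transcriptId, object@geneId, nchar(object@cds),
              nchar(object@cds) %/% 3L, object@upstream, object@downstream))
})

setMethod("show", "TrinucleotideSpectrum", function(object) {
  ch <- object@channels
  cat(sprintf(
    "TrinucleotideSpectrum: 192 channels, %d contexts counted, %g mutations\n",
    sum(ch$context_count[!duplicated(paste(ch$ctx5, ch$ref, ch$ctx3))] > 0),
    sum(ch$mutation_count)))
})

setMethod("show", "SnvCatalogue", function(object) {
  e <- object@entries
  cat(sprintf("SnvCatalogue '%s': %d possible SNVs (%d included)\n",
              object@regionId, nrow(e), sum(e$included)))
  if (nrow(e)) {
    tab <- table(factor(e$consequence, CONSEQUENCE_LEVELS))
    cat("  consequences:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    feat <- setdiff(names(e), c("cds_pos", "ref", "alt", "ctx5", "ctx3",
                                "codon_index", "residue", "aa_ref", "aa_alt",
                                "consequence", "included", "prob"))
    if (length(feat))
      cat("  features:", paste(feat, collapse = ", "), "\n")
  }
  if (length(object@exclusions))
    cat("  exclusions:", paste(object@exclusions, collapse = " -> "), "\n")
})

setMethod("show", "ObservedMutationSet", function(object) {
  cat(sprintf(
    "ObservedMutationSet '%s': %g mutations at %d distinct sites\n",
    object@regionId, sum(object@count), length(object@entryIndex)))
})

setMethod("show", "SelectionTestResult", function(object) {
  cat(sprintf("SelectionTestResult [%s] feature '%s'\n",
              object@test, object@feature))
  cat(sprintf("  n = %g, expected = %.4g, observed = %.4g, p = %.3g\n",
              object@n, object@expected, object@observed, object@p))
  cat(sprintf("  95%% CI (expected): [%.4g, %.4g]\n",
              object@ciLow, object@ciHigh))
  if (length(object@exclusions))
    cat("  exclusions:", paste(object@exclusions, collapse = " -> "), "\n")
  if (!is.null(object@details$status))
    cat("  status:", object@details$status, "\n")
})

setMethod("show", "CdfShiftResult", function(object) {
  cat(sprintf("CdfShiftResult gene '%s': shift = %.4f (n = %g, %d structure%s)\n",
              object@geneId, object@shift, object@n,
              max(1L, length(object@perStructure)),
              if (length(object@perStructure) > 1L) "s" else ""))
})

setMethod("show", "DdgTable", function(object) {
  cat(sprintf("DdgTable (%s): %d substitutions on %d residues\n",
              object@sourceStructure, nrow(object@table),
              length(unique(object@table$residue))))
})

setMethod("show", "ResidueSet", function(object) {
  cat(sprintf("ResidueSet '%s': %d residues\n",
              object@name, length(object@residues)))
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf(
    "StructureModel: %d atoms, %d residues, %d target atoms (%s)\n",
    nrow(a), length(unique(paste(a$chain, a$resno)[!a$isTarget])),
    sum(a$isTarget), object@targetSelection))
})
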