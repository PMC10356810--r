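#' @import methods
#' @importFrom stats dbinom qbinom median cor.test setNames rnorm runif
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES_ <- c("A", "C", "G", "T")
CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense", "stop-loss")

#' Coding transcript with single-base flanks
#'
#' Holds the spliced coding sequence of one transcript in transcription
#' direction, plus one flanking base at each end so that every CDS position
#' has a full trinucleotide context.
#'
#' @slot geneId gene identifier.
#' @slot transcriptId transcript identifier.
#' @slot cds coding sequence (A/C/G/T, length divisible by 3).
#' @slot upstream single base 5' of the CDS.
#' @slot downstream single base 3' of the CDS.
#'
#' @seealso [transcript()] for the user constructor, [contextOf()],
#'   [enumerateSnvs()].
#' @exportClass Transcript
setClass("Transcript",
  representation(
    geneId = "character",
    transcriptId = "character",
    cds = "character",
    upstream = "character",
    downstream = "character"
  )
)

setValidity("Transcript", function(object) {
  msg <- character()
  if (length(object@cds) != 1L || !nzchar(object@cds))
    msg <- c(msg, "cds must be a single non-empty string")
  else {
    if (nchar(object@cds) %% 3L != 0L)
      msg <- c(msg, "cds length must be divisible by 3")
    if (grepl("[^ACGTN]", object@cds))
      msg <- c(msg, "cds may contain only A/C/G/T/N")
  }
  for (fl in c("upstream", "downstream")) {
    b <- slot(object, fl)
    if (length(b) != 1L || nchar(b) != 1L || grepl("[^ACGTN]", b))
      msg <- c(msg, sprintf("%s flank must be a single A/C/G/T/N base", fl))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Transcript
#'
#' @param geneId,transcriptId identifiers.
#' @param cds coding sequence string in transcription direction (multiple
#'   of 3, A/C/G/T; N tolerated but excluded from spectrum counting).
#' @param upstream,downstream one flanking base each side.
#' @return A [Transcript-class] object.
#' @examples
#' tx <- transcript("G1", "T1", "ATGGCT", upstream = "C", downstream = "A")
#' transcriptLength(tx)
#' @export
transcript <- function(geneId, transcriptId, cds,
                       upstream = "N", downstream = "N") {
  new("Transcript",
    geneId = as.character(geneId),
    transcriptId = as.character(transcriptId),
    cds = toupper(as.character(cds)),
    upstream = toupper(as.character(upstream)),
    downstream = toupper(as.character(downstream))
  )
}

#' Trinucleotide mutational spectrum
#'
#' Strand-specific per-context substitution rates: 192 channels, one for
#' each (5' base, reference base, 3' base, alternate base) combination,
#' computed in the direction of transcription. The rate of a channel is
#' the number of observed mutations of that trinucleotide change divided
#' by the number of times the context occurs in the included transcripts.
#'
#' @slot channels data.frame with 192 rows and columns `ctx5`, `ref`,
#'   `ctx3`, `alt`, `context_count`, `mutation_count`, `rate`, in fixed
#'   canonical order (ctx5, ref, ctx3, alt each A<C<G<T).
#'
#' @seealso [estimateSpectrum()], [spectrumRate()], [uniformSpectrum()].
#' @exportClass TrinucleotideSpectrum
setClass("TrinucleotideSpectrum",
  representation(channels = "data.frame")
)

setValidity("TrinucleotideSpectrum", function(object) {
  ch <- object@channels
  need <- c("ctx5", "ref", "ctx3", "alt",
            "context_count", "mutation_count", "rate")
  if (!all(need %in% names(ch)))
    return(sprintf("channels must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ch) != 192L)
    return("spectrum must have exactly 192 channels")
  if (any(ch$ref == ch$alt))
    return("ref and alt must differ in every channel")
  if (any(!is.finite(ch$rate)) || any(ch$rate < 0))
    return("rates must be finite and non-negative")
  bad <- ch$context_count > 0 &
    abs(ch$rate - ch$mutation_count / pmax(ch$context_count, 1)) > 1e-9 *
      pmax(1, ch$rate)
  if (any(bad))
    return("rate must equal mutation_count / context_count")
  TRUE
})

#' Catalogue of every possible coding SNV in a region
#'
#' Enumerates all single-nucleotide variants of a coding region (three per
#' CDS position), annotated with codon consequence and, once a null model
#' is attached, a neutral probability per included entry. Feature columns
#' (free-energy change, residue-set membership, distances) are attached by
#' [attachFeatures()]. Entries excluded by the consequence-class filter or
#' by layering carry `included = FALSE` and probability 0; probabilities
#' over included entries always sum to one.
#'
#' @slot regionId label for the gene/region analysed.
#' @slot entries data.frame, one row per possible SNV: `cds_pos`, `ref`,
#'   `alt`, `ctx5`, `ctx3`, `codon_index`, `residue`, `aa_ref`, `aa_alt`,
#'   `consequence`, `included`, `prob`, plus any feature columns.
#' @slot classFilter consequence classes retained by the null model.
#' @slot exclusions character vector of exclusion labels applied, in order.
#'
#' @seealso [enumerateSnvs()], [buildNull()], [mapObserved()],
#'   [excludeEntries()].
#' @exportClass SnvCatalogue
setClass("SnvCatalogue",
  representation(
    regionId = "character",
    entries = "data.frame",
    classFilter = "character",
    exclusions = "character"
  )
)

setValidity("SnvCatalogue", function(object) {
  e <- object@entries
  need <- c("cds_pos", "ref", "alt", "codon_index", "residue",
            "aa_ref", "aa_alt", "consequence", "included", "prob")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$consequence %in% CONSEQUENCE_LEVELS))
      return("unknown consequence class in entries")
    if (any(e$residue != e$codon_index))
      return("residue numbering must equal codon index")
    s <- sum(e$prob[e$included])
    if (any(e$included) && abs(s - 1) > 1e-9)
      return(sprintf("included probabilities sum to %.15f, not 1", s))
    if (any(e$prob < 0))
      return("probabilities must be non-negative")
  }
  TRUE
})

#' Observed somatic mutations mapped onto a catalogue
#'
#' References entries of an [SnvCatalogue-class] by row index, with a
#' recurrence count per entry (number of independent mutant clones).
#'
#' @slot regionId region label, matching the catalogue.
#' @slot entryIndex integer row indices into the catalogue entries.
#' @slot count recurrence count per referenced entry.
#'
#' @seealso [mapObserved()], [simulateMutations()].
#' @exportClass ObservedMutationSet
setClass("ObservedMutationSet",
  representation(
    regionId = "character",
    entryIndex = "integer",
    count = "numeric"
  )
)

setValidity("ObservedMutationSet", function(object) {
  if (length(object@entryIndex) != length(object@count))
    return("entryIndex and count must have equal length")
  if (any(object@count <= 0))
    return("counts must be positive")
  if (anyDuplicated(object@entryIndex))
    return("entryIndex must be unique (counts are aggregated)")
  TRUE
})

#' Result of one selection test
#'
#' Summary of a binomial or Monte Carlo comparison of observed mutations
#' against the neutral null: expected and observed summaries, a two-tailed
#' p-value, a 95% interval for the expected count or statistic, and the
#' exclusion labels in force when the test was run.
#'
#' @slot feature name of the feature or score column tested.
#' @slot test "binomial" or "monte_carlo".
#' @slot n number of observed mutations included (recurrence-weighted).
#' @slot expected expected summary under the null (proportion, or median
#'   in feature units).
#' @slot observed observed summary.
#' @slot p two-tailed p-value (never 0; floored at the test's resolution).
#' @slot ciLow,ciHigh 95% interval for the expected count (binomial) or
#'   null statistic (Monte Carlo).
#' @slot exclusions exclusion labels applied upstream.
#' @slot details list of test internals (seed, nDraws, dropped tallies,
#'   status flags such as "underpowered").
#'
#' @exportClass SelectionTestResult
setClass("SelectionTestResult",
  representation(
    feature = "character",
    test = "character",
    n = "numeric",
    expected = "numeric",
    observed = "numeric",
    p = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    exclusions = "character",
    details = "list"
  )
)

setValidity("SelectionTestResult", function(object) {
  if (length(object@p) == 1L && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  if (length(object@ciLow) == 1L && length(object@ciHigh) == 1L &&
      is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ciLow must not exceed ciHigh")
  TRUE
})

#' CDF-shift of a score distribution
#'
#' Difference between the mean of the observed and the null distributions
#' of mid-distribution CDF values of a score (typically the folding
#' free-energy change). Bounded in [-0.5, 0.5]: -0.5 means all observed
#' mutations sit at the minimum possible score, 0.5 at the maximum, and 0
#' means observed and null means coincide.
#'
#' @slot geneId gene label.
#' @slot shift the mean CDF shift.
#' @slot perStructure per-structure shifts averaged into `shift`.
#' @slot n observed mutations used (recurrence-weighted; for a
#'   multi-structure average, the total over structures).
#'
#' @seealso [cdfShift()], [aggregateGeneShift()].
#' @exportClass CdfShiftResult
setClass("CdfShiftResult",
  representation(
    geneId = "character",
    shift = "numeric",
    perStructure = "numeric",
    n = "numeric"
  )
)

setValidity("CdfShiftResult", function(object) {
  if (any(object@shift < -0.5 - 1e-12) || any(object@shift > 0.5 + 1e-12))
    return("shift must lie within [-0.5, 0.5]")
  TRUE
})

#' Table of per-mutation folding free-energy changes
#'
#' Folding free-energy changes (kcal/mol; positive destabilises) for amino
#' acid substitutions in one structure, keyed by chain, protein residue
#' number and the reference/alternate amino acids, as produced by a FoldX
#' PositionScan run.
#'
#' @slot table data.frame with columns `chain`, `residue`, `aa_ref`,
#'   `aa_alt`, `ddg`.
#' @slot sourceStructure identifier of the structure scanned.
#'
#' @seealso [readFoldxPositionScan()], [classifyDestabilising()].
#' @exportClass DdgTable
setClass("DdgTable",
  representation(table = "data.frame", sourceStructure = "character")
)

setValidity("DdgTable", function(object) {
  t <- object@table
  need <- c("chain", "residue", "aa_ref", "aa_alt", "ddg")
  if (!all(need %in% names(t)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(t) && any(!is.finite(t$ddg)))
    return("ddg values must be finite")
  TRUE
})

#' Named set of protein residues
#'
#' A named set of protein residue numbers, e.g. a ligand-binding interface
#' or the calcium-binding residues of an EGF repeat pair.
#'
#' @slot name set label.
#' @slot residues integer residue numbers (no duplicates).
#' @slot provenance free-text description of where the set comes from.
#'
#' @seealso [residueSet()], [inResidueSet()], [notchResidueSets()].
#' @exportClass ResidueSet
setClass("ResidueSet",
  representation(
    name = "character",
    residues = "integer",
    provenance = "character"
  )
)

setValidity("ResidueSet", function(object) {
  if (any(object@residues < 0))
    return("residue numbers must be non-negative")
  if (anyDuplicated(object@residues))
    return("residue set must not contain duplicates")
  TRUE
})

#' Construct a ResidueSet
#' @param name set label.
#' @param residues residue numbers.
#' @param provenance free-text provenance.
#' @return A [ResidueSet-class].
#' @examples
#' ca <- residueSet("calcium", c(412, 413, 415))
#' inResidueSet(413, ca)
#' @export
residueSet <- function(name, residues, provenance = "") {
  new("ResidueSet",
    name = as.character(name),
    residues = sort(unique(as.integer(residues))),
    provenance = as.character(provenance)
  )
}

#' Protein structure model with a declared binding target
#'
#' Heavy-atom coordinates of a structure plus a target selection — the
#' atoms representing a binding partner (ligand peptide, DNA, substrate) —
#' against which per-residue minimum distances are measured.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`, `isTarget` (logical).
#' @slot targetSelection free-text description of the target atoms.
#'
#' @seealso [readStructurePdb()], [minDistanceToTarget()],
#'   [simulateStructure()].
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", targetSelection = "character")
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "isTarget")
  if (!all(need %in% names(a)))
    return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  if (nrow(a) && any(!is.finite(c(a$x, a$y, a$z))))
    return("coordinates must be finite")
  TRUE
})

#' Planted-selection scenario for the mutation simulator
#'
#' Describes how observed mutations are drawn from a null catalogue:
#' each layer multiplies the sampling weight of entries matching its
#' predicate by an enrichment factor (1 = neutral, 0 = fully negatively
#' selected, >1 = positively selected). Factors compose multiplicatively
#' where predicates overlap.
#'
#' @slot layers list of `list(feature = <predicate string>, factor = <num>)`.
#' @slot nMutations number of mutations to draw.
#'
#' @seealso [selectionScenario()], [fig1Scenario()], [simulateMutations()].
#' @exportClass SelectionScenario
setClass("SelectionScenario",
  representation(layers = "list", nMutations = "numeric")
)

setValidity("SelectionScenario", function(object) {
  for (ly in object@layers) {
    if (!is.list(ly) || is.null(ly$feature) || is.null(ly$factor))
      return("each layer needs 'feature' and 'factor'")
    if (!is.finite(ly$factor) || ly$factor < 0)
      return("enrichment factors must be finite and >= 0")
  }
  if (object@nMutations < 1)
    return("nMutations must be >= 1")
  TRUE
})

#' Construct a SelectionScenario
#'
#' @param layers list of layers, each `list(feature = , factor = )` where
#'   `feature` is a predicate expression over catalogue feature columns
#'   (e.g. `"ddg > 2"` or `"interface"`) and `factor` the enrichment
#'   multiplier.
#' @param nMutations number of observed mutations to draw.
#' @return A [SelectionScenario-class].
#' @examples
#' sc <- selectionScenario(
#'   list(list(feature = "strong", factor = 3),
#'        list(feature = "weak", factor = 2)),
#'   nMutations = 300)
#' @export
selectionScenario <- function(layers, nMutations) {
  new("SelectionScenario", layers = layers, nMutations = as.numeric(nMutations))
}
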