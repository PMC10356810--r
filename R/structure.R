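# Structural feature scoring: FoldX PositionScan ddG tables, residue-set
# membership, and minimum heavy-atom distance to a declared binding target.

AA_THREE_TO_ONE <- local({
  three <- toupper(Biostrings::AMINO_ACID_CODE)
  stats::setNames(names(three), three)
})

#' Read FoldX PositionScan output into a DdgTable
#'
#' Parses per-mutation folding free-energy changes from FoldX
#' PositionScan output. Two dialects are accepted, detected per line:
#' \itemize{
#'   \item label format: `<REF><chain><resnum><alt>` followed by the
#'     energy difference, e.g. `GLUA455K\t1.23` (3-letter or 1-letter
#'     reference amino acid, single-character chain, 1-letter alternate);
#'   \item the package's own 5-column TSV (`chain`, `residue`, `aa_ref`,
#'     `aa_alt`, `ddg`) with header, as written by [writeDdgTable()].
#' }
#' Blank lines and `#` comments are skipped. Duplicate keys keep the last
#' value with a warning; malformed records are an error reporting the
#' line number.
#'
#' @param files path(s) to PositionScan output files.
#' @param residueOffset integer added to structure residue numbers to map
#'   them to protein coordinates (explicit, never inferred).
#' @param sourceStructure identifier stored on the table.
#' @return A [DdgTable-class].
#' @seealso [writeFoldxPositionScan()], [writeDdgTable()].
#' @export
readFoldxPositionScan <- function(files, residueOffset = 0L,
                                  sourceStructure = "unknown") {
  rows <- list()
  labRe <- "^([A-Z]{3}|[A-Z*])([A-Za-z0-9])([0-9]+)([A-Z*])$"
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    header <- FALSE
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "#")) next
      fields <- strsplit(ln, "[\t ]+")[[1L]]
      if (identical(tolower(fields[1L]), "chain")) { header <- TRUE; next }
      if (header && length(fields) == 5L) {
        ddg <- suppressWarnings(as.numeric(fields[5L]))
        if (is.na(ddg))
          stop(sprintf("%s line %d: non-numeric ddG '%s'", f, i, fields[5L]),
               call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = fields[1L],
          residue = as.integer(fields[2L]) + as.integer(residueOffset),
          aa_ref = toupper(fields[3L]), aa_alt = toupper(fields[4L]),
          ddg = ddg, stringsAsFactors = FALSE)
        next
      }
      if (length(fields) != 2L)
        stop(sprintf("%s line %d: expected 'label ddG', got %d field(s)",
                     f, i, length(fields)), call. = FALSE)
      m <- regmatches(fields[1L], regexec(labRe, fields[1L]))[[1L]]
      if (length(m) != 5L)
        stop(sprintf("%s line %d: cannot parse mutation label '%s'",
                     f, i, fields[1L]), call. = FALSE)
      ref1 <- if (nchar(m[2L]) == 3L) AA_THREE_TO_ONE[[m[2L]]] else m[2L]
      if (is.null(ref1) || is.na(ref1))
        stop(sprintf("%s line %d: unknown amino acid code '%s'", f, i, m[2L]),
             call. = FALSE)
      ddg <- suppressWarnings(as.numeric(fields[2L]))
      if (is.na(ddg))
        stop(sprintf("%s line %d: non-numeric ddG '%s'", f, i, fields[2L]),
             call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = m[3L], residue = as.integer(m[4L]) + as.integer(residueOffset),
        aa_ref = ref1, aa_alt = m[5L], ddg = ddg, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), residue = integer(),
               aa_ref = character(), aa_alt = character(), ddg = numeric(),
               stringsAsFactors = FALSE)
  key <- paste(tab$chain, tab$residue, tab$aa_ref, tab$aa_alt)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate mutation record(s); last value kept",
                    sum(dup)), call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  new("DdgTable", table = tab, sourceStructure = as.character(sourceStructure))
}

#' Write a DdgTable in PositionScan label dialect
#'
#' Writes one `<REF3><chain><resnum><alt>\tddG` record per substitution,
#' the dialect that [readFoldxPositionScan()] reads back.
#'
#' @param ddg a [DdgTable-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFoldxPositionScan <- function(ddg, file) {
  t <- ddg@table
  one2three <- toupper(Biostrings::AMINO_ACID_CODE)
  lines <- sprintf("%s%s%d%s\t%.8g",
                   one2three[t$aa_ref], t$chain, t$residue, t$aa_alt, t$ddg)
  writeLines(lines, file)
  invisible(file)
}

#' Is a mutation destabilising?
#'
#' A mutation is called destabilising when its folding free-energy change
#' strictly exceeds the threshold; the default 2 kcal/mol is the
#' conventional cut-off for highly destabilising mutations.
#'
#' @param ddg numeric ddG value(s), kcal/mol.
#' @param threshold kcal/mol (default 2).
#' @return logical; `NA` propagates (unscored entries stay unscored).
#' @examples
#' classifyDestabilising(c(1.9, 2.0, 3.49))
#' @export
classifyDestabilising <- function(ddg, threshold = 2.0) {
  stopifnot(is.numeric(ddg), length(threshold) == 1L, is.finite(threshold))
  ddg > threshold
}

#' Residue-set membership
#'
#' @param residueNumber residue number(s).
#' @param set a [ResidueSet-class] (or plain numeric vector).
#' @return logical vector.
#' @examples
#' sets <- notchResidueSets()
#' inResidueSet(455, sets$notch1_calcium)
#' @export
inResidueSet <- function(residueNumber, set) {
  res <- if (is(set, "ResidueSet")) set@residues else as.integer(set)
  as.integer(residueNumber) %in% res
}

#' Bundled NOTCH1/NOTCH2 EGF11-12 residue sets
#'
#' Ligand-binding interface residues and calcium-binding residues of the
#' EGF repeats 11-12 of human NOTCH1 and NOTCH2, as used throughout the
#' worked analyses. Shipped as a YAML fixture under `extdata/`.
#'
#' @return named list of [ResidueSet-class] objects:
#'   `notch1_interface`, `notch1_calcium`, `notch2_interface`,
#'   `notch2_calcium`.
#' @export
notchResidueSets <- function() {
  readResidueSets(system.file("extdata", "residue_sets_notch.yaml",
                              package = "SomaticSelect", mustWork = TRUE))
}

#' Minimum distance from a residue to the binding target
#'
#' Minimum Euclidean distance over all pairs of (residue heavy atom,
#' target atom), in ångström. Hydrogens are ignored.
#'
#' @param structure a [StructureModel-class].
#' @param residueNumber protein residue number (in the structure's
#'   numbering).
#' @param chain optional chain restriction for the residue.
#' @return distance in Å; an absent residue is a coverage error.
#' @examples
#' s <- simulateStructure(5, seed = 1, targetDistance = 5)
#' minDistanceToTarget(s, 1)
#' @export
minDistanceToTarget <- function(structure, residueNumber, chain = NULL) {
  a <- structure@atoms
  tgt <- a[a$isTarget, , drop = FALSE]
  if (nrow(tgt) == 0L)
    stop("structure has no target atoms", call. = FALSE)
  sel <- !a$isTarget & a$resno == as.integer(residueNumber)
  if (!is.null(chain)) sel <- sel & a$chain == chain
  res <- a[sel, , drop = FALSE]
  res <- dropHydrogens(res)
  tgtH <- dropHydrogens(tgt)
  if (nrow(tgtH)) tgt <- tgtH
  if (nrow(res) == 0L)
    stop(sprintf("residue %d absent from structure (unscored)",
                 as.integer(residueNumber)), call. = FALSE)
  d2 <- outer(res$x, tgt$x, "-")^2 + outer(res$y, tgt$y, "-")^2 +
    outer(res$z, tgt$z, "-")^2
  sqrt(min(d2))
}

dropHydrogens <- function(atoms) {
  el <- sub("^[0-9]+", "", toupper(atoms$elety))
  atoms[!startsWith(el, "H"), , drop = FALSE]
}

#' Is a residue within a distance cutoff of the target?
#'
#' Inclusive comparison: a residue exactly at the cutoff counts as
#' within it. The default 8 Å is the conventional functional-site
#' definition for DNA/substrate proximity.
#'
#' @inheritParams minDistanceToTarget
#' @param cutoff distance cutoff in Å (default 8).
#' @return logical.
#' @export
withinDistance <- function(structure, residueNumber, cutoff = 8.0,
                           chain = NULL) {
  minDistanceToTarget(structure, residueNumber, chain) <= cutoff
}

#' Attach structural feature columns to a catalogue
#'
#' Adds named feature columns to every catalogue entry: `ddg` (and its
#' Boolean `destabilising` classification) from a [DdgTable-class],
#' one Boolean membership column per supplied [ResidueSet-class], and
#' `dist_target` (with Boolean `near_target`) from a
#' [StructureModel-class]. Entries whose residue lacks coverage are left
#' `NA` (unscored) and a tally is reported; tests drop unscored entries
#' from both null and observed.
#'
#' @param catalogue an [SnvCatalogue-class].
#' @param ddg optional [DdgTable-class]; matched by (residue, aa_ref,
#'   aa_alt), amino-acid-level values copied onto every nucleotide-level
#'   entry.
#' @param residueSets optional named list of [ResidueSet-class] (or
#'   numeric vectors); column names are taken from the list names.
#' @param structure optional [StructureModel-class].
#' @param ddgThreshold threshold for the `destabilising` column
#'   (kcal/mol).
#' @param distanceCutoff cutoff for the `near_target` column (Å).
#' @return the catalogue with feature columns added.
#' @export
attachFeatures <- function(catalogue, ddg = NULL, residueSets = NULL,
                           structure = NULL, ddgThreshold = 2.0,
                           distanceCutoff = 8.0) {
  e <- catalogue@entries
  if (!is.null(ddg)) {
    t <- ddg@table
    key <- paste(t$residue, t$aa_ref, t$aa_alt)
    q <- paste(e$residue, e$aa_ref, e$aa_alt)
    idx <- match(q, key)
    e$ddg <- t$ddg[idx]
    e$destabilising <- classifyDestabilising(e$ddg, ddgThreshold)
    miss <- e$included & is.na(e$ddg) & e$consequence == "missense"
    if (any(miss))
      message(sprintf("%d included entr%s without ddG coverage (unscored)",
                      sum(miss), if (sum(miss) == 1L) "y" else "ies"))
  }
  if (!is.null(residueSets)) {
    if (is.null(names(residueSets)) || any(!nzchar(names(residueSets))))
      stop("residueSets must be a named list", call. = FALSE)
    for (nm in names(residueSets))
      e[[nm]] <- inResidueSet(e$residue, residueSets[[nm]])
  }
  if (!is.null(structure)) {
    res <- sort(unique(e$residue))
    d <- vapply(res, function(r) {
      tryCatch(minDistanceToTarget(structure, r), error = function(err) NA_real_)
    }, numeric(1))
    e$dist_target <- d[match(e$residue, res)]
    e$near_target <- e$dist_target <= distanceCutoff
    miss <- e$included & is.na(e$dist_target)
    if (any(miss))
      message(sprintf("%d included entr%s without structure coverage (unscored)",
                      sum(miss), if (sum(miss) == 1L) "y" else "ies"))
  }
  catalogue@entries <- e
  validObject(catalogue)
  catalogue
}

#' Read a PDB structure and declare its binding target
#'
#' Reads ATOM/HETATM records through `bio3d` and splits atoms into the
#' analysed protein and the binding target (by chain). Insertion codes
#' are rejected — renumber the structure first. Hydrogens are dropped.
#'
#' @param file PDB path.
#' @param targetChain chain identifier(s) of the binding partner.
#' @param proteinChain optional chain restriction for the protein; by
#'   default every non-target chain is kept.
#' @return A [StructureModel-class].
#' @export
readStructurePdb <- function(file, targetChain, proteinChain = NULL) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  a <- pdb$atom
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    stop("PDB contains insertion codes; renumber the structure first",
         call. = FALSE)
  atoms <- data.frame(
    chain = a$chain, resno = as.integer(a$resno), resid = a$resid,
    elety = a$elety, x = a$x, y = a$y, z = a$z,
    isTarget = a$chain %in% targetChain, stringsAsFactors = FALSE)
  if (!is.null(proteinChain))
    atoms <- atoms[atoms$isTarget | atoms$chain %in% proteinChain, ,
                   drop = FALSE]
  atoms <- dropHydrogens(atoms)
  if (!any(atoms$isTarget))
    stop(sprintf("no atoms found on target chain(s) %s",
                 paste(targetChain, collapse = ",")), call. = FALSE)
  new("StructureModel", atoms = atoms,
      targetSelection = sprintf("chain %s",
                                paste(targetChain, collapse = ",")))
}

#' Write a StructureModel as PDB
#'
#' @param structure a [StructureModel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeStructurePdb <- function(structure, file) {
  a <- structure@atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety)
  invisible(file)
}
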