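# Internal helpers: codon translation, channel keys, safe predicate
# evaluation over catalogue feature columns.

# standard codon table from Biostrings; stops are "*"
codonTable <- function() Biostrings::GENETIC_CODE

translateCodon <- function(codon) {
  gc <- codonTable()
  aa <- unname(gc[codon])
  aa[is.na(aa)] <- NA_character_
  aa
}

# canonical channel key "ctx5 ref ctx3 alt"; contexts strand-specific
channelKey <- function(ctx5, ref, ctx3, alt) {
  paste(ctx5, ref, ctx3, alt, sep = "")
}

contextKey <- function(ctx5, ref, ctx3) paste(ctx5, ref, ctx3, sep = "")

# all 192 channels in canonical order (A<C<G<T on every axis)
emptyChannelTable <- function() {
  g <- expand.grid(alt = DNA_BASES_, ctx3 = DNA_BASES_, ref = DNA_BASES_,
                   ctx5 = DNA_BASES_, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, c("ctx5", "ref", "ctx3", "alt")]
  g <- g[order(g$ctx5, g$ref, g$ctx3, g$alt), ]
  rownames(g) <- NULL
  g$context_count <- 0L
  g$mutation_count <- 0
  g$rate <- 0
  g
}

# predicate expressions over catalogue feature columns: comparisons,
# boolean operators, arithmetic and parentheses only
ALLOWED_PREDICATE_CALLS <- c(">", "<", ">=", "<=", "==", "!=",
                             "&", "|", "!", "(", "+", "-", "*", "/",
                             "&&", "||", "abs", "is.na")

checkPredicateAst <- function(ex) {
  if (is.call(ex)) {
    fn <- as.character(ex[[1L]])
    if (!fn %in% ALLOWED_PREDICATE_CALLS)
      stop(sprintf("disallowed function '%s' in predicate", fn), call. = FALSE)
    for (i in seq_along(ex)[-1L]) checkPredicateAst(ex[[i]])
  } else if (!(is.name(ex) || is.numeric(ex) || is.logical(ex))) {
    stop("predicate may contain only names, numbers and logicals",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate a predicate string on the entries data.frame. NA feature values
# evaluate to FALSE (an unscored entry never matches a predicate).
evalPredicate <- function(predicate, entries) {
  ex <- tryCatch(str2lang(predicate),
                 error = function(e) stop(sprintf(
                   "cannot parse predicate '%s': %s", predicate,
                   conditionMessage(e)), call. = FALSE))
  checkPredicateAst(ex)
  vars <- all.vars(ex)
  missing <- setdiff(vars, names(entries))
  if (length(missing))
    stop(sprintf("predicate '%s' references unknown feature column(s): %s",
                 predicate, paste(missing, collapse = ", ")), call. = FALSE)
  v <- eval(ex, envir = entries, enclos = baseenv())
  if (!is.logical(v))
    stop(sprintf("predicate '%s' does not evaluate to a logical", predicate),
         call. = FALSE)
  v <- rep_len(v, nrow(entries))
  v[is.na(v)] <- FALSE
  v
}

# named-stream seeding: derive independent child seeds (< 2^31) from one
# top-level seed so subcommands/operations are independently reproducible
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) *
             (31L^(seq_len(nchar(as.character(stream))) %% 7L)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
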