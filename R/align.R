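# Pairwise local alignment. This is the workhorse behind genome scanning,
# clustering and LTR-pair detection; Smith-Waterman semantics with affine
# gaps, scored +1 match / -1 mismatch / -5 gap open / -1 per gap position by
# default. N (and any IUPAC ambiguity code) matches nothing: it is always
# scored as a mismatch.

#' Alignment scoring scheme
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening penalty (negative; surcharge on top of the
#'   per-position extension cost).
#' @param gap_extend Per-gap-position extension penalty (negative).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -5, gap_extend = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal local alignment of two nucleotide strings
#'
#' Smith-Waterman local alignment with affine gap penalties. Identity is
#' computed as matches / aligned columns, with gap positions counted as
#' columns. When no positive-scoring cell exists the empty alignment (score 0,
#' width 0) is returned.
#'
#' @param a,b Nucleotide strings (A/C/G/T plus N and IUPAC ambiguity codes;
#'   anything else is an error).
#' @param scoring A [scoring_scheme()].
#' @param keep_alignment Also return the gapped alignment strings
#'   (`aligned_a`, `aligned_b`); off by default because their extraction
#'   dominates the runtime of high-volume callers.
#' @return A one-row tibble with 0-based half-open coordinates `a_start`,
#'   `a_end`, `b_start`, `b_end`, plus `score`, `identity`, `columns`,
#'   `matches` (and the alignment strings when requested).
#' @export
local_align <- function(a, b, scoring = scoring_scheme(), keep_alignment = FALSE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) abort("local_align requires non-empty sequences")
  a <- normalize_residues(a); b <- normalize_residues(b)
  check_nucleotides(c(a, b), "alignment input")
  mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(tibble(a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                  score = 0, identity = NA_real_, columns = 0L, matches = 0L,
                  aligned_a = "", aligned_b = ""))
  }
  ambiguous <- grepl("[^ACGT]", a) || grepl("[^ACGT]", b)
  if (!ambiguous && !keep_alignment) {
    # cheap accessors: with a pure-ACGT alphabet, Biostrings' match count
    # equals our matches-over-columns definition
    cols <- Biostrings::nchar(pa)
    matches <- Biostrings::nmatch(pa)
    al_a <- ""; al_b <- ""
  } else {
    al_a <- as.character(Biostrings::alignedPattern(pa))
    al_b <- as.character(Biostrings::alignedSubject(pa))
    ca <- chars(al_a); cb <- chars(al_b)
    matches <- sum(ca == cb & ca %in% c("A", "C", "G", "T"))
    cols <- length(ca)
    if (!keep_alignment) { al_a <- ""; al_b <- "" }
  }
  tibble(
    a_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    a_end = Biostrings::end(Biostrings::pattern(pa)),
    b_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
    b_end = Biostrings::end(Biostrings::subject(pa)),
    score = sc, identity = matches / cols,
    columns = as.integer(cols), matches = as.integer(matches),
    aligned_a = al_a, aligned_b = al_b
  )
}

# Global and overlap ("query-global") variants used by the consensus builder
# to map consensus coordinates onto member copies.
align_global <- function(a, b, scoring = scoring_scheme()) {
  mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
  Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
}

align_query_in_target <- function(query, target, scoring = scoring_scheme()) {
  mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    query, target, type = "global-local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  list(start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       end = Biostrings::end(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}
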