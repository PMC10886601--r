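# Shared low-level helpers. Coordinates are 0-based half-open everywhere in
# memory; conversion to 1-based inclusive happens only at the GFF3 boundary.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of nucleotide strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNRYSWKMBDHV]", x)
  if (any(bad)) {
    ch <- setdiff(unique(chars(gsub("[ACGTNRYSWKMBDHV]", "", paste(x[bad], collapse = "")))), "")
    abort(sprintf("%s contains non-nucleotide characters: %s",
                  what, paste(ch, collapse = ", ")))
  }
  invisible(x)
}

normalize_residues <- function(x) {
  toupper(chartr("u", "T", chartr("U", "T", x)))
}

# substitution matrix over the IUPAC alphabet: +match only for an exact
# A/C/G/T self-match; everything else (incl. N and ambiguity codes) scores
# as a mismatch, so N matches nothing. Cached per (match, mismatch).
.matrix_cache <- new.env(parent = emptyenv())
iupac_scoring_matrix <- function(match = 1, mismatch = -1) {
  key <- paste(match, mismatch)
  hit <- .matrix_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- matrix(mismatch, length(IUPAC_CHARS), length(IUPAC_CHARS),
              dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (b in c("A", "C", "G", "T")) m[b, b] <- match
  .matrix_cache[[key]] <- m
  m
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0-based half-open substring
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# statistical mode with deterministic tie-break (smallest value)
int_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_integer_)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}
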