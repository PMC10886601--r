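# RNA polymerase III internal promoter detection inside LTRs, and the
# TRIMp2 / TRIMp3 family classification that follows from it.
#
# Two promoter architectures are scanned: the type-2 (tRNA-gene) bipartite
# box A + box B promoter, and the type-1 (5S rRNA-gene) internal control
# region with box A, intermediate element (IE) and box C.

iupac_class <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# mismatches of an IUPAC pattern against seq chars at 0-based offset
iupac_mismatches <- function(seq_chars, pattern, offset) {
  pc <- chars(pattern)
  n <- length(pc)
  if (offset < 0 || offset + n > length(seq_chars)) return(NA_integer_)
  mm <- 0L
  for (k in seq_len(n)) {
    if (!seq_chars[offset + k] %in% iupac_class[[pc[k]]]) mm <- mm + 1L
  }
  mm
}

promoter_none <- function() {
  structure(list(promoter_type = "none", score = 0L), class = "promoter_annotation")
}

#' Scan an LTR for a tRNA-type (type 2) pol III promoter
#'
#' Box A is the bipartite motif `TRGCY` followed 2-8 nt later by `YGG`
#' (tolerating `max_boxA_mismatch` mismatches across both parts); box B is
#' the conserved `GGTTC` and must start 25-55 nt downstream of the box A
#' start, the spacing observed between the A and B blocks of tRNA genes.
#' The earliest qualifying pair wins.
#'
#' @param ltr_seq LTR nucleotide string (at least 40 nt to qualify).
#' @param max_boxA_mismatch Mismatch budget over both box A parts.
#' @param boxB_exact Whether box B must match `GGTTC` exactly.
#' @param spacing Allowed box A start to box B start distance (nt).
#' @param linker Allowed gap (nt) between the two box A parts.
#' @return A `promoter_annotation` with `promoter_type` `"tRNA_type2"` or
#'   `"none"`, box intervals (0-based half-open), matched strings and a
#'   `score` counting matched motif positions.
#' @export
scan_trna_promoter <- function(ltr_seq, max_boxA_mismatch = 1,
                               boxB_exact = TRUE, spacing = c(25, 55),
                               linker = c(2, 8)) {
  ltr_seq <- normalize_residues(ltr_seq)
  sc <- chars(ltr_seq)
  len <- length(sc)
  if (len < 40) return(promoter_none())
  part1 <- "TRGCY"; part2 <- "YGG"; boxB <- "GGTTC"
  max_b_mm <- if (boxB_exact) 0L else 1L
  for (a in 0:(len - 8)) {
    mm1 <- iupac_mismatches(sc, part1, a)
    if (is.na(mm1) || mm1 > max_boxA_mismatch) next
    for (g in linker[1]:linker[2]) {
      p2 <- a + 5L + g
      mm2 <- iupac_mismatches(sc, part2, p2)
      if (is.na(mm2) || mm1 + mm2 > max_boxA_mismatch) next
      for (b in (a + spacing[1]):(a + spacing[2])) {
        mmb <- iupac_mismatches(sc, boxB, b)
        if (is.na(mmb) || mmb > max_b_mm) next
        a_end <- p2 + 3L
        return(structure(list(
          promoter_type = "tRNA_type2",
          boxA = list(start = as.integer(a), end = as.integer(a_end),
                      seq = substr0(ltr_seq, a, a_end),
                      mismatches = mm1 + mm2),
          boxB = list(start = as.integer(b), end = as.integer(b + 5L),
                      seq = substr0(ltr_seq, b, b + 5L), mismatches = mmb),
          score = as.integer((8L - mm1 - mm2) + (5L - mmb))
        ), class = "promoter_annotation"))
      }
    }
  }
  promoter_none()
}

#' Scan an LTR for a 5S-type (type 1) pol III promoter
#'
#' The internal control region of 5S rRNA genes is modelled as three IUPAC
#' motifs in order -- box A, the intermediate element (IE) and box C -- with
#' the IE starting `gap_a_ie` nt after the box A end and box C starting
#' `gap_ie_c` nt after the IE end. Motif strings and spacings come from a
#' plain-text configuration (see [read_motif_config()]); the shipped default
#' was drawn from a synthetic canonical 5S rDNA internal control region. The
#' earliest qualifying triple wins.
#'
#' @param ltr_seq LTR nucleotide string (at least 60 nt to qualify).
#' @param motifs Motif configuration list, see [default_5s_motifs()].
#' @param max_mismatch_per_box Mismatch budget per motif.
#' @return A `promoter_annotation` with `promoter_type` `"fiveS_type1"` or
#'   `"none"`, intervals for `boxA`, `IE` and `boxC`, and a `score`.
#' @export
scan_5s_promoter <- function(ltr_seq, motifs = default_5s_motifs(),
                             max_mismatch_per_box = 1) {
  ltr_seq <- normalize_residues(ltr_seq)
  sc <- chars(ltr_seq)
  len <- length(sc)
  if (len < 60) return(promoter_none())
  la <- nchar(motifs$boxA); li <- nchar(motifs$ie); lc <- nchar(motifs$boxC)
  for (a in 0:(len - la)) {
    mma <- iupac_mismatches(sc, motifs$boxA, a)
    if (is.na(mma) || mma > max_mismatch_per_box) next
    a_end <- a + la
    for (i in (a_end + motifs$gap_a_ie[1]):(a_end + motifs$gap_a_ie[2])) {
      mmi <- iupac_mismatches(sc, motifs$ie, i)
      if (is.na(mmi) || mmi > max_mismatch_per_box) next
      i_end <- i + li
      for (cc in (i_end + motifs$gap_ie_c[1]):(i_end + motifs$gap_ie_c[2])) {
        mmc <- iupac_mismatches(sc, motifs$boxC, cc)
        if (is.na(mmc) || mmc > max_mismatch_per_box) next
        return(structure(list(
          promoter_type = "fiveS_type1",
          boxA = list(start = as.integer(a), end = as.integer(a_end),
                      seq = substr0(ltr_seq, a, a_end), mismatches = mma),
          IE = list(start = as.integer(i), end = as.integer(i_end),
                    seq = substr0(ltr_seq, i, i_end), mismatches = mmi),
          boxC = list(start = as.integer(cc), end = as.integer(cc + lc),
                      seq = substr0(ltr_seq, cc, cc + lc), mismatches = mmc),
          score = as.integer((la - mma) + (li - mmi) + (lc - mmc))
        ), class = "promoter_annotation"))
      }
    }
  }
  promoter_none()
}

#' Read a 5S promoter motif configuration
#'
#' Plain-text `key=value` format with IUPAC motif strings `boxA`, `ie`,
#' `boxC` and spacing ranges `gap_a_ie`, `gap_ie_c` written as `lo-hi`.
#'
#' @param path Path to a motif configuration file.
#' @return A list with elements `boxA`, `ie`, `boxC`, `gap_a_ie`, `gap_ie_c`.
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(map_chr(kv, ~ trimws(.x[2])), map_chr(kv, ~ trimws(.x[1])))
  parse_range <- function(x) as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  list(boxA = toupper(vals[["boxA"]]), ie = toupper(vals[["ie"]]),
       boxC = toupper(vals[["boxC"]]),
       gap_a_ie = parse_range(vals[["gap_a_ie"]]),
       gap_ie_c = parse_range(vals[["gap_ie_c"]]))
}

#' Default 5S promoter motifs
#'
#' Reads the configuration shipped at `inst/extdata/motifs_5s.txt`.
#'
#' @return See [read_motif_config()].
#' @export
default_5s_motifs <- function() {
  read_motif_config(system.file("extdata", "motifs_5s.txt", package = "trimscan"))
}

#' Classify a family as TRIMp2 / TRIMp3
#'
#' Both LTRs of a partitioned family are scanned for the two pol III
#' promoter architectures. A tRNA-type promoter in either LTR yields
#' `TRIMp3_tRNA`, a 5S-type promoter `TRIMp3_5S`; when both are found the
#' higher motif score wins and a tie is left `unclassified` with a warning.
#' Neither promoter yields the canonical class `TRIMp2`. Elements must be
#' shorter than 1000 bp for the TRIM label; lengths up to 1300 bp are
#' accepted with a `long_trim` flag, beyond that the family is left
#' unclassified.
#'
#' @param family A partitioned [trim_family].
#' @param motifs 5S motif configuration.
#' @return A list with `family_class`, `long_trim`, and `annotation` (the
#'   winning `promoter_annotation`, or the 5' LTR scan when none).
#' @export
classify_family <- function(family, motifs = default_5s_motifs()) {
  if (is.na(family$ltr_len)) {
    abort(sprintf("family %s is not partitioned; cannot classify", family$family_id))
  }
  p <- family_partition(family)
  ltrs <- c(substr0(family$consensus, p$ltr5[1], p$ltr5[2]),
            substr0(family$consensus, p$ltr3[1], p$ltr3[2]))
  trna_best <- promoter_none()
  fives_best <- promoter_none()
  for (ltr in ltrs) {
    t <- scan_trna_promoter(ltr)
    if (t$score > trna_best$score) trna_best <- t
    f <- scan_5s_promoter(ltr, motifs)
    if (f$score > fives_best$score) fives_best <- f
  }
  total_len <- nchar(family$consensus)
  long_trim <- total_len >= 1000 && total_len <= 1300
  if (total_len > 1300) {
    return(list(family_class = "unclassified", long_trim = FALSE,
                annotation = promoter_none()))
  }
  has_t <- trna_best$promoter_type == "tRNA_type2"
  has_f <- fives_best$promoter_type == "fiveS_type1"
  if (has_t && has_f) {
    if (trna_best$score == fives_best$score) {
      warn(sprintf("family %s: tRNA-type and 5S-type promoter scores tie; left unclassified",
                   family$family_id))
      return(list(family_class = "unclassified", long_trim = long_trim,
                  annotation = trna_best))
    }
    if (trna_best$score > fives_best$score) has_f <- FALSE else has_t <- FALSE
  }
  cls <- if (has_t) "TRIMp3_tRNA" else if (has_f) "TRIMp3_5S" else "TRIMp2"
  list(family_class = cls, long_trim = long_trim,
       annotation = if (has_t) trna_best else if (has_f) fives_best else promoter_none())
}
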