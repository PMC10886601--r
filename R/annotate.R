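# Structural annotation of TRIM elements: the LTR pair, target-site
# duplication, primer-binding site (typed by tRNA complementarity), the
# polypurine tract, and solo LTRs.

#' Detect the LTR pair of an element sequence
#'
#' Finds the highest-scoring local alignment between a prefix window and a
#' suffix window of the sequence (each capped at the sequence midpoint, so a
#' terminal repeat is never aligned against itself), requires a minimum
#' aligned length and identity, and extends the boundaries outward while
#' columns continue to match exactly. The 5' LTR start defines the element
#' start and the 3' LTR end the element end.
#'
#' @param seq Nucleotide string (a consensus or element copy).
#' @param min_ltr Minimum aligned LTR length (bp).
#' @param max_ltr Maximum expected LTR length; the search windows are
#'   `window = max_ltr + 100` bp.
#' @param min_identity Minimum identity between the two LTR copies.
#' @param window Search window length at each end (overrides the default).
#' @param scoring A [scoring_scheme()].
#' @return `NULL` when no qualifying repeat exists, otherwise a list with
#'   0-based half-open intervals `ltr5`, `internal`, `ltr3` and the
#'   `ltr_identity` between the LTR copies.
#' @export
detect_ltr_pair <- function(seq, min_ltr = 80, max_ltr = 400,
                            min_identity = 0.8, window = max_ltr + 100,
                            scoring = scoring_scheme()) {
  seq <- normalize_residues(seq)
  len <- nchar(seq)
  if (len < 2 * min_ltr) return(NULL)
  half <- len %/% 2
  pre_end <- min(window, half)
  suf_start <- max(len - window, len - half)
  pre <- substr0(seq, 0, pre_end)
  suf <- substr0(seq, suf_start, len)
  al <- local_align(pre, suf, scoring)
  if (al$columns == 0) return(NULL)
  s5 <- al$a_start; e5 <- al$a_end
  s3 <- suf_start + al$b_start; e3 <- suf_start + al$b_end
  if (s3 < e5) return(NULL)
  matches <- al$matches; cols <- al$columns
  cs <- chars(seq)
  # extend both alignment edges outward over exactly matching columns
  while (s5 > 0 && s3 > e5 && cs[s5] == cs[s3] && cs[s5] %in% c("A", "C", "G", "T")) {
    s5 <- s5 - 1L; s3 <- s3 - 1L; matches <- matches + 1L; cols <- cols + 1L
  }
  while (e3 < len && e5 < s3 && cs[e5 + 1L] == cs[e3 + 1L] &&
         cs[e5 + 1L] %in% c("A", "C", "G", "T")) {
    e5 <- e5 + 1L; e3 <- e3 + 1L; matches <- matches + 1L; cols <- cols + 1L
  }
  if (cols < min_ltr) return(NULL)
  identity <- matches / cols
  if (identity < min_identity) return(NULL)
  list(ltr5 = c(as.integer(s5), as.integer(e5)),
       internal = c(as.integer(e5), as.integer(s3)),
       ltr3 = c(as.integer(s3), as.integer(e3)),
       ltr_identity = identity)
}

#' Detect a target-site duplication flanking an element
#'
#' Looks for the longest exact match of length `min_len` to `max_len`
#' between the suffix of the immediate left flank and the prefix of the
#' immediate right flank of the element interval.
#'
#' @param seq The sequence holding the element (genome record or extracted
#'   window).
#' @param start,end Element interval, 0-based half-open.
#' @param min_len,max_len TSD length range (default 4-6 bp).
#' @return `NULL` when no TSD is found (an empty list with attribute
#'   `reason = "flank"` when there is insufficient flanking sequence),
#'   otherwise `list(len, tsd)`. [tsd_found()] tests for a positive call.
#' @export
detect_tsd <- function(seq, start, end, min_len = 4, max_len = 6) {
  stopifnot(start <= end)
  len <- nchar(seq)
  if (start < max_len || len - end < max_len) {
    return(structure(list(), reason = "flank"))
  }
  for (l in max_len:min_len) {
    left <- substr0(seq, start - l, start)
    right <- substr0(seq, end, end + l)
    if (left == right && !grepl("[^ACGT]", left)) {
      return(list(len = as.integer(l), tsd = left))
    }
  }
  NULL
}

#' Test whether a [detect_tsd()] result is a positive call
#'
#' @param t A [detect_tsd()] return value.
#' @return `TRUE` for a found TSD.
#' @export
tsd_found <- function(t) {
  is.list(t) && length(t) > 0
}

#' Detect the primer-binding site by tRNA complementarity
#'
#' Searches the first `search_window` nt of the internal region for
#' complementarity to a tRNA library in two modes: (a) the reverse complement
#' of each mature tRNA 3' terminus, including the post-transcriptional CCA
#' (`three_prime_end` priming, the rule for most LTR retrotransposons), and
#' (b) the reverse complement of the anticodon-loop region of each spliced
#' tRNA (`anticodon_loop` priming by a 3'-truncated tRNA). The best call is
#' the longest complementary stretch with at most `max_mismatch` mismatches.
#'
#' @param internal_seq Internal-portion nucleotide string (at least 20 nt).
#' @param trna_library A tRNA table from [read_trna_library()] or
#'   [synthetic_trna_library()].
#' @param min_match Minimum complementary length (nt).
#' @param max_mismatch Maximum mismatches tolerated in the pairing.
#' @param search_window Length of the 5' internal region searched (nt).
#' @return `NULL` or a list with `trna_id`, `mode`, `start`, `end` (interval
#'   on the internal sequence), `length`, `mismatches`.
#' @export
detect_pbs <- function(internal_seq, trna_library, min_match = 8,
                       max_mismatch = 1, search_window = 50) {
  internal_seq <- normalize_residues(internal_seq)
  if (nchar(internal_seq) < 20) abort("internal sequence shorter than 20 nt")
  stopifnot(nrow(trna_library) >= 1)
  region <- substr0(internal_seq, 0, min(search_window, nchar(internal_seq)))
  rc <- chars(region)
  best <- NULL
  consider <- function(cand) {
    if (is.null(cand)) return()
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$mismatches < best$mismatches)) {
      best <<- cand
    }
  }
  for (i in seq_len(nrow(trna_library))) {
    consider(pbs_three_prime(rc, trna_library$mature[i], trna_library$id[i],
                             min_match, max_mismatch))
    consider(pbs_anticodon_loop(rc, trna_library$spliced[i], trna_library$id[i],
                                min_match, max_mismatch))
  }
  best
}

# complementarity to the mature tRNA 3' terminus (suffix including CCA).
# A stretch must begin and end on paired positions (a terminal mismatch is
# not part of the pairing), and every internal mismatch must be compensated
# by two additional paired positions beyond the minimum.
pbs_three_prime <- function(region_chars, mature, trna_id, min_match, max_mismatch) {
  lr <- length(region_chars)
  lm <- nchar(mature)
  target_full <- chars(revcomp(mature))
  for (m in min(lm, lr):min_match) {
    tg <- target_full[seq_len(m)]        # revcomp of the last m nt of mature
    for (pos in 0:(lr - m)) {
      seg <- region_chars[(pos + 1):(pos + m)]
      if (seg[1] != tg[1] || seg[m] != tg[m]) next
      mm <- sum(seg != tg)
      if (mm <= max_mismatch && m >= min_match + 2L * mm) {
        return(list(trna_id = trna_id, mode = "three_prime_end",
                    start = as.integer(pos), end = as.integer(pos + m),
                    length = as.integer(m), mismatches = as.integer(mm)))
      }
    }
  }
  NULL
}

# complementarity to the anticodon loop (9 nt window at conventional tRNA
# positions 32-40 of the spliced sequence), extended while exact
# complementarity continues on both sides
pbs_anticodon_loop <- function(region_chars, spliced, trna_id, min_match,
                               max_mismatch, loop = c(31L, 40L)) {
  ls <- nchar(spliced)
  if (ls < loop[2]) return(NULL)
  tfull <- chars(revcomp(spliced))
  # loop interval [31,40) on spliced maps to [ls-40, ls-31) on the revcomp
  cs <- ls - loop[2]; ce <- ls - loop[1]
  core <- tfull[(cs + 1):ce]
  m <- length(core)
  lr <- length(region_chars)
  if (lr < m) return(NULL)
  best <- NULL
  for (pos in 0:(lr - m)) {
    mm <- sum(region_chars[(pos + 1):(pos + m)] != core)
    if (mm > max_mismatch) next
    s <- pos; e <- pos + m
    ts <- cs; te <- ce
    while (s > 0 && ts > 0 && region_chars[s] == tfull[ts]) {
      s <- s - 1L; ts <- ts - 1L
    }
    while (e < lr && te < ls && region_chars[e + 1L] == tfull[te + 1L]) {
      e <- e + 1L; te <- te + 1L
    }
    len <- e - s
    if (len < min_match + 2L * mm) next
    cand <- list(trna_id = trna_id, mode = "anticodon_loop",
                 start = as.integer(s), end = as.integer(e),
                 length = as.integer(len), mismatches = as.integer(mm))
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$mismatches < best$mismatches)) {
      best <- cand
    }
  }
  best
}

#' Detect the polypurine tract
#'
#' Finds the right-most window of at least `window` nt with purine (A/G)
#' fraction at least `min_purine_frac` that ends within `max_gap_to_ltr` nt
#' of the internal/3' LTR junction, extended maximally leftward while the
#' purine fraction holds.
#'
#' @param internal_seq Internal-portion nucleotide string.
#' @param window Minimum PPT length (nt).
#' @param min_purine_frac Minimum purine fraction.
#' @param max_gap_to_ltr Maximum distance (nt) between the PPT end and the
#'   internal 3' end.
#' @return `NULL` or the 0-based half-open interval `c(start, end)` on the
#'   internal sequence.
#' @export
detect_ppt <- function(internal_seq, window = 10, min_purine_frac = 0.8,
                       max_gap_to_ltr = 5) {
  internal_seq <- normalize_residues(internal_seq)
  len <- nchar(internal_seq)
  if (len < window) return(NULL)
  pur <- chars(internal_seq) %in% c("A", "G")
  cum <- c(0, cumsum(pur))
  frac <- function(s, e) (cum[e + 1] - cum[s + 1]) / (e - s)
  for (e in len:max(window, len - max_gap_to_ltr)) {
    s <- e - window
    if (s < 0) break
    if (frac(s, e) < min_purine_frac) next
    while (s > 0 && frac(s - 1, e) >= min_purine_frac) s <- s - 1
    return(c(as.integer(s), as.integer(e)))
  }
  NULL
}

#' Identify solo LTRs among family hits
#'
#' A hit is called a solo LTR when it was found with the LTR consensus at
#' query coverage of at least `min_coverage`, no internal-portion hit of the
#' same family lies within `max_internal_dist` nt, and a single 4-6 bp
#' target-site duplication directly flanks the lone LTR. Because alignment
#' end points can wobble by a base or two, the hit boundaries are jittered
#' by up to 2 nt when testing for the TSD; the longest TSD at the smallest
#' jitter wins.
#'
#' @param hits Combined hit tibble for one family with a `part` column
#'   (`"ltr"` or `"internal"`), e.g. from [count_family_copies()].
#' @param family A partitioned [trim_family].
#' @param genome Sequence table holding the scanned genome.
#' @param min_coverage Minimum LTR-consensus coverage.
#' @param max_internal_dist Exclusion distance (nt) to the nearest internal
#'   hit.
#' @return Tibble of solo-LTR calls: `seq_id`, `start`, `end`, `strand`,
#'   `tsd_len`, `tsd`.
#' @export
find_solo_ltrs <- function(hits, family, genome, min_coverage = 0.9,
                           max_internal_dist = 50) {
  if (is.na(family$ltr_len)) {
    abort(sprintf("family %s is not partitioned; cannot call solo LTRs",
                  family$family_id))
  }
  ltr_hits <- filter(hits, .data$part == "ltr", .data$coverage >= min_coverage)
  int_hits <- filter(hits, .data$part == "internal")
  ltr_len <- family$ltr_len
  out <- list()
  for (i in seq_len(nrow(ltr_hits))) {
    h <- ltr_hits[i, ]
    near <- filter(int_hits, .data$seq_id == h$seq_id,
                   pmax(.data$start - h$end, h$start - .data$end) <= max_internal_dist)
    if (nrow(near) > 0) next
    res <- genome$residues[genome$id == h$seq_id]
    # local alignment trims mutated termini; q_start/q_end say how much of
    # the LTR consensus is missing on each side, giving the true boundaries
    if (h$strand == "+") {
      s0 <- h$start - h$q_start; e0 <- h$end + (ltr_len - h$q_end)
    } else {
      s0 <- h$start - (ltr_len - h$q_end); e0 <- h$end + h$q_start
    }
    best <- NULL
    want <- family$tsd_len
    for (ds in -6:6) {
      for (de in -6:6) {
        t <- detect_tsd(res, s0 + ds, e0 + de)
        if (!tsd_found(t)) next
        pen <- abs(ds) + abs(de)
        # prefer the family's known TSD length, then longer, then the
        # smallest boundary adjustment
        mw <- !is.na(want) && t$len == want
        take <- if (is.null(best)) TRUE else {
          bw <- !is.na(want) && best$len == want
          if (mw != bw) mw else if (t$len != best$len) t$len > best$len
          else pen < best$pen
        }
        if (take) {
          best <- list(len = t$len, tsd = t$tsd, pen = pen,
                       start = s0 + ds, end = e0 + de)
        }
      }
    }
    if (is.null(best)) next
    out[[length(out) + 1]] <- tibble(seq_id = h$seq_id, start = best$start,
                                     end = best$end, strand = h$strand,
                                     tsd_len = best$len, tsd = best$tsd)
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), tsd_len = integer(), tsd = character()))
  }
  bind_rows(out)
}

#' Full structural annotation of a partitioned family
#'
#' Runs PBS, PPT and pol III promoter detection on a partitioned family
#' consensus and classifies it (see [classify_family()]).
#'
#' @param family A partitioned [trim_family].
#' @param trna_library Optional tRNA table; when `NULL` the PBS call is
#'   skipped.
#' @param motifs 5S promoter motif configuration, see [read_motif_config()].
#' @return A `trim_annotation` list with the LTR/internal intervals,
#'   `ltr_identity`, `tsd_len`, `pbs`, `ppt`, `boxes` (promoter annotation of
#'   the 5' LTR), and `family_class`.
#' @export
annotate_family <- function(family, trna_library = NULL,
                            motifs = default_5s_motifs()) {
  p <- family_partition(family)
  parts <- family_parts(family)
  pbs <- NULL
  if (!is.null(trna_library) && nchar(parts$internal) >= 20) {
    pbs <- detect_pbs(parts$internal, trna_library)
  }
  ppt <- detect_ppt(parts$internal)
  cls <- classify_family(family, motifs = motifs)
  structure(
    list(family_id = family$family_id,
         ltr5 = p$ltr5, internal = p$internal, ltr3 = p$ltr3,
         ltr_identity = family$ltr_identity, tsd_len = family$tsd_len,
         pbs = pbs, ppt = ppt,
         boxes = cls$annotation, family_class = cls$family_class,
         long_trim = cls$long_trim),
    class = "trim_annotation"
  )
}

#' @export
print.trim_annotation <- function(x, ...) {
  cat(sprintf("<trim_annotation> %s (%s)\n", x$family_id, x$family_class))
  cat(sprintf("  LTR5 [%d,%d) internal [%d,%d) LTR3 [%d,%d)\n",
              x$ltr5[1], x$ltr5[2], x$internal[1], x$internal[2],
              x$ltr3[1], x$ltr3[2]))
  if (!is.null(x$pbs)) {
    cat(sprintf("  PBS: %s (%s), %d nt, %d mismatch(es)\n",
                x$pbs$trna_id, x$pbs$mode, x$pbs$length, x$pbs$mismatches))
  }
  if (!is.null(x$ppt)) cat(sprintf("  PPT: [%d,%d) on internal\n", x$ppt[1], x$ppt[2]))
  invisible(x)
}

#' @export
#' @method tidy trim_annotation
tidy.trim_annotation <- function(x, ...) {
  tibble(
    family_id = x$family_id,
    ltr_len = x$ltr5[2] - x$ltr5[1],
    internal_len = x$internal[2] - x$internal[1],
    ltr_identity = x$ltr_identity,
    tsd_len = x$tsd_len,
    pbs_trna = if (is.null(x$pbs)) NA_character_ else x$pbs$trna_id,
    pbs_mode = if (is.null(x$pbs)) NA_character_ else x$pbs$mode,
    ppt_found = !is.null(x$ppt),
    promoter_type = x$boxes$promoter_type,
    family_class = x$family_class,
    long_trim = x$long_trim
  )
}
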