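# Family consensus construction: center-star multiple alignment, the 50%
# majority rule, and the iterative flank-extension loop that walks a family
# consensus out to its element termini (LTR pair + TSD).

#' Center-star multiple sequence alignment
#'
#' The center is the member with the greatest total pairwise alignment score
#' against all other members; every other member is aligned to the center
#' globally and the pairwise gaps are merged into common columns.
#'
#' @param members Sequence table with columns `id`, `residues` (one or more
#'   rows).
#' @param scoring A [scoring_scheme()].
#' @param center Optional row index of a pre-chosen center (skips the
#'   all-pairs scoring step; used by the elongation loop, whose member set is
#'   stable across rounds).
#' @return A `trim_msa` tibble with columns `id` and `aligned` (equal-length
#'   gapped strings); the center row index is kept in attribute `center`.
#' @export
build_msa <- function(members, scoring = scoring_scheme(), center = NULL) {
  stopifnot(nrow(members) >= 1)
  n <- nrow(members)
  if (n == 1) {
    out <- tibble(id = members$id, aligned = members$residues)
    class(out) <- c("trim_msa", class(out))
    attr(out, "center") <- 1L
    return(out)
  }
  if (is.null(center)) {
    mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
    sc <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      s <- Biostrings::pairwiseAlignment(
        members$residues[(i + 1):n], members$residues[i],
        type = "local", substitutionMatrix = mat,
        gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
        scoreOnly = TRUE
      )
      sc[i, (i + 1):n] <- s; sc[(i + 1):n, i] <- s
    }
    center <- which.max(rowSums(sc))
  }
  cseq <- members$residues[center]
  lc <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  # per-alignment insertion profile: number of member bases between
  # consecutive center positions (slot k = before center base k+1, 0..lc)
  profiles <- vector("list", n)
  for (m in others) {
    pa <- align_global(cseq, members$residues[m], scoring)
    profiles[[m]] <- alignment_profile(pa, lc, members$residues[m])
  }
  max_ins <- integer(lc + 1)
  for (m in others) max_ins <- pmax(max_ins, profiles[[m]]$ins)
  pad <- function(piece, width) {
    if (width == 0) return(character(0))
    c(piece, rep("-", width - length(piece)))
  }
  rows <- vector("character", n)
  # assemble rows slot-by-slot in preallocated lists (2*lc+1 slots)
  cc <- chars(cseq)
  parts <- vector("list", 2L * lc + 1L)
  for (k in 0:lc) {
    parts[[2L * k + 1L]] <- rep("-", max_ins[k + 1L])
    if (k < lc) parts[[2L * k + 2L]] <- cc[k + 1L]
  }
  rows[center] <- paste(unlist(parts), collapse = "")
  for (m in others) {
    pr <- profiles[[m]]
    parts <- vector("list", 2L * lc + 1L)
    for (k in 0:lc) {
      parts[[2L * k + 1L]] <- pad(pr$pieces[[k + 1L]], max_ins[k + 1L])
      if (k < lc) parts[[2L * k + 2L]] <- pr$base[k + 1L]
    }
    rows[m] <- paste(unlist(parts), collapse = "")
  }
  out <- tibble(id = members$id, aligned = rows)
  class(out) <- c("trim_msa", class(out))
  attr(out, "center") <- as.integer(center)
  out
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column: if the gap frequency is at least `threshold` the column is
#' dropped; otherwise the most frequent base is emitted if its frequency
#' among non-gap characters is at least `threshold`, else `N`. Base ties are
#' broken in the fixed order A < C < G < T.
#'
#' @param msa A `trim_msa` (tibble with an `aligned` column of equal-length
#'   gapped strings).
#' @param threshold Majority threshold (default 0.5).
#' @return The consensus nucleotide string.
#' @export
majority_consensus <- function(msa, threshold = 0.5) {
  stopifnot(nrow(msa) >= 1)
  mat <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  base_order <- c("A", "C", "G", "T", "N", setdiff(IUPAC_CHARS, c("A", "C", "G", "T", "N")))
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac >= threshold) next
    bases <- col[col != "-"]
    tb <- table(factor(bases, levels = base_order))
    best <- names(tb)[which.max(tb)]   # which.max takes the first = fixed order
    out <- c(out, if (max(tb) / length(bases) >= threshold) best else "N")
  }
  paste(out, collapse = "")
}

# Decompose a global center-vs-member alignment into the center-coordinate
# profile used for gap merging: `base` holds the member character aligned to
# each center position ("-" where the member has a deletion), and
# `pieces[[k+1]]` the member bases inserted between center positions k and
# k+1 (slot 0 precedes the center). Works from the indel block ranges, which
# Biostrings reports in aligned-column coordinates, avoiding the costly
# construction of gapped alignment strings.
alignment_profile <- function(pa, lc, member_seq) {
  mi <- Biostrings::indel(pa)
  # Biostrings reports gap blocks with start = the position *following* the
  # block: center-row gaps ("deletion") in center coordinates, member-row
  # gaps ("insertion") in member coordinates
  dels <- unlist(Biostrings::deletion(mi))
  inss <- unlist(Biostrings::insertion(mi))
  del_p <- Biostrings::start(dels); del_w <- Biostrings::width(dels)
  ins_s <- Biostrings::start(inss); ins_w <- Biostrings::width(inss)
  mchars <- chars(member_seq)
  ls <- length(mchars)
  ins <- integer(lc + 1)
  pieces <- vector("list", lc + 1)
  base_char <- character(lc)
  # terminal gaps are not reported as indel blocks; the clipped
  # pattern/subject ranges carry them instead
  ps <- Biostrings::start(Biostrings::pattern(pa))
  pe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  p <- ps - 1L; s <- ss - 1L
  if (p > 0) base_char[1:p] <- "-"
  if (s > 0) {
    ins[p + 1L] <- s
    pieces[[p + 1L]] <- mchars[1:s]
  }
  di <- 1L; si <- 1L
  repeat {
    kd <- if (di <= length(del_p)) del_p[di] - 1L - p else NA_integer_
    ki <- if (si <= length(ins_s)) ins_s[si] - 1L - s else NA_integer_
    k <- suppressWarnings(min(kd, ki, na.rm = TRUE))
    if (is.infinite(k) || is.na(k)) break
    if (k > 0) {   # match/mismatch columns up to the next gap block
      base_char[(p + 1):(p + k)] <- mchars[(s + 1):(s + k)]
      p <- p + k; s <- s + k
    }
    if (!is.na(kd) && kd == k) {
      w <- del_w[di]
      ins[p + 1L] <- w
      pieces[[p + 1L]] <- mchars[(s + 1):(s + w)]
      s <- s + w
      di <- di + 1L
    } else {
      w <- ins_w[si]
      base_char[(p + 1):(p + w)] <- "-"
      p <- p + w
      si <- si + 1L
    }
  }
  if (p < pe) {
    k <- pe - p
    base_char[(p + 1):(p + k)] <- mchars[(s + 1):(s + k)]
    p <- p + k; s <- s + k
  }
  if (p < lc) base_char[(p + 1):lc] <- "-"
  if (s < se) {
    # residual aligned member bases (should not occur; guard for safety)
    s <- se
  }
  if (se < ls) {
    ins[pe + 1L] <- ins[pe + 1L] + (ls - se)
    pieces[[pe + 1L]] <- c(pieces[[pe + 1L]], mchars[(se + 1):ls])
  }
  list(ins = ins, pieces = pieces, base = base_char)
}

# Index of the member with the greatest total pairwise local alignment
# score against all others (the star center).
star_center <- function(seqs, scoring = scoring_scheme()) {
  n <- length(seqs)
  if (n == 1) return(1L)
  mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
  sc <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    s <- Biostrings::pairwiseAlignment(
      seqs[(i + 1):n], seqs[i], type = "local", substitutionMatrix = mat,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
      scoreOnly = TRUE
    )
    sc[i, (i + 1):n] <- s; sc[(i + 1):n, i] <- s
  }
  which.max(rowSums(sc))
}

# Extract a window around an interval, clipped to the sequence.
extract_window <- function(residues, start, end) {
  len <- nchar(residues)
  s <- max(0L, start); e <- min(len, end)
  list(seq = substr0(residues, s, e), offset = s)
}

#' Extend a family cluster to its element termini
#'
#' Implements the iterative elongation loop of repeat-library construction:
#' in each round the (up to `max_members` best) copies are re-extracted with
#' `flank` bp of genomic flanking sequence on both sides, re-aligned, a
#' majority-rule consensus is rebuilt, and an LTR pair plus target-site
#' duplications are sought. Element boundaries are refined by a small shift
#' search maximizing cross-copy TSD agreement, and the loop stops when the
#' per-copy element boundaries are stable (within 2 nt) across two
#' consecutive rounds. The final consensus is trimmed to the element
#' boundaries; TSDs, being target-derived, are excluded.
#'
#' @param cluster Hit tibble for one family (as from [scan_genome()]).
#' @param genome Sequence table holding the scanned genome.
#' @param flank Flank length (bp) re-extracted around each copy per round.
#' @param max_rounds Maximum number of elongation rounds.
#' @param max_members Maximum number of copies used per round (best scores).
#' @param family_id Name for the resulting family.
#' @param min_ltr,max_ltr,min_ltr_identity LTR-pair detection parameters,
#'   see [detect_ltr_pair()].
#' @param scoring A [scoring_scheme()].
#' @return A [trim_family]. When no termini are found within `max_rounds`
#'   the family is returned unpartitioned with `complete = FALSE` and a
#'   warning is raised.
#' @export
extend_to_termini <- function(cluster, genome, flank = 500, max_rounds = 10,
                              max_members = 10, family_id = cluster$family_id[1],
                              min_ltr = 80, max_ltr = 400,
                              min_ltr_identity = 0.8,
                              scoring = scoring_scheme()) {
  stopifnot(nrow(cluster) >= 1)
  cur <- select(cluster, "seq_id", "start", "end", "strand", "score")
  # solo LTRs and fragments in the cluster would dilute the element
  # consensus (their non-element context votes at element columns), so the
  # consensus is built from hits spanning most of the longest copy; solos
  # are called and counted downstream instead
  span <- cur$end - cur$start
  full <- span >= 0.5 * max(span)
  if (sum(full) >= 2) cur <- cur[full, ]
  # the input hit intervals are the round-0 boundary estimate, so a first
  # round that reproduces them (+-2 nt) already counts as stable
  prev_bounds <- head(arrange(cur, desc(.data$score)), max_members)
  cons <- NULL
  last_result <- NULL
  center_key <- NULL   # carry the center copy across rounds
  for (round in seq_len(max_rounds)) {
    cur <- head(arrange(cur, desc(.data$score)), max_members)
    ext <- extract_members(cur, genome, flank)
    center <- NULL
    if (!is.null(center_key)) {
      hit <- which(ext$seq_id == center_key$seq_id &
                     abs(ext$win_start - center_key$win_start) < 100)
      if (length(hit) > 0) center <- hit[1]
    }
    # the center (greatest total alignment score to all other members) is
    # scored on the unflanked copies: the flanks are target-derived and
    # non-homologous, so they only add noise to the comparison
    if (is.null(center)) {
      cores <- map_chr(seq_len(nrow(cur)), function(i) {
        res <- genome$residues[genome$id == cur$seq_id[i]]
        s <- substr0(res, cur$start[i], cur$end[i])
        if (cur$strand[i] == "-") revcomp(s) else s
      })
      center <- star_center(cores, scoring)
    }
    msa <- build_msa(tibble(id = ext$member_id, residues = ext$oriented),
                     scoring, center = center)
    center <- attr(msa, "center")
    center_key <- list(seq_id = ext$seq_id[center],
                       win_start = ext$win_start[center])
    cons <- majority_consensus(msa)
    # polish: realign members against the consensus itself, whose coordinate
    # system is free of the center copy's private indels; this restores
    # bases that inconsistent gap placement around center deletions would
    # otherwise spread over sub-majority columns
    pm <- build_msa(tibble(id = c(".ref", ext$member_id),
                           residues = c(cons, ext$oriented)),
                    scoring, center = 1L)
    cons <- majority_consensus(pm[-1, ])
    # the element sits `flank` inside the extracted windows, so the LTR
    # search window must span the flank plus the expected LTR
    lp <- detect_ltr_pair(cons, min_ltr = min_ltr, max_ltr = max_ltr,
                          min_identity = min_ltr_identity,
                          window = flank + max_ltr + 100, scoring = scoring)
    if (is.null(lp)) {
      # the member set only changes when termini are found, so a failed
      # detection would repeat identically in every further round
      last_result <- NULL
      break
    }
    ref <- refine_element(cons, lp, ext, scoring)
    last_result <- ref
    bounds <- ref$copies
    if (!is.null(prev_bounds) && nrow(bounds) == nrow(prev_bounds)) {
      a <- arrange(bounds, .data$seq_id, .data$start)
      b <- arrange(prev_bounds, .data$seq_id, .data$start)
      stable <- all(a$seq_id == b$seq_id) &&
        all(abs(a$start - b$start) <= 2) && all(abs(a$end - b$end) <= 2)
      if (stable) break
    }
    prev_bounds <- bounds
    cur <- select(bounds, "seq_id", "start", "end", "strand", "score")
  }
  if (is.null(last_result)) {
    warn(sprintf("family %s: no element termini found; returning unpartitioned consensus",
                 family_id))
    return(trim_family(family_id = family_id, consensus = cons, complete = FALSE))
  }
  # final polish: rebuild the consensus directly from the refined per-copy
  # element intervals (tight flanks), so edge wander of the windowed LTR
  # alignment cannot truncate or pad the consensus termini, then re-map the
  # copies once against that edge-exact consensus
  cur2 <- select(last_result$copies, "seq_id", "start", "end", "strand", "score")
  ext2 <- extract_members(cur2, genome, flank = 50)
  msa2 <- build_msa(tibble(id = ext2$member_id, residues = ext2$oriented),
                    scoring, center = star_center(ext2$oriented, scoring))
  cons2 <- majority_consensus(msa2)
  # polish to a fixpoint: realigning members against the consensus removes
  # the center copy's private indel artifacts; iterate until stable
  for (pp in 1:3) {
    pm2 <- build_msa(tibble(id = c(".ref", ext2$member_id),
                            residues = c(cons2, ext2$oriented)),
                     scoring, center = 1L)
    cons_new <- majority_consensus(pm2[-1, ])
    stable <- identical(cons_new, cons2)
    cons2 <- cons_new
    if (stable) break
  }
  lp2a <- detect_ltr_pair(cons2, min_ltr = min_ltr, max_ltr = max_ltr,
                          min_identity = min_ltr_identity,
                          window = 50 + max_ltr + 100, scoring = scoring)
  if (!is.null(lp2a)) {
    last_result <- refine_element(cons2, lp2a, ext2, scoring)
  }
  fam_cons <- last_result$consensus
  lp2 <- detect_ltr_pair(fam_cons, min_ltr = min_ltr, max_ltr = max_ltr,
                         min_identity = min_ltr_identity, scoring = scoring)
  ltr_len <- if (!is.null(lp2)) lp2$ltr5[2] - lp2$ltr5[1] else NA_integer_
  ltr_id <- if (!is.null(lp2)) lp2$ltr_identity else NA_real_
  trim_family(
    family_id = family_id, consensus = fam_cons, ltr_len = ltr_len,
    ltr_identity = ltr_id,
    tsd_len = int_mode(last_result$copies$tsd_len),
    copies = last_result$copies,
    complete = !is.null(lp2)
  )
}

# Extract flanked, strand-oriented copies for one round.
extract_members <- function(cur, genome, flank) {
  out <- list(member_id = character(0), oriented = character(0),
              seq_id = character(0), win_start = integer(0),
              win_end = integer(0), strand = character(0),
              window = character(0), score = double(0))
  for (i in seq_len(nrow(cur))) {
    res <- genome$residues[genome$id == cur$seq_id[i]]
    w <- extract_window(res, cur$start[i] - flank, cur$end[i] + flank)
    oriented <- if (cur$strand[i] == "-") revcomp(w$seq) else w$seq
    out$member_id <- c(out$member_id, sprintf("m%02d", i))
    out$oriented <- c(out$oriented, oriented)
    out$seq_id <- c(out$seq_id, cur$seq_id[i])
    out$win_start <- c(out$win_start, w$offset)
    out$win_end <- c(out$win_end, w$offset + nchar(w$seq))
    out$strand <- c(out$strand, cur$strand[i])
    out$window <- c(out$window, w$seq)
    out$score <- c(out$score, cur$score[i])
  }
  out
}


# All TSD lengths (4-6) that match exactly at a fixed element boundary.
tsd_all_lengths <- function(seq, start, end, min_len = 4, max_len = 6) {
  len <- nchar(seq)
  if (start < max_len || len - end < max_len || start > end) return(list())
  out <- list()
  for (l in max_len:min_len) {
    left <- substr0(seq, start - l, start)
    right <- substr0(seq, end, end + l)
    if (left == right && !grepl("[^ACGT]", left)) {
      out[[length(out) + 1]] <- list(len = as.integer(l), tsd = left)
    }
  }
  out
}

# Given an LTR-pair call on the (flanked) consensus, map element boundaries
# onto each member and refine them per copy by a small shift search
# maximizing the flanking TSD (longest TSD at the smallest shift wins; a
# mis-placed boundary can only truncate the true TSD, never lengthen it).
# The family TSD length is the mode across well-mapped copies, and the
# consensus trim follows the modal shift of the agreeing copies.
refine_element <- function(cons, lp, ext, scoring, max_shift = 8) {
  es <- lp$ltr5[1]; ee <- lp$ltr3[2]
  elem <- substr0(cons, es, ee)
  n <- length(ext$member_id)
  loc <- vector("list", n)
  for (i in seq_len(n)) {
    loc[[i]] <- align_query_in_target(elem, ext$oriented[i], scoring)
  }
  map_score <- map_dbl(loc, "score")
  good_map <- map_score >= 0.5 * max(map_score)   # fragments/solos map poorly
  # per copy and per TSD length, the smallest-shift cell producing that length
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    byl <- list()
    for (ds in -max_shift:max_shift) {
      for (de in -max_shift:max_shift) {
        # record every matching length at this boundary (nested prefixes):
        # a chance one-base extension must not mask the true length
        for (t in tsd_all_lengths(ext$oriented[i], loc[[i]]$start + ds,
                                  loc[[i]]$end + de)) {
          pen <- abs(ds) + abs(de)
          key <- as.character(t$len)
          b <- byl[[key]]
          if (is.null(b) || pen < b$pen) {
            byl[[key]] <- list(len = t$len, tsd = t$tsd, ds = ds, de = de, pen = pen)
          }
        }
      }
    }
    cand[[i]] <- byl
  }
  # family TSD length: the length supported by the most well-mapped copies;
  # ties go to the longer length. A boundary shifted into the element
  # truncates every copy's TSD identically (full support, shorter), while a
  # chance one-base extension appears only in the ~1/4 of copies whose
  # element edge base matches the flank, so the true length wins both ways.
  support <- vapply(4:6, function(L) {
    sum(vapply(which(good_map), function(i) {
      !is.null(cand[[i]][[as.character(L)]])
    }, logical(1)))
  }, integer(1))
  mode_len <- if (all(support == 0)) NA_integer_ else {
    ls <- 4:6
    best_sup <- max(support)
    as.integer(max(ls[support == best_sup]))
  }
  key <- as.character(mode_len)
  agree <- vapply(seq_len(n), function(i) {
    good_map[i] && !is.na(mode_len) && !is.null(cand[[i]][[key]])
  }, logical(1))
  modal_ds <- int_mode(map_int(which(agree), ~ cand[[.x]][[key]]$ds))
  modal_de <- int_mode(map_int(which(agree), ~ cand[[.x]][[key]]$de))
  if (is.na(modal_ds)) modal_ds <- 0L
  if (is.na(modal_de)) modal_de <- 0L
  # terminal-agreement rescue: when the element edge bases coincide with
  # the background beyond the TSD, a shifted boundary carries an equally
  # valid TSD of the same length; only the true cell's terminal bases match
  # the consensus termini, so cells of the modal length are re-ranked by
  # agreement of their first/last 6 bases with the element consensus
  el_chars <- chars(elem)
  le <- length(el_chars)
  term_score <- function(mch, ms, me) {
    k <- 6L
    if (ms < 0 || me > length(mch) || me - ms < 2 * k) return(0L)
    sum(mch[(ms + 1):(ms + k)] == el_chars[1:k]) +
      sum(mch[(me - k + 1):me] == el_chars[(le - k + 1):le])
  }
  if (!is.na(mode_len)) {
    for (i in seq_len(n)) {
      if (!agree[i]) next
      mch <- chars(ext$oriented[i])
      best_cell <- NULL
      for (ds in -max_shift:max_shift) {
        for (de in -max_shift:max_shift) {
          ms <- loc[[i]]$start + ds; me <- loc[[i]]$end + de
          hit <- FALSE
          for (t in tsd_all_lengths(ext$oriented[i], ms, me)) {
            if (t$len == mode_len) { hit <- TRUE; tt <- t }
          }
          if (!hit) next
          cell <- list(len = mode_len, tsd = tt$tsd, ds = ds, de = de,
                       pen = abs(ds) + abs(de),
                       term = term_score(mch, ms, me))
          if (is.null(best_cell) || cell$term > best_cell$term ||
              (cell$term == best_cell$term && cell$pen < best_cell$pen)) {
            best_cell <- cell
          }
        }
      }
      if (!is.null(best_cell)) cand[[i]][[key]] <- best_cell
    }
    modal_ds <- int_mode(map_int(which(agree), ~ cand[[.x]][[key]]$ds))
    modal_de <- int_mode(map_int(which(agree), ~ cand[[.x]][[key]]$de))
    if (is.na(modal_ds)) modal_ds <- 0L
    if (is.na(modal_de)) modal_de <- 0L
  }
  copies <- vector("list", n)
  for (i in seq_len(n)) {
    if (agree[i]) {
      b <- cand[[i]][[key]]
      ms <- loc[[i]]$start + b$ds; me <- loc[[i]]$end + b$de
      tlen <- b$len; tseq <- b$tsd
    } else {
      ms <- loc[[i]]$start + modal_ds; me <- loc[[i]]$end + modal_de
      tlen <- NA_integer_; tseq <- NA_character_
    }
    # member-local (oriented) -> genome plus-strand coordinates
    if (ext$strand[i] == "+") {
      gs <- ext$win_start[i] + ms; ge <- ext$win_start[i] + me
    } else {
      gs <- ext$win_end[i] - me; ge <- ext$win_end[i] - ms
    }
    copies[[i]] <- tibble(
      seq_id = ext$seq_id[i], start = as.integer(gs), end = as.integer(ge),
      strand = ext$strand[i], score = loc[[i]]$score,
      tsd_len = tlen, tsd = tseq
    )
  }
  list(consensus = substr0(cons, es + modal_ds, ee + modal_de),
       copies = bind_rows(copies))
}
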