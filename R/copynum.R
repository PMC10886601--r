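# Full-length copy counting: a hit counts as full length when its aligned
# length exceeds 90% of the respective consensus AND its identity exceeds
# 90% (both strict). LTR and internal portions are counted independently.

#' Count full-length LTR and internal copies
#'
#' @param hits Combined hit tibble for one family with a `part` column
#'   (`"ltr"` / `"internal"`), e.g. from [count_family_copies()] or built
#'   manually.
#' @param family A partitioned [trim_family].
#' @param length_frac Aligned length must exceed this fraction of the
#'   respective consensus (strict).
#' @param identity_min Identity must exceed this value (strict).
#' @param solo Optional solo-LTR call tibble (from [find_solo_ltrs()]); its
#'   row count is reported as `solo_ltr`.
#' @return One-row tibble: `family_id`, `ltr_full`, `internal_full`,
#'   `solo_ltr`, `length_frac`, `identity_min`.
#' @export
count_full_length <- function(hits, family, length_frac = 0.9,
                              identity_min = 0.9, solo = NULL) {
  if (is.na(family$ltr_len)) {
    abort(sprintf("family %s is not partitioned; cannot count full-length copies",
                  family$family_id))
  }
  parts <- family_parts(family)
  count_part <- function(part_name, cons_len) {
    h <- filter(hits, .data$part == part_name)
    if (nrow(h) == 0) return(0L)
    alen <- (h$q_end - h$q_start)
    sum(alen > length_frac * cons_len & h$identity > identity_min)
  }
  tibble(
    family_id = family$family_id,
    ltr_full = count_part("ltr", nchar(parts$ltr)),
    internal_full = count_part("internal", nchar(parts$internal)),
    solo_ltr = if (is.null(solo)) NA_integer_ else nrow(solo),
    length_frac = length_frac,
    identity_min = identity_min
  )
}

#' Scan a genome with the LTR and internal consensus of a family
#'
#' Convenience wrapper used by the counting and solo-LTR stages: scans the
#' genome separately with the family's LTR consensus and internal consensus
#' and returns the combined hit table with a `part` column.
#'
#' @param genome Sequence table.
#' @param family A partitioned [trim_family].
#' @param min_identity,min_length,seed_k,scoring Passed to [scan_genome()].
#' @param regions Optional tibble (`seq_id`, `start`, `end`) restricting the
#'   scan to candidate neighbourhoods (e.g. the full-consensus hits from the
#'   discovery scan, which contain every region similar to any part of the
#'   consensus); coordinates of the returned hits are genomic either way.
#' @return Hit tibble with an added `part` column.
#' @export
count_family_copies <- function(genome, family, min_identity = 0.6,
                                min_length = 30, seed_k = 11,
                                scoring = scoring_scheme(), regions = NULL) {
  parts <- family_parts(family)
  target <- genome
  offsets <- NULL
  if (!is.null(regions) && nrow(regions) > 0) {
    pad <- nchar(family$consensus) + 200L
    merged <- merge_regions(regions, pad)
    target <- tibble(
      id = sprintf("w%03d", seq_len(nrow(merged))),
      residues = map_chr(seq_len(nrow(merged)), function(i) {
        res <- genome$residues[genome$id == merged$seq_id[i]]
        substr0(res, max(0L, merged$start[i]),
                min(nchar(res), merged$end[i]))
      }),
      description = ""
    )
    offsets <- mutate(merged, win_id = target$id,
                      start = pmax(0L, .data$start))
  }
  ltr_hits <- scan_genome(target, setNames(parts$ltr, family$family_id),
                          min_identity, min_length, seed_k, scoring)
  int_hits <- scan_genome(target, setNames(parts$internal, family$family_id),
                          min_identity, min_length,
                          min(seed_k, nchar(parts$internal)), scoring)
  hits <- bind_rows(mutate(ltr_hits, part = "ltr"),
                    mutate(int_hits, part = "internal"))
  if (!is.null(offsets) && nrow(hits) > 0) {
    m <- match(hits$seq_id, offsets$win_id)
    hits <- mutate(hits,
                   start = .data$start + offsets$start[m],
                   end = .data$end + offsets$start[m],
                   seq_id = offsets$seq_id[m])
  }
  arrange(hits, .data$seq_id, .data$start)
}

# merge overlapping/nearby intervals after padding
merge_regions <- function(regions, pad) {
  r <- arrange(mutate(regions, start = .data$start - pad, end = .data$end + pad),
               .data$seq_id, .data$start)
  out <- r[0, ]
  for (i in seq_len(nrow(r))) {
    k <- nrow(out)
    if (k > 0 && out$seq_id[k] == r$seq_id[i] && r$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], r$end[i])
    } else {
      out <- bind_rows(out, r[i, c("seq_id", "start", "end")])
    }
  }
  out
}
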