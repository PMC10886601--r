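# Seeded genome scanning (k-mer seeds + Smith-Waterman verification) and
# single-linkage family clustering at the 75% coverage / 75% identity
# thresholds used to delimit repeat families.

#' Scan a genome for copies of a repeat family
#'
#' Seed-and-extend search: exact k-mer seeds of the query consensus are
#' located with a precompiled dictionary, chained into candidate regions, and
#' each candidate is verified by Smith-Waterman local alignment. Both strands
#' are searched; minus-strand hits are reported in plus-strand genome
#' coordinates with `strand = "-"`. Overlapping hits of the same family are
#' merged when they overlap more than 50% reciprocally (the higher-scoring
#' hit is kept).
#'
#' @param genome Sequence table (as from [read_fasta()]); may hold several
#'   records.
#' @param family A [trim_family], or a single named character string to scan
#'   with a bare consensus (e.g. an LTR-only query).
#' @param min_identity Minimum alignment identity to report a hit.
#' @param min_length Minimum aligned query length (bp) to report a hit.
#' @param seed_k Seed k-mer size; must not exceed the consensus length.
#' @param scoring A [scoring_scheme()].
#' @param .cache Optional environment reusing per-record target conversions
#'   across scans of the same genome (internal use by the pipeline).
#' @return A hit tibble: `family_id`, `seq_id`, `start`, `end` (0-based
#'   half-open genome coordinates), `strand`, `identity`, `coverage` (aligned
#'   fraction of the query consensus), `score`, `q_start`, `q_end`, sorted by
#'   position.
#' @export
scan_genome <- function(genome, family, min_identity = 0.6, min_length = 30,
                        seed_k = 11, scoring = scoring_scheme(),
                        .cache = NULL) {
  if (inherits(family, "trim_family")) {
    fid <- family$family_id
    consensus <- family$consensus
  } else {
    stopifnot(is.character(family), length(family) == 1)
    fid <- names(family) %||% "query"
    consensus <- normalize_residues(unname(family))
  }
  lq <- nchar(consensus)
  if (seed_k > lq) abort(sprintf("seed_k (%d) exceeds consensus length (%d)", seed_k, lq))
  dict <- seed_dict(consensus, seed_k)
  hits <- purrr::pmap(genome, function(id, residues, ...) {
    scan_one_seq(id, residues, fid, consensus, min_identity, min_length,
                 dict, scoring, .cache = .cache)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) return(empty_hits())
  hits <- merge_hits(hits)
  arrange(hits, .data$seq_id, .data$start, .data$end)
}

empty_hits <- function() {
  tibble(family_id = character(), seq_id = character(), start = integer(),
         end = integer(), strand = character(), identity = double(),
         coverage = double(), score = double(), q_start = integer(),
         q_end = integer())
}

scan_one_seq <- function(seq_id, target, fid, consensus, min_identity,
                         min_length, dict, scoring, .cache = NULL) {
  lt <- nchar(target)
  out <- list()
  tl <- if (!is.null(.cache)) .cache[[seq_id]] else NULL
  if (is.null(tl)) {
    minus <- revcomp(target)
    tl <- list(chr = c("+" = target, "-" = minus),
               dna = list("+" = Biostrings::DNAString(target),
                          "-" = Biostrings::DNAString(minus)))
    if (!is.null(.cache)) .cache[[seq_id]] <- tl
  }
  for (strand in c("+", "-")) {
    tseq <- tl$chr[[strand]]
    cand <- seed_candidates(dict, tl$dna[[strand]])
    for (w in cand) {
      win <- substr0(tseq, w[1], w[2])
      al <- local_align(consensus, win, scoring)
      if (al$columns == 0) next
      qlen <- al$a_end - al$a_start
      if (qlen < min_length || al$identity < min_identity) next
      s <- w[1] + al$b_start
      e <- w[1] + al$b_end
      if (strand == "-") { tmp <- s; s <- lt - e; e <- lt - tmp }
      out[[length(out) + 1]] <- tibble(
        family_id = fid, seq_id = seq_id, start = as.integer(s),
        end = as.integer(e), strand = strand, identity = al$identity,
        coverage = qlen / nchar(consensus), score = al$score,
        q_start = al$a_start, q_end = al$a_end
      )
    }
  }
  bind_rows(out)
}

# Precompile the query k-mer dictionary once per scan (shared by strands).
seed_dict <- function(consensus, seed_k) {
  lq <- nchar(consensus)
  kpos <- 0:(lq - seed_k)                       # 0-based query offsets
  kmers <- substring(consensus, kpos + 1L, kpos + seed_k)
  ok <- !grepl("[^ACGT]", kmers)
  if (!any(ok)) return(NULL)
  kmers <- kmers[ok]; kpos <- kpos[ok]
  uk <- unique(kmers)
  list(pd = Biostrings::PDict(Biostrings::DNAStringSet(uk)),
       qpos_by_kmer = split(kpos, match(kmers, uk)),
       lq = lq, seed_k = seed_k)
}

# Chain exact seed matches into candidate target windows. Seeds are
# clustered on target position (a gap larger than the query length starts a
# new candidate); the window around each cluster is estimated from the seed
# diagonals (target position minus query position), and clusters with fewer
# than `min_seeds` seeds are discarded as chance matches of isolated k-mers.
seed_candidates <- function(dict, target, min_seeds = NULL) {
  if (is.null(dict)) return(list())
  lq <- dict$lq
  seed_k <- dict$seed_k
  if (is.character(target)) target <- Biostrings::DNAString(target)
  lt <- length(target)
  if (lt < seed_k) return(list())
  if (is.null(min_seeds)) min_seeds <- if (lq >= 100) 3L else 2L
  qpos_by_kmer <- dict$qpos_by_kmer
  mi <- Biostrings::matchPDict(dict$pd, target)
  starts <- Biostrings::startIndex(mi)
  nhit <- lengths(starts)
  if (sum(nhit) == 0) return(list())
  nq <- lengths(qpos_by_kmer)
  # expand all (query offset, target offset) seed pairs
  tpos <- rep(unlist(starts, use.names = FALSE) - 1L,
              times = rep(nq, nhit))
  qpos <- unlist(map2(qpos_by_kmer, nhit, ~ rep(.x, times = .y)),
                 use.names = FALSE)
  ord <- order(tpos)
  tpos <- tpos[ord]; qpos <- qpos[ord]
  brk <- c(0L, which(diff(tpos) > lq), length(tpos))
  out <- list()
  for (i in seq_len(length(brk) - 1)) {
    idx <- (brk[i] + 1):brk[i + 1]
    if (length(unique(tpos[idx])) < min_seeds) next
    diag <- tpos[idx] - qpos[idx]
    out[[length(out) + 1]] <- c(max(0L, min(diag) - 40L),
                                min(lt, max(diag) + lq + 40L))
  }
  out
}

# Merge same-family hits that overlap >50% reciprocally, keeping the best
# scoring one.
merge_hits <- function(hits) {
  hits <- arrange(hits, .data$seq_id, desc(.data$score))
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    for (j in (i + 1):nrow(hits)) {
      if (!keep[j] || hits$seq_id[j] != hits$seq_id[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      li <- hits$end[i] - hits$start[i]
      lj <- hits$end[j] - hits$start[j]
      if (ov > 0.5 * li && ov > 0.5 * lj) keep[j] <- FALSE
    }
  }
  hits[keep, ]
}

#' Cluster sequences into families at coverage/identity thresholds
#'
#' Single-linkage clustering under the predicate "the pairwise local alignment
#' covers at least `min_coverage` of the shorter sequence at identity at
#' least `min_identity`" (the convention of BLAST-style repeat-family
#' clustering at 75/75). The partition is invariant to input order; clusters
#' are numbered by decreasing size, ties broken by the length of the longest
#' member, then lexicographically by member ids.
#'
#' @param sequences Sequence table with columns `id`, `residues`.
#' @param min_coverage Minimum aligned fraction of the shorter sequence.
#' @param min_identity Minimum alignment identity.
#' @param scoring A [scoring_scheme()].
#' @return The input tibble with an integer `cluster` column added.
#' @export
cluster_hits <- function(sequences, min_coverage = 0.75, min_identity = 0.75,
                         scoring = scoring_scheme()) {
  stopifnot(nrow(sequences) >= 1)
  n <- nrow(sequences)
  ord <- order(sequences$id)
  seqs <- sequences[ord, ]
  edges <- integer(0)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  mat <- iupac_scoring_matrix(scoring$match, scoring$mismatch)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      # transitivity of single linkage: pairs already connected cannot
      # change the partition, so their alignment is skipped; remaining
      # partners of i are aligned in one vectorized call
      js <- ((i + 1):n)
      js <- js[vapply(js, function(j) find(j) != find(i), logical(1))]
      if (length(js) == 0) next
      # provable score screen: a pair meeting coverage c and identity y has
      # optimal local score >= (2y-1)*c*shorter + gap_open, so anything
      # below that bound cannot qualify and is dropped on a cheap
      # score-only pass
      sc_only <- Biostrings::pairwiseAlignment(
        seqs$residues[js], seqs$residues[i], type = "local",
        substitutionMatrix = mat, gapOpening = -scoring$gap_open,
        gapExtension = -scoring$gap_extend, scoreOnly = TRUE
      )
      shorter_js <- pmin(nchar(seqs$residues[js]), nchar(seqs$residues[i]))
      bound <- (2 * min_identity - 1) * min_coverage * shorter_js + scoring$gap_open
      js <- js[sc_only >= bound]
      if (length(js) == 0) next
      pa <- Biostrings::pairwiseAlignment(
        seqs$residues[js], seqs$residues[i], type = "local",
        substitutionMatrix = mat, gapOpening = -scoring$gap_open,
        gapExtension = -scoring$gap_extend
      )
      cols <- Biostrings::nchar(pa)
      ident <- ifelse(cols > 0, Biostrings::nmatch(pa) / cols, 0)
      wj <- Biostrings::width(Biostrings::pattern(pa))   # aligned span in j
      wi <- Biostrings::width(Biostrings::subject(pa))   # aligned span in i
      for (k in seq_along(js)) {
        j <- js[k]
        shorter <- min(nchar(seqs$residues[i]), nchar(seqs$residues[j]))
        alen <- if (nchar(seqs$residues[j]) <= nchar(seqs$residues[i])) wj[k] else wi[k]
        if (Biostrings::score(pa)[k] > 0 &&
            alen / shorter >= min_coverage && ident[k] >= min_identity) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) {
            edges <- c(edges, i, j)
            parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  longest <- map_dbl(split(nchar(seqs$residues), comp), max)
  sizes <- tabulate(comp)
  first_id <- map_chr(split(seqs$id, comp), ~ sort(.x)[1])
  rank <- order(-sizes, -longest, first_id)
  relabel <- match(seq_along(sizes), rank)
  seqs$cluster <- relabel[comp]
  seqs[match(sequences$id, seqs$id), ]
}

pair_linked <- function(a, b, min_coverage, min_identity, scoring) {
  al <- local_align(a, b, scoring)
  if (al$columns == 0) return(FALSE)
  shorter <- min(nchar(a), nchar(b))
  alen <- if (nchar(a) <= nchar(b)) al$a_end - al$a_start else al$b_end - al$b_start
  alen / shorter >= min_coverage && al$identity >= min_identity
}
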