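# Independent oracles used to validate the package's algorithmic kernels.
# They deliberately share no code with the implementation paths they check.

# Affine-gap Smith-Waterman best local score (Gotoh), pure R.
# Gap of length L costs gap_open + L * gap_extend (positive penalties).
oracle_sw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # best score ending at (i,j), local
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")) match else mismatch
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Per-column counting consensus (same published rule, independent code):
# drop column if gap fraction >= threshold; else most frequent base among
# non-gaps if its frequency >= threshold, else N; ties by A<C<G<T.
oracle_consensus <- function(rows, threshold = 0.5) {
  m <- do.call(rbind, strsplit(rows, ""))
  res <- c()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (sum(col == "-") / length(col) >= threshold) next
    bases <- col[col != "-"]
    lv <- c("A", "C", "G", "T", "N")
    counts <- vapply(lv, function(b) sum(bases == b), integer(1))
    top <- lv[which(counts == max(counts))][1]
    res <- c(res, if (counts[top] / length(bases) >= threshold) top else "N")
  }
  paste(res, collapse = "")
}

# Brute-force single-linkage partition over an explicit pairwise predicate.
oracle_single_linkage <- function(n, linked) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && linked[i, j] && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# the 75/75 predicate evaluated through local_align (a code path independent
# of cluster_hits' batched alignment)
oracle_pair_linked <- function(a, b, min_coverage = 0.75, min_identity = 0.75) {
  al <- trimscan::local_align(a, b)
  if (al$columns == 0) return(FALSE)
  shorter <- min(nchar(a), nchar(b))
  alen <- if (nchar(a) <= nchar(b)) al$a_end - al$a_start else al$b_end - al$b_start
  alen / shorter >= min_coverage && al$identity >= min_identity
}

# Sliding-window PPT oracle: right-most end within max_gap of the 3' edge
# whose trailing window passes the purine threshold, grown leftwards.
oracle_ppt <- function(seq, window = 10, min_frac = 0.8, max_gap = 5) {
  v <- strsplit(seq, "")[[1]] %in% c("A", "G")
  len <- length(v)
  if (len < window) return(NULL)
  for (e in len:max(window, len - max_gap)) {
    s <- e - window
    if (s < 0) next
    if (mean(v[(s + 1):e]) < min_frac) next
    while (s > 0 && mean(v[s:e]) >= min_frac) s <- s - 1
    return(c(s, e))
  }
  NULL
}

# random nucleotide string helper for tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# mutate a sequence by iid substitutions at rate p
mutate_subs <- function(seq, p) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
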