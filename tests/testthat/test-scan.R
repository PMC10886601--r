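make_test_genome <- function(copies, background_len = 20000, seed = 7) {
  # plant given sequences at fixed, well-separated positions
  set.seed(seed)
  bg <- rand_dna(background_len)
  gap <- floor(background_len / (length(copies) + 1))
  pieces <- character(0)
  pos <- integer(0)
  cursor <- 0
  for (i in seq_along(copies)) {
    p <- i * gap
    pieces <- c(pieces, substr(bg, cursor + 1, p), copies[[i]])
    pos <- c(pos, p + sum(nchar(head(copies, i - 1))))
    cursor <- p
  }
  pieces <- c(pieces, substr(bg, cursor + 1, background_len))
  list(genome = tibble::tibble(id = "chr1",
                               residues = paste(pieces, collapse = ""),
                               description = ""),
       starts = pos)
}

test_that("an exact planted copy is recovered with exact coordinates", {
  set.seed(11)
  fam <- rand_dna(400)
  g <- make_test_genome(list(fam))
  hits <- scan_genome(g$genome, c(fam1 = fam))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, g$starts[1])
  expect_equal(hits$end, g$starts[1] + 400L)
  expect_equal(hits$coverage, 1)
})

test_that("a reverse-strand copy is reported on the minus strand", {
  set.seed(12)
  fam <- rand_dna(350)
  g <- make_test_genome(list(revcomp(fam)))
  hits <- scan_genome(g$genome, c(fam1 = fam))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, g$starts[1])
  expect_equal(hits$end, g$starts[1] + 350L)
})

test_that("scanning a genome plus its reverse complement gives mirror hits", {
  set.seed(13)
  fam <- rand_dna(300)
  g <- make_test_genome(list(fam), background_len = 8000)
  res <- g$genome$residues
  both <- tibble::tibble(id = "pal", residues = paste0(res, revcomp(res)),
                         description = "")
  hits <- scan_genome(both, c(f = fam))
  expect_equal(nrow(hits), 2)
  L <- nchar(both$residues)
  h <- hits[order(hits$start), ]
  # mirror symmetry: the second hit is the reflection of the first
  expect_equal(h$start[1], L - h$end[2])
  expect_equal(h$end[1], L - h$start[2])
  expect_setequal(h$strand, c("+", "-"))
})

test_that("seed_k larger than the consensus errors", {
  expect_error(scan_genome(tibble::tibble(id = "c", residues = rand_dna(100),
                                          description = ""),
                           c(f = "ACGTT"), seed_k = 11), "seed_k")
})

test_that("divergent copies are recovered with oracle-matched identities", {
  tl <- synthetic_trna_library()
  spec <- family_spec("famX", ltr_len = 100, internal_len = 150,
                      promoter = "none", tsd_len = 5, copy_count = 60,
                      divergence = 0.05, indel_prob = 0, seed = 5)
  sim <- plant_elements(6e5, list(spec), seed = 17, trna_library = tl)
  anc <- sim$ancestors$residues[1]
  hits <- scan_genome(sim$genome, c(famX = anc))
  big <- hits[hits$coverage > 0.5, ]
  expect_gte(nrow(big), 59)   # >= 59/60 recovered
  # reported identity within 0.01 of realigning the true planted interval
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    h <- big[abs(big$start - tr$start) < 20, ]
    if (nrow(h) != 1) next
    copy <- substr(sim$genome$residues, tr$start + 1, tr$end)
    if (tr$strand == "-") copy <- revcomp(copy)
    expect_lt(abs(h$identity - local_align(anc, copy)$identity), 0.01)
  }
})

test_that("clustering: identical sequences form one cluster, disjoint sets two", {
  set.seed(21)
  s <- rand_dna(200)
  same <- tibble::tibble(id = paste0("s", 1:5), residues = rep(s, 5))
  cl <- cluster_hits(same)
  expect_equal(unique(cl$cluster), 1L)

  other <- rand_dna(200)
  two <- tibble::tibble(id = paste0("x", 1:6),
                        residues = c(rep(s, 3), rep(other, 3)))
  cl2 <- cluster_hits(two)
  expect_equal(length(unique(cl2$cluster)), 2)
  expect_equal(length(unique(cl2$cluster[1:3])), 1)
})

test_that("clustering matches the brute-force union-find oracle near 75%", {
  set.seed(22)
  base1 <- rand_dna(200)
  base2 <- rand_dna(200)
  seqs <- c(
    vapply(c(0.02, 0.08, 0.15, 0.2, 0.26, 0.3), function(p) mutate_subs(base1, p), ""),
    vapply(c(0.02, 0.1, 0.18, 0.24, 0.3, 0.35), function(p) mutate_subs(base2, p), ""),
    replicate(4, rand_dna(200))
  )
  tbl <- tibble::tibble(id = sprintf("q%02d", seq_along(seqs)), residues = seqs)
  got <- cluster_hits(tbl)
  linked <- matrix(FALSE, nrow(tbl), nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    for (j in seq_len(nrow(tbl))) {
      if (i < j) {
        linked[i, j] <- linked[j, i] <- oracle_pair_linked(seqs[i], seqs[j])
      }
    }
  }
  want <- oracle_single_linkage(nrow(tbl), linked)
  # compare as partitions (same co-membership relation)
  expect_equal(outer(got$cluster, got$cluster, "=="),
               outer(want, want, "=="))
})

test_that("clustering is invariant to input order", {
  set.seed(23)
  base <- rand_dna(150)
  seqs <- c(vapply(c(0.05, 0.1, 0.2), function(p) mutate_subs(base, p), ""),
            replicate(3, rand_dna(150)))
  tbl <- tibble::tibble(id = sprintf("q%d", 1:6), residues = seqs)
  a <- cluster_hits(tbl)
  perm <- c(4, 2, 6, 1, 3, 5)
  b <- cluster_hits(tbl[perm, ])
  ma <- outer(a$cluster, a$cluster, "==")
  mb <- outer(b$cluster[match(tbl$id, b$id)],
              b$cluster[match(tbl$id, b$id)], "==")
  expect_equal(ma, mb)
})
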