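test_that("center-star MSA of identical members is gapless; singleton works", {
  set.seed(31)
  s <- rand_dna(80)
  msa <- build_msa(tibble::tibble(id = paste0("m", 1:4), residues = rep(s, 4)))
  expect_true(all(msa$aligned == s))
  one <- build_msa(tibble::tibble(id = "m1", residues = s))
  expect_equal(one$aligned, s)
})

test_that("MSA columns stay homologous for lightly mutated members", {
  set.seed(32)
  anc <- rand_dna(120)
  members <- tibble::tibble(
    id = paste0("m", 1:5),
    residues = vapply(1:5, function(i) mutate_subs(anc, 3 / 120), "")
  )
  msa <- build_msa(members)
  cons <- majority_consensus(msa)
  expect_equal(cons, anc)   # <=3 substitutions per member cannot shift majority
})

test_that("majority rule: forced columns, ties and gap-majority columns", {
  msa1 <- tibble::tibble(id = as.character(1:5),
                         aligned = c("A", "A", "A", "C", "C"))
  expect_equal(majority_consensus(msa1), "A")
  msa2 <- tibble::tibble(id = as.character(1:4), aligned = c("A", "A", "C", "C"))
  expect_equal(majority_consensus(msa2), "A")   # tie -> fixed order A<C<G<T
  msa3 <- tibble::tibble(id = as.character(1:5),
                         aligned = c("-A", "-A", "-A", "AA", "AA"))
  expect_equal(majority_consensus(msa3), "A")   # first column dropped (gap 3/5)
  # sub-majority plurality -> N
  msa4 <- tibble::tibble(id = as.character(1:5),
                         aligned = c("A", "A", "C", "G", "T"))
  expect_equal(majority_consensus(msa4), "N")
})

test_that("majority consensus equals the per-column counting oracle", {
  set.seed(33)
  for (trial in 1:20) {
    rows <- vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T", "-"), 50, TRUE,
                   prob = c(.2, .2, .2, .2, .2)), collapse = "")
    }, "")
    msa <- tibble::tibble(id = as.character(1:10), aligned = rows)
    expect_equal(majority_consensus(msa), oracle_consensus(rows))
  }
})

test_that("consensus of n identical rows is that row; length bounded by columns", {
  set.seed(34)
  s <- rand_dna(60)
  for (n in c(1, 2, 5)) {
    msa <- tibble::tibble(id = as.character(1:n), aligned = rep(s, n))
    expect_equal(majority_consensus(msa), s)
  }
  rows <- c("AC-GT", "A-CGT", "ACC-T")
  msa <- tibble::tibble(id = as.character(1:3), aligned = rows)
  expect_lte(nchar(majority_consensus(msa)), 5)
})

test_that("noiseless elongation recovers the planted ancestor exactly", {
  tl <- synthetic_trna_library()
  spec <- family_spec("famN", ltr_len = 100, internal_len = 200,
                      promoter = "tRNA_type2", pbs_trna_id = "tRNA-Lys",
                      tsd_len = 5, copy_count = 10, divergence = 0,
                      indel_prob = 0, seed = 9)
  sim <- plant_elements(3e5, list(spec), seed = 19, trna_library = tl)
  hits <- scan_genome(sim$genome, c(famN = sim$ancestors$residues[1]))
  hits$family_id <- "famN"
  fam <- extend_to_termini(hits, sim$genome)
  expect_true(fam$complete)
  expect_equal(fam$consensus, sim$ancestors$residues[1])
  expect_equal(fam$ltr_len, 100L)
  expect_equal(fam$tsd_len, 5L)

  # idempotence: re-running on the recovered copies changes nothing
  again <- extend_to_termini(
    dplyr::mutate(fam$copies, family_id = "famN"), sim$genome)
  expect_equal(again$consensus, fam$consensus)
  expect_equal(again$ltr_len, fam$ltr_len)
})

test_that("elongation at 2% divergence stays within spec tolerances", {
  tl <- synthetic_trna_library()
  spec <- family_spec("famD", ltr_len = 120, internal_len = 250,
                      promoter = "none", tsd_len = 5, copy_count = 10,
                      divergence = 0.02, seed = 10)
  sim <- plant_elements(4e5, list(spec), seed = 29, trna_library = tl)
  hits <- scan_genome(sim$genome, c(famD = sim$ancestors$residues[1]))
  hits$family_id <- "famD"
  fam <- extend_to_termini(hits, sim$genome)
  expect_true(fam$complete)
  anc <- sim$ancestors$residues[1]
  al <- local_align(fam$consensus, anc)
  expect_gte(al$identity, 0.99)
  # per-copy boundaries within 2 nt of truth
  truth <- dplyr::arrange(sim$truth, start)
  got <- dplyr::arrange(fam$copies, start)
  m <- match(got$start, truth$start)   # may be NA if off by a little
  for (i in seq_len(nrow(got))) {
    tr <- truth[which.min(abs(truth$start - got$start[i])), ]
    expect_lte(abs(got$start[i] - tr$start), 2)
    expect_lte(abs(got$end[i] - tr$end), 2)
  }
})

test_that("a cluster with no terminal repeat is returned unpartitioned", {
  set.seed(36)
  frag <- rand_dna(300)   # no LTR structure at all
  g <- tibble::tibble(
    id = "chr1",
    residues = paste0(rand_dna(2000), frag, rand_dna(2000), frag, rand_dna(2000)),
    description = ""
  )
  hits <- scan_genome(g, c(frag = frag))
  hits$family_id <- "frag"
  expect_warning(fam <- extend_to_termini(hits, g), "termini")
  expect_false(fam$complete)
  expect_true(is.na(fam$ltr_len))
})

test_that("consensus recovery holds across repeated simulations", {
  tl <- synthetic_trna_library()
  ids <- c()
  tsd_ok <- 0
  for (k in 1:5) {
    spec <- family_spec("famR", ltr_len = 100, internal_len = 150,
                        promoter = "none", tsd_len = 4, copy_count = 10,
                        divergence = 0.02, seed = 100 + k)
    sim <- plant_elements(3e5, list(spec), seed = 200 + k, trna_library = tl)
    hits <- scan_genome(sim$genome, c(famR = sim$ancestors$residues[1]))
    hits$family_id <- "famR"
    fam <- suppressWarnings(extend_to_termini(hits, sim$genome))
    if (!fam$complete) next
    ids <- c(ids, local_align(fam$consensus, sim$ancestors$residues[1])$identity)
    if (identical(fam$tsd_len, 4L)) tsd_ok <- tsd_ok + 1
  }
  expect_gte(mean(ids), 0.99)
  expect_gte(tsd_ok, 4)
})
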