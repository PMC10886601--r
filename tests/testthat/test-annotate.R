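test_that("LTR pair boundaries are exact on constructed elements", {
  set.seed(51)
  for (L in c(80, 150, 400)) {
    for (I in c(50, 300, 700)) {
      ltr <- rand_dna(L)
      seq <- paste0(ltr, rand_dna(I), ltr)
      lp <- detect_ltr_pair(seq, min_ltr = 80, max_ltr = 400)
      expect_false(is.null(lp))
      expect_equal(lp$ltr5, c(0L, L))
      expect_equal(lp$internal, c(L, L + I))
      expect_equal(lp$ltr3, c(L + I, 2L * L + I))
      expect_equal(lp$ltr_identity, 1)
    }
  }
})

test_that("no LTR pair is called on random sequence", {
  set.seed(52)
  for (i in 1:5) expect_null(detect_ltr_pair(rand_dna(500)))
})

test_that("a planted family with the printed plant-TRIM dimensions annotates back", {
  # 120 bp LTRs around an 85 bp internal region, the smallest layout the
  # generator supports, mirroring a compact plant TRIM
  tl <- synthetic_trna_library()
  fam <- make_family(family_spec("compact", 120, 85, "tRNA_type2",
                                 pbs_trna_id = "tRNA-Lys", tsd_len = 5,
                                 seed = 3), tl)
  expect_equal(nchar(fam$element), 325)
  lp <- detect_ltr_pair(fam$element, min_ltr = 80)
  expect_equal(lp$ltr5, c(0L, 120L))
  expect_equal(lp$internal[2] - lp$internal[1], 85L)
})

test_that("TSD detection: planted, absent, and insufficient-flank cases", {
  set.seed(53)
  core <- rand_dna(60)
  g <- paste0(rand_dna(20), "ACGTA", core, "ACGTA", rand_dna(20))
  t <- detect_tsd(g, 25, 85)
  expect_equal(t$len, 5L)
  expect_equal(t$tsd, "ACGTA")

  g2 <- paste0(rand_dna(20), "TTTT", core, "GGGG", rand_dna(20))
  expect_null(detect_tsd(g2, 24, 84))

  short <- detect_tsd("ACGTACGT", 2, 6)
  expect_false(tsd_found(short))
  expect_equal(attr(short, "reason"), "flank")
})

test_that("PBS detection: exact 3'-end construction including CCA", {
  tl <- synthetic_trna_library()
  lys <- tl[tl$id == "tRNA-Lys", ]
  pbs12 <- revcomp(substring(lys$mature, nchar(lys$mature) - 11, nchar(lys$mature)))
  set.seed(54)
  internal <- paste0(pbs12, rand_dna(80))
  call <- detect_pbs(internal, tl)
  expect_equal(call$trna_id, "tRNA-Lys")
  expect_equal(call$mode, "three_prime_end")
  expect_gte(call$length, 12L)
  expect_lte(call$mismatches, 1L)
  expect_equal(call$start, 0L)
})

test_that("PBS anticodon-loop mode requires the spliced (mature) tRNA", {
  tl <- synthetic_trna_library()
  tyr <- tl[tl$id == "tRNA-Tyr", ]   # intron at [38,52) on the gene
  # region complementary to spliced positions [29,42): spans the splice
  # junction, so it cannot match the unspliced gene contiguously
  probe <- revcomp(substring(tyr$spliced, 30, 42))
  set.seed(55)
  internal <- paste0(rand_dna(5), probe, rand_dna(70))
  call <- detect_pbs(internal, tl)
  expect_equal(call$trna_id, "tRNA-Tyr")
  expect_equal(call$mode, "anticodon_loop")
  expect_gte(call$length, 13L)
  # sanity: the probe is split by the intron on the unspliced gene
  expect_false(grepl(revcomp(probe), tyr$residues, fixed = TRUE))
  expect_true(grepl(revcomp(probe), tyr$spliced, fixed = TRUE))
})

test_that("PBS false-positive rate on random internals is below 5%", {
  tl <- synthetic_trna_library()
  set.seed(56)
  fp <- 0
  n <- 300
  for (i in 1:n) {
    if (!is.null(detect_pbs(rand_dna(50), tl))) fp <- fp + 1
  }
  expect_lt(fp / n, 0.05)
})

test_that("PPT detection obeys the stated rule and matches the window oracle", {
  set.seed(57)
  internal <- paste0(rand_dna(60), "GAAAAGGGGA")
  ppt <- detect_ppt(internal)
  expect_false(is.null(ppt))
  expect_equal(ppt[2], 70L)

  pyr <- paste0(rand_dna(50), paste(rep("CT", 6), collapse = ""))
  expect_null(detect_ppt(pyr))

  for (i in 1:200) {
    s <- rand_dna(sample(15:80, 1))
    got <- detect_ppt(s)
    want <- oracle_ppt(s)
    if (is.null(want)) expect_null(got, info = s)
    else expect_equal(got, as.integer(want), info = s)
  }
})

test_that("solo LTRs are recovered with their original TSDs", {
  tl <- synthetic_trna_library()
  spec <- family_spec("famS", ltr_len = 120, internal_len = 200,
                      promoter = "none", tsd_len = 5, copy_count = 10,
                      divergence = 0, indel_prob = 0, solo_fraction = 0.3,
                      seed = 41)
  sim <- plant_elements(4e5, list(spec), seed = 77, trna_library = tl)
  n_solo <- sum(sim$truth$is_solo)
  expect_gt(n_solo, 0)
  fam <- trim_family("famS", sim$ancestors$residues[1], ltr_len = 120,
                     tsd_len = 5L)
  hits <- count_family_copies(sim$genome, fam)
  solo <- find_solo_ltrs(hits, fam, sim$genome)
  expect_equal(nrow(solo), n_solo)
  truth_solo <- dplyr::arrange(sim$truth[sim$truth$is_solo, ], start)
  solo <- dplyr::arrange(solo, start)
  expect_equal(solo$tsd, truth_solo$tsd)
  expect_equal(solo$start, truth_solo$start)
})

test_that("full-length copies and sub-threshold fragments are not called solo", {
  set.seed(58)
  fam <- trim_family("f", paste0(rand_dna(100), rand_dna(200), rand_dna(100)),
                     ltr_len = 100)
  # full copy: internal hit adjacent to the LTR hit
  hits <- tibble::tibble(
    family_id = "f", seq_id = "chr1",
    start = c(1000L, 1100L), end = c(1100L, 1300L),
    strand = "+", identity = c(1, 1), coverage = c(1, 1),
    score = c(100, 200), q_start = c(0L, 0L), q_end = c(100L, 200L),
    part = c("ltr", "internal")
  )
  g <- tibble::tibble(id = "chr1", residues = rand_dna(2000), description = "")
  expect_equal(nrow(find_solo_ltrs(hits, fam, g)), 0)

  # LTR fragment at 50% coverage fails the threshold contract
  frag <- hits[1, ]
  frag$coverage <- 0.5
  expect_equal(nrow(find_solo_ltrs(frag, fam, g)), 0)

  unpart <- trim_family("u", rand_dna(400))
  expect_error(find_solo_ltrs(hits, unpart, g), "not partitioned")
})

test_that("annotation of a planted consensus reproduces the generator spec", {
  tl <- synthetic_trna_library()
  ok <- 0
  for (k in 1:10) {
    spec <- family_spec("famA", ltr_len = 150, internal_len = 250,
                        promoter = "tRNA_type2", pbs_mode = "three_prime_end",
                        pbs_trna_id = "tRNA-His", tsd_len = 5,
                        divergence = 0.02, seed = 500 + k)
    fam_src <- make_family(spec, tl)
    fam <- trim_family("famA", fam_src$element, ltr_len = 150, tsd_len = 5L)
    ann <- annotate_family(fam, tl)
    good <- ann$family_class == "TRIMp3_tRNA" &&
      !is.null(ann$pbs) && ann$pbs$trna_id == "tRNA-His" &&
      ann$pbs$mode == "three_prime_end" && !is.null(ann$ppt)
    ok <- ok + good
  }
  expect_gte(ok, 10 * 0.95 - 1)   # >=95% of trials (allowing one miss)
})
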