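test_that("constructed box A / box B layout yields a tRNA-type call", {
  set.seed(61)
  ltr <- paste0("CCCCCCCCCC", "TAGCT", rand_dna(6), "TGG",
                paste(rep("C", 16), collapse = ""), "GGTTC", rand_dna(60))
  ann <- scan_trna_promoter(ltr)
  expect_equal(ann$promoter_type, "tRNA_type2")
  expect_equal(ann$boxA$start, 10L)
  expect_equal(ann$boxB$seq, "GGTTC")
  expect_gt(ann$boxB$start, ann$boxA$start)
})

test_that("generator-planted promoters are detected at recorded offsets", {
  tl <- synthetic_trna_library()
  f1 <- make_family(family_spec("t2", 200, 100, "tRNA_type2", seed = 11), tl)
  a1 <- scan_trna_promoter(f1$ltr)
  expect_equal(a1$promoter_type, "tRNA_type2")

  f2 <- make_family(family_spec("t1", 160, 100, "fiveS_type1", seed = 12), tl)
  a2 <- scan_5s_promoter(f2$ltr)
  expect_equal(a2$promoter_type, "fiveS_type1")
  expect_equal(a2$boxA$start, f2$meta$boxA[1])
  expect_equal(a2$IE$start, f2$meta$IE[1])
  expect_equal(a2$boxC$start, f2$meta$boxC[1])
})

test_that("the shipped synthetic 5S control sequence is a positive control", {
  ctrl <- read_fasta(system.file("extdata", "synthetic_5s_rDNA.fasta",
                                 package = "trimscan"))
  ann <- scan_5s_promoter(ctrl$residues)
  expect_equal(ann$promoter_type, "fiveS_type1")
  expect_equal(ann$boxA$mismatches + ann$IE$mismatches + ann$boxC$mismatches, 0L)
})

test_that("promoter scanners are specific on random LTRs", {
  set.seed(62)
  n <- 300
  fp_t <- 0; fp_f <- 0
  for (i in 1:n) {
    s <- rand_dna(300)
    if (scan_trna_promoter(s)$promoter_type != "none") fp_t <- fp_t + 1
    if (scan_5s_promoter(s)$promoter_type != "none") fp_f <- fp_f + 1
  }
  expect_lt(fp_t / n, 0.10)
  expect_lt(fp_f / n, 0.10)
})

test_that("planted promoters survive 5% divergence at the family level", {
  # classification looks at both LTR copies, each independently mutated
  tl <- synthetic_trna_library()
  set.seed(63)
  hit <- 0
  n <- 50
  for (i in 1:n) {
    f <- make_family(family_spec("x", 200, 100, "tRNA_type2", seed = 700 + i), tl)
    el <- mutate_subs(f$element, 0.05)
    fam <- trim_family("x", el, ltr_len = 200)
    if (classify_family(fam)$family_class == "TRIMp3_tRNA") hit <- hit + 1
  }
  expect_gte(hit / n, 0.9)
})

test_that("family classification covers all promoter and length regimes", {
  tl <- synthetic_trna_library()
  f_t <- make_family(family_spec("a", 200, 100, "tRNA_type2", seed = 21), tl)
  fam_t <- trim_family("a", f_t$element, ltr_len = 200)
  expect_equal(classify_family(fam_t)$family_class, "TRIMp3_tRNA")

  f_5 <- make_family(family_spec("b", 160, 100, "fiveS_type1", seed = 22), tl)
  fam_5 <- trim_family("b", f_5$element, ltr_len = 160)
  expect_equal(classify_family(fam_5)$family_class, "TRIMp3_5S")

  f_n <- make_family(family_spec("c", 150, 100, "none", seed = 23), tl)
  fam_n <- trim_family("c", f_n$element, ltr_len = 150)
  expect_equal(classify_family(fam_n)$family_class, "TRIMp2")

  # lengths between 1000 and 1300 keep their class with a long-TRIM flag
  f_long <- make_family(family_spec("d", 300, 500, "tRNA_type2", seed = 24), tl)
  fam_long <- trim_family("d", f_long$element, ltr_len = 300)
  cl <- classify_family(fam_long)
  expect_equal(cl$family_class, "TRIMp3_tRNA")
  expect_true(cl$long_trim)

  # beyond 1300 bp the TRIM label no longer applies
  set.seed(25)
  big <- trim_family("e", paste0(rand_dna(400), rand_dna(700), rand_dna(400)),
                     ltr_len = 400)
  expect_equal(classify_family(big)$family_class, "unclassified")

  expect_error(classify_family(trim_family("f", rand_dna(500))), "not partitioned")
})

test_that("classification is a pure function of the sequence", {
  tl <- synthetic_trna_library()
  f <- make_family(family_spec("p", 200, 120, "tRNA_type2", seed = 31), tl)
  fam <- trim_family("p", f$element, ltr_len = 200)
  a <- classify_family(fam)
  b <- classify_family(fam)
  expect_identical(a, b)
})

test_that("motif configuration round-trips through the plain-text format", {
  m <- default_5s_motifs()
  expect_true(all(c("boxA", "ie", "boxC") %in% names(m)))
  expect_equal(m$gap_a_ie, c(2L, 10L))
  expect_equal(m$gap_ie_c, c(5L, 15L))
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom", "boxA = GGGTT", "ie = CCCAA", "boxC = TTTGG",
               "gap_a_ie = 1-5", "gap_ie_c = 2-8"), tmp)
  m2 <- read_motif_config(tmp)
  expect_equal(m2$boxA, "GGGTT")
  expect_equal(m2$gap_ie_c, c(2L, 8L))
})
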