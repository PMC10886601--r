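test_that("Jukes-Cantor distance matches the closed form and its edge cases", {
  expect_equal(as.numeric(jc_distance("ACGTACGTAC", "ACGTACGTAC")), 0)

  # p = 0.1: 1 mismatch in 10 shared columns
  d <- jc_distance("ACGTACGTAC", "ACGTACGTAT")
  expect_equal(as.numeric(d), -0.75 * log(1 - 0.4 / 3))
  expect_lt(abs(as.numeric(d) - 0.10732), 1e-5)

  # saturation: p >= 0.75 capped
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(rep("C", 20), collapse = "")
  ds <- jc_distance(a, b)
  expect_equal(as.numeric(ds), 5)
  expect_true(attr(ds, "saturated"))

  expect_error(jc_distance("A---", "-CG-"), "shared")

  # pairwise deletion: gaps excluded from shared columns
  d2 <- jc_distance("AC-TA", "ACGTA")
  expect_equal(attr(d2, "p"), 0)

  # monotone increasing in p on [0, 0.75)
  base <- paste(rep("A", 100), collapse = "")
  ds <- vapply(c(5, 20, 40, 60, 70), function(k) {
    other <- paste(c(rep("C", k), rep("A", 100 - k)), collapse = "")
    as.numeric(jc_distance(base, other))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("BioNJ solves the three-taxon case exactly", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.4,
                 0.5, 0.4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- bionj_tree(dm)
  expect_equal(length(tr$tip.label), 3)
  # three-point formulas: x_a = (dab + dac - dbc) / 2, etc.
  want <- c(a = (0.3 + 0.5 - 0.4) / 2, b = (0.3 + 0.4 - 0.5) / 2,
            c = (0.5 + 0.4 - 0.3) / 2)
  tip_edge <- setNames(tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(tip_edge[names(want)], want, tolerance = 1e-6)

  expect_error(bionj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("BioNJ recovers random additive trees exactly", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    dm <- stats::cophenetic(tr)
    got <- bionj_tree(as.dist(dm))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), got)), 0)
    back <- stats::cophenetic(got)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(back - dm)), 1e-5)
  }
})

test_that("bootstrap supports: unanimous alignments, determinism", {
  # every informative column supports the split ab|cd
  inf <- c(a = "A", b = "A", c = "T", d = "T")
  cst <- c(a = "G", b = "G", c = "G", d = "G")
  cols <- c(rep(list(inf), 20), rep(list(cst), 30))
  rows <- vapply(names(inf), function(tx) {
    paste(vapply(cols, function(cl) cl[[tx]], ""), collapse = "")
  }, "")
  msa <- tibble::tibble(id = names(inf), aligned = unname(rows))
  tr <- bootstrap_support(msa, n = 100, seed = 5)
  expect_true(all(tr$node.label[!is.na(tr$node.label)] == 100))

  tr2 <- bootstrap_support(msa, n = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("bootstrap supports hit the binomial expectation on conflicting sites", {
  # 7 columns support ab|cd, 2 support ac|bd, 21 are constant; each
  # replicate's BioNJ split follows the resampled majority, so the support
  # equals P(X > Y) under multinomial resampling (ties are negligible but
  # folded into the tolerance)
  t1 <- c(a = "A", b = "A", c = "T", d = "T")
  t2 <- c(a = "A", b = "T", c = "A", d = "T")
  cst <- c(a = "G", b = "G", c = "G", d = "G")
  cols <- c(rep(list(t1), 7), rep(list(t2), 2), rep(list(cst), 21))
  rows <- vapply(names(t1), function(tx) {
    paste(vapply(cols, function(cl) cl[[tx]], ""), collapse = "")
  }, "")
  msa <- tibble::tibble(id = names(t1), aligned = unname(rows))

  # enumeration oracle: joint pmf of (X, Y) counts in a 30-column resample
  n_cols <- 30
  p1 <- 7 / 30; p2 <- 2 / 30
  p_win <- 0; p_tie <- 0
  for (x in 0:n_cols) {
    for (y in 0:(n_cols - x)) {
      pr <- stats::dmultinom(c(x, y, n_cols - x - y), prob = c(p1, p2, 1 - p1 - p2))
      if (x > y) p_win <- p_win + pr
      if (x == y) p_tie <- p_tie + pr
    }
  }
  # on exact resample ties BioNJ deterministically returns the ab|cd
  # split, so the expected support is P(X > Y) + P(X == Y)
  p_exp <- p_win + p_tie
  n_boot <- 400
  tr <- bootstrap_support(msa, n = n_boot, seed = 9)
  node_ab <- ape::getMRCA(tr, c("a", "b"))
  sup <- tr$node.label[node_ab - length(tr$tip.label)]   # ab|cd support
  se <- 100 * sqrt(p_exp * (1 - p_exp) / n_boot)
  expect_lt(abs(sup - 100 * p_exp), 3 * se + 0.1)
})

test_that("distance matrices carry raw mismatch proportions", {
  msa <- tibble::tibble(id = c("x", "y", "z"),
                        aligned = c("AAAA", "AAAT", "TTTT"))
  dm <- jc_distance_matrix(msa)
  p <- attr(dm, "p_raw")
  expect_equal(p["x", "y"], 0.25)
  expect_equal(p["x", "z"], 1)
  expect_equal(as.matrix(dm)["x", "z"], 5)   # saturated, capped
})
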