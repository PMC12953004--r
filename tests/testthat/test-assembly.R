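toy_tree <- function(seed = 17, n = 8) simulate_tree(n, seed)

test_that("cophenetic distances equal path lengths on the tree", {
  # 2-tip tree with branches 1 and 2 -> distance 3
  tr <- ape::read.tree(text = "(a:1,b:2);")
  expect_equal(cophenetic_distances(tr)["a", "b"], 3)

  tr2 <- toy_tree()
  d <- cophenetic_distances(tr2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # ultrametric by construction (pure-birth with extant sampling)
  depths <- ape::node.depth.edgelength(tr2)[seq_along(tr2$tip.label)]
  expect_true(diff(range(depths)) < 1e-6)

  trx <- tr2
  trx$edge.length <- NULL
  expect_error(cophenetic_distances(trx), "branch lengths")
})

test_that("beta_mntd matches the direct-formula oracle", {
  tr <- toy_tree(3, 6)
  d <- cophenetic_distances(tr)
  taxa <- rownames(d)

  a <- c(5, 3, 0, 0, 2, 0); names(a) <- taxa
  b <- c(0, 1, 4, 4, 0, 1); names(b) <- taxa
  expect_equal(beta_mntd(a, b, d), bmntd_oracle(a, b, d))

  # identical communities -> 0
  expect_equal(beta_mntd(a, a, d), 0)

  # single-taxon communities -> their pairwise distance
  i <- c(1, 0, 0, 0, 0, 0); names(i) <- taxa
  j <- c(0, 0, 1, 0, 0, 0); names(j) <- taxa
  expect_equal(beta_mntd(i, j, d), d[1, 3])

  # random cases against the oracle, weighted and unweighted
  set.seed(11)
  for (k in 1:10) {
    a <- rpois(6, 3); names(a) <- taxa
    b <- rpois(6, 3); names(b) <- taxa
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(beta_mntd(a, b, d), bmntd_oracle(a, b, d))
    expect_equal(beta_mntd(a, b, d, weighted = FALSE),
                 bmntd_oracle((a > 0) * 1, (b > 0) * 1, d))
  }

  expect_error(beta_mntd(a * 0, b, d), "empty")
})

test_that("beta_mntd agrees with picante as an independent implementation", {
  fx <- small_table(n_taxa = 15, seed = 2, depth = 500)
  d <- cophenetic_distances(fx$tree)
  comm <- t(fx$table$counts)  # picante wants samples x taxa
  ref <- as.matrix(picante::comdistnt(comm, d, abundance.weighted = TRUE))
  for (pair in list(c(1, 5), c(2, 9), c(12, 30))) {
    a <- fx$table$counts[, pair[1]]
    b <- fx$table$counts[, pair[2]]
    expect_equal(beta_mntd(a, b, d),
                 ref[colnames(fx$table$counts)[pair[1]],
                     colnames(fx$table$counts)[pair[2]]],
                 tolerance = 1e-10)
  }
})

test_that("beta_nti behaves as a standardised effect size", {
  tr <- toy_tree(5, 10)
  d <- cophenetic_distances(tr)
  taxa <- rownames(d)
  a <- stats::setNames(c(4, 6, 3, 0, 0, 0, 0, 0, 0, 0), taxa)
  b <- stats::setNames(c(3, 0, 5, 2, 0, 0, 0, 0, 0, 0), taxa)

  # identical communities: every nearest-taxon distance is 0 under any
  # relabelling, so the null collapses and the effect size is undefined
  expect_warning(
    res <- beta_nti(a, a, d, n_null = 99, rng_seed = 1, details = TRUE),
    "zero spread")
  expect_equal(res$obs, 0)
  expect_true(is.nan(res$bnti))

  # determinism
  s1 <- beta_nti(a, b, d, n_null = 199, rng_seed = 3)
  s2 <- beta_nti(a, b, d, n_null = 199, rng_seed = 3)
  expect_identical(s1, s2)

  # invariance to uniform branch-length rescaling
  s3 <- beta_nti(a, b, d * 7.3, n_null = 199, rng_seed = 3)
  expect_equal(s1, s3, tolerance = 1e-12)

  expect_error(beta_nti(a, b, d, n_null = 10), "n_null")
})

test_that("classification thresholds are strict at +/-2", {
  expect_equal(classify_assembly(-2.5), "homogeneous_selection")
  expect_equal(classify_assembly(2.5), "variable_selection")
  expect_equal(classify_assembly(c(0, -2, 2, 1.99)),
               rep("stochastic", 4))
  expect_warning(cls <- classify_assembly(NaN), "unclassified")
  expect_equal(cls, "unclassified")
})

test_that("stage fractions count pairs correctly and sum to one", {
  fx <- small_table(n_taxa = 25, seed = 8, depth = 1000)
  asm <- stage_fractions(fx$table, fx$tree, n_null = 99, rng_seed = 1)
  # 9 replicates per stage -> choose(9,2) = 36 within-stage pairs
  expect_equal(asm$stage_fractions$n_pairs, rep(36L, 4),
               ignore_attr = TRUE)
  sums <- rowSums(asm$stage_fractions[, c("homogeneous_selection",
                                          "variable_selection",
                                          "stochastic")])
  expect_equal(sums, rep(1, 4), tolerance = 1e-9, ignore_attr = TRUE)
  # classification column is consistent with the bnti values
  ok <- is.finite(asm$bnti$bnti)
  expect_identical(asm$bnti$classification[ok],
                   classify_assembly(asm$bnti$bnti[ok]))
})

test_that("regime ranking is recovered across all-pairs comparisons", {
  tr <- simulate_tree(100, 31L)
  frac_of <- function(regime, what) {
    cfg <- simulation_config(n_taxa = 100, seq_depth = 5000,
                             selection_regime = regime, rng_seed = 31)
    tab <- simulate_communities(tr, cfg)
    asm <- suppressWarnings(
      stage_fractions(tab, tr, n_null = 199, rng_seed = 31,
                      all_pairs = TRUE))
    mean(asm$bnti$classification == what)
  }
  h <- vapply(c("homogeneous", "variable", "neutral"), frac_of,
              numeric(1), what = "homogeneous_selection")
  v <- vapply(c("homogeneous", "variable", "neutral"), frac_of,
              numeric(1), what = "variable_selection")
  expect_gt(h["homogeneous"], h["neutral"])
  expect_gt(v["variable"], v["homogeneous"])
  expect_gt(v["variable"], v["neutral"])
})
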