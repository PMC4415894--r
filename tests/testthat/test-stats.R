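test_that("group summaries report mean, sem and n", {
  g <- groupSummary(c(5, 5, 5, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(g$mean, c(5, 2))
  expect_equal(g$sem, c(0, 1 / sqrt(3)))
  expect_equal(g$sem[2], 0.5774, tolerance = 1e-4)
  expect_identical(g$n, c(3L, 3L))
  expect_error(groupSummary(1:3, c("a", "b")), "equal length")
})

test_that("the unpaired t-test matches the closed-form pooled computation", {
  r <- ttestUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(statValue(r), -3.674, tolerance = 1e-3)
  expect_equal(pValue(r), 0.02131, tolerance = 1e-4)

  same <- ttestUnpaired(c(2, 4, 6), c(2, 4, 6))
  expect_identical(statValue(same), 0)
  expect_identical(pValue(same), 1)

  degen <- ttestUnpaired(c(1, 1, 1), c(2, 2, 2))
  expect_true(is.nan(statValue(degen)))
  expect_match(degen@note, "degenerate")

  flat <- ttestUnpaired(c(3, 3), c(3, 3))
  expect_identical(statValue(flat), 0)
  expect_identical(pValue(flat), 1)
})

test_that("Kruskal-Wallis reproduces the rank-sum formula and degenerate cases", {
  r <- kruskalWallis(list(1:3, 4:6, 7:9))
  # direct formula: 12/(N(N+1)) * sum(R^2/n) - 3(N+1) with N=9
  expect_equal(statValue(r), 7.2, tolerance = 1e-12)
  expect_equal(pValue(r), stats::pchisq(7.2, df = 2, lower.tail = FALSE))

  flat <- kruskalWallis(list(c(4, 4), c(4, 4), c(4, 4)))
  expect_identical(statValue(flat), 0)
  expect_identical(pValue(flat), 1)
  expect_error(kruskalWallis(list(1:3)), "groups")
})

test_that("Spearman rho and approximations behave at the extremes", {
  up <- spearmanCorr(1:10, (1:10)^3)
  expect_identical(statValue(up), 1)
  down <- spearmanCorr(1:10, -(1:10))
  expect_identical(statValue(down), -1)
  degen <- spearmanCorr(rep(1, 5), 1:5)
  expect_true(is.na(statValue(degen)))
  expect_match(degen@note, "zero variance")
})

test_that("the permutation p equals brute-force enumeration at n = 6", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  r <- spearmanCorr(x, y, method = "permutation")
  # independent oracle: recursive enumeration of all 720 pairings
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  rhos <- vapply(oraclePerms(6L), function(p) stats::cor(rx, ry[p]),
                 numeric(1))
  pOracle <- mean(abs(rhos) >= abs(obs) - 1e-12)
  expect_lt(abs(pValue(r) - pOracle), 1e-12)
  expect_match(r@method, "exact")
})

test_that("sampled permutation p-values respect the add-one bounds", {
  x <- 1:20
  y <- c(2:20, 1)
  r <- spearmanCorr(x, y, method = "permutation", nPerm = 99L, seed = 5L)
  expect_gte(pValue(r), 1 / 100)
  expect_lte(pValue(r), 1)
  # deterministic for a fixed seed
  r2 <- spearmanCorr(x, y, method = "permutation", nPerm = 99L, seed = 5L)
  expect_identical(pValue(r), pValue(r2))
})

test_that("rank statistics are invariant under monotone transformations", {
  withr::with_seed(8L, {
    for (i in 1:5) {
      x <- stats::rnorm(15)
      y <- stats::rnorm(15)
      g <- list(stats::rnorm(6), stats::rnorm(6) + 1, stats::rnorm(6) + 2)
      expect_equal(statValue(spearmanCorr(x, y)),
                   statValue(spearmanCorr(exp(x), atan(y))))
      expect_equal(statValue(kruskalWallis(g)),
                   statValue(kruskalWallis(lapply(g, exp))))
    }
  })
})

test_that("null type-I error is nominal for the rank tests", {
  withr::with_seed(31L, {
    kw <- mean(replicate(2000, {
      g <- split(stats::rnorm(45), rep(1:3, 15))
      pValue(kruskalWallis(g)) < 0.05
    }))
    sp <- mean(replicate(2000, {
      pValue(spearmanCorr(stats::rnorm(15), stats::rnorm(15))) < 0.05
    }))
  })
  expect_gte(kw, 0.035)
  expect_lte(kw, 0.065)
  expect_gte(sp, 0.035)
  expect_lte(sp, 0.065)
})

test_that("the cohort battery emits the expected family of tests", {
  tab <- simulateCohort(cohortSimParams(nEyes = 40L, seed = 19L))
  st <- cohortStats(tab)
  expect_identical(sum(grepl("^spearman", st$name)), 1L)
  expect_identical(sum(grepl("^kruskal-wallis", st$name)), 5L)
  expect_identical(sum(grepl("^t-test", st$name)), 4L)
  expect_true(all(st$p >= 0 & st$p <= 1, na.rm = TRUE))
  # Holm adjustment only on the t-test / Kruskal-Wallis family
  expect_true(all(!is.na(st$p_holm[grepl("^(t-test|kruskal)", st$name)])))
  expect_true(all(st$p_holm >= st$p, na.rm = TRUE))
})
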