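test_that("cohort bookkeeping: one row per eye per observed age", {
  tab <- simulateCohort(cohortSimParams(nEyes = 5L, ages = 3, seed = 2L))
  expect_identical(nrow(tab), 5L)
  expect_identical(sort(unique(tab$eye_id)), sprintf("eye%03d", 1:5))

  tab2 <- simulateCohort(cohortSimParams(nEyes = 12L, seed = 5L))
  expect_identical(nrow(tab2), 12L * 5L)
  expect_false(anyDuplicated(tab2[c("eye_id", "age_months")]) > 0)
  # every timeline's ages equal the simulated grid under full observation
  expect_true(all(vapply(split(tab2$age_months, tab2$eye_id),
                         function(a) identical(sort(a), as.numeric(1:5)),
                         logical(1))))
})

test_that("counts are non-negative integers and fractions lie in [0, 100]", {
  tab <- simulateCohort(cohortSimParams(nEyes = 100L, seed = 8L))
  expect_true(is.integer(tab$onh_count))
  expect_true(all(tab$onh_count >= 0))
  expect_true(all(tab$glial_fraction_pct >= 0 & tab$glial_fraction_pct <= 100))
  expect_identical(tab$category,
                   unname(classifyDamage(tab$glial_fraction_pct)))
})

test_that("a zero effect size decouples early counts from the late outcome", {
  tab <- simulateCohort(cohortSimParams(nEyes = 200L, effectSize = 0,
                                        seed = 4L))
  eo <- earlyCountOutcome(tab)
  rho <- statValue(spearmanCorr(eo$early_count, eo$glial_fraction_pct))
  expect_lt(abs(rho), 0.15)
})

test_that("default calibration reproduces the age-trend means", {
  tab <- simulateCohort(cohortSimParams(nEyes = 500L, seed = 11L))
  m <- tapply(tab$onh_count, tab$age_months, mean)
  expect_lt(abs(m[["1"]] - 10), 1.5)
  expect_lt(abs(m[["5"]] - 19.93), 2.5)
})

test_that("the cohort simulator is seed-deterministic", {
  p <- cohortSimParams(nEyes = 20L, observeProb = 0.8, seed = 13L)
  expect_identical(simulateCohort(p), simulateCohort(p))
})
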