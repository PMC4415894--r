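test_that("ONH counting respects the circle and its boundary", {
  f <- retinaFrame(matrix(0, 100, 100), 10, c(500, 500))
  # 12 inside, 5 outside by construction
  inside <- cbind(500 + seq(-80, 80, length.out = 12),
                  500 + rep(c(-40, 40), 6))
  outside <- cbind(500 + c(200, -200, 0, 300, 150), 500 + c(0, 0, 200, 300, 200))
  cells <- data.frame(x_um = c(inside[, 1L], outside[, 1L]),
                      y_um = c(inside[, 2L], outside[, 2L]))
  oc <- countOnhCells(cells, f)
  expect_identical(oc$onh_count, 12L)
  expect_identical(oc$density_per_0p05mm2, 12L)

  # exactly on the 125-um radius: included
  boundary <- data.frame(x_um = 500 + 125, y_um = 500)
  expect_identical(countOnhCells(boundary, f)$onh_count, 1L)
  expect_identical(countOnhCells(boundary, f, circleDiameter = 249)$onh_count, 0L)
})

test_that("the 250-um circle area matches the 0.05 mm^2 convention within 2%", {
  areaMm2 <- pi * (125 / 1000)^2
  expect_lt(abs(areaMm2 - 0.05) / 0.05, 0.02)
  f <- retinaFrame(matrix(0, 10, 10), 100, c(450, 450))
  oc <- countOnhCells(data.frame(x_um = 450, y_um = 450), f)
  expect_lt(abs(oc$density_exact_per_0p05mm2 - oc$onh_count) / oc$onh_count,
            0.02)
})

test_that("adding a cell changes the count by exactly its circle membership", {
  f <- retinaFrame(matrix(0, 100, 100), 10, c(500, 500))
  base <- data.frame(x_um = c(480, 520), y_um = c(500, 500))
  n0 <- countOnhCells(base, f)$onh_count
  withIn <- rbind(base, data.frame(x_um = 510, y_um = 490))
  withOut <- rbind(base, data.frame(x_um = 900, y_um = 900))
  expect_identical(countOnhCells(withIn, f)$onh_count, n0 + 1L)
  expect_identical(countOnhCells(withOut, f)$onh_count, n0)
})

test_that("ONH-cluster cells in a phantom are all counted", {
  ph <- generateRetinaPhantom(retinaPhantomParams(seed = 51L))
  cells <- segmentCells(ph$frame)
  oc <- countOnhCells(cells, ph$frame)
  # with near-perfect segmentation the count equals the ground-truth cells
  # inside the circle: the 15-cell cluster plus any parenchymal cells that
  # landed in the 100-125 um ring
  ctr <- onhCenter(ph$frame)
  dTruth <- sqrt((ph$truth$x_um - ctr[1L])^2 + (ph$truth$y_um - ctr[2L])^2)
  expect_identical(oc$onh_count, sum(dTruth <= 125))
  expect_gte(oc$onh_count, 15L)
})

test_that("timelines join counts to outcomes and partition the inputs", {
  counts <- data.frame(
    eye_id = rep(c("a", "b", "c"), each = 2),
    age_months = rep(c(3, 4), 3),
    onh_count = c(5, 7, 12, 15, 9, 9))
  outcomes <- data.frame(eye_id = c("a", "b"),
                         glial_fraction_pct = c(55, 12))
  tl <- buildTimelines(counts, outcomes)
  expect_length(tl, 3L)
  expect_identical(tl[["a"]]@lateCategory, "high")
  expect_identical(tl[["b"]]@lateCategory, "low")
  expect_true(is.na(tl[["c"]]@lateGlialFraction))

  # partition: every count row appears in exactly one timeline
  got <- do.call(rbind, lapply(tl, function(t)
    data.frame(eye_id = eyeId(t), age_months = t@ages, onh_count = t@counts)))
  rownames(got) <- NULL
  expect_identical(got[order(got$eye_id, got$age_months), ],
                   counts[order(counts$eye_id, counts$age_months), ])

  expect_identical(buildTimelines(counts[0, ]), list())
  expect_error(buildTimelines(rbind(counts, counts[1, ])), "duplicate")
  expect_error(buildTimelines(counts, data.frame(eye_id = "zz",
                                                 glial_fraction_pct = 1)),
               "unknown")
})

test_that("a simulated cohort round-trips through timelines", {
  tab <- simulateCohort(cohortSimParams(nEyes = 60L, seed = 7L))
  outcomes <- unique(tab[c("eye_id", "glial_fraction_pct", "category")])
  tl <- buildTimelines(tab[c("eye_id", "age_months", "onh_count", "treated")],
                       outcomes)
  expect_length(tl, 60L)
  expect_true(all(vapply(tl, function(t) identical(t@ages, as.numeric(1:5)),
                         logical(1))))
  expect_identical(sum(vapply(tl, function(t) length(t@counts), integer(1))),
                   nrow(tab))
})

test_that("treatment comparison reports means, drops and both tests", {
  pre <- c(a = 10, b = 12, c = 15)
  tc0 <- compareTreatment(pre, pre)
  expect_identical(tc0@meanDifference, 0)
  expect_identical(tc0@statistic, 0)
  expect_identical(tc0@pValue, 1)
  expect_identical(tc0@nDecreased, 0L)

  # constructed nine-eye fixture in which six of nine counts drop
  pre9 <- c(e1 = 20, e2 = 18, e3 = 17, e4 = 16, e5 = 19, e6 = 21,
            e7 = 14, e8 = 13, e9 = 15)
  post9 <- pre9 + c(-5, -4, -6, -3, -5, -4, 2, 1, 3)
  tc <- compareTreatment(pre9, post9)
  expect_identical(tc@nPairs, 9L)
  expect_identical(tc@nDecreased, 6L)
  expect_lt(tc@meanDifference, 0)

  expect_error(compareTreatment(pre9, post9[1:8]), "same set")
  expect_error(compareTreatment(c(a = 1), c(a = 2)), "at least 2")
})

test_that("a real post-treatment drop is detected in most replicates", {
  # pre ~ Normal(17, 5); post = pre - 4 + noise on the same eyes: the paired
  # test carries the power for this within-eye design
  hits <- withr::with_seed(99L, replicate(200, {
    pre <- stats::rnorm(9, 17, 5)
    post <- pre - 4 + stats::rnorm(9, 0, 2)
    names(pre) <- names(post) <- paste0("e", 1:9)
    compareTreatment(pre, post)@pairedPValue < 0.05
  }))
  expect_gt(mean(hits), 0.5)
})
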