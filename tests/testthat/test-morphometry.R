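test_that("activation bins are exhaustive, mutually exclusive and correctly closed", {
  expect_identical(unname(classifyActivation(55)), "activated")
  expect_identical(unname(classifyActivation(10)), "non_activated")
  expect_identical(unname(classifyActivation(50)), "non_activated")
  expect_identical(unname(classifyActivation(8)), "small")
  expect_error(classifyActivation(0), "positive")
  expect_error(classifyActivation(-3), "positive")

  sweep <- seq(0.5, 120, by = 0.5)
  cls <- classifyActivation(sweep)
  expect_true(all(cls %in% c("small", "non_activated", "activated")))
  # one switch per boundary, in order
  expect_identical(rle(unname(cls))$values,
                   c("small", "non_activated", "activated"))
})

test_that("a pure-noise or constant image yields no cells", {
  p <- smallRetinaParams(seed = 5L, nParenchymalCells = 0L, nOnhCells = 0L)
  ph <- generateRetinaPhantom(p)
  expect_identical(nrow(segmentCells(ph$frame)), 0L)

  flat <- retinaFrame(matrix(10, 50, 50), 1, c(25, 25))
  expect_identical(nrow(segmentCells(flat)), 0L)
})

test_that("non-finite pixels are rejected", {
  f <- retinaFrame(matrix(10, 20, 20), 1, c(10, 10))
  f@pixels[5, 5] <- NA_real_
  expect_error(segmentCells(f), "non-finite")
})

test_that("a single disk is measured near its true soma area and classified", {
  f <- makeDiskFrame(matrix(c(100, 100), 1L), areas = 80, seed = 2L)
  cells <- segmentCells(f)
  expect_identical(nrow(cells), 1L)
  expect_lt(abs(cells$soma_area_um2 - 80) / 80, 0.15)
  expect_identical(cells$class, "activated")
  expect_lte(cells$soma_area_um2, cells$component_area_um2)
})

test_that("soma-area estimates stay within 15% for disks of 20-100 um^2", {
  areas <- c(20, 35, 50, 75, 100)
  centers <- cbind(seq(30, 170, length.out = 5), 100)
  f <- makeDiskFrame(centers, areas, seed = 6L)
  cells <- segmentCells(f)
  cells <- cells[order(cells$x_um), ]
  expect_identical(nrow(cells), 5L)
  rel <- (cells$soma_area_um2 - areas) / areas
  expect_lte(mean(abs(rel)), 0.15)      # mean absolute relative error
  expect_lte(abs(mean(rel)), 0.10)      # and no systematic bias
  expect_true(all(abs(rel) <= 0.25))
})

test_that("touching cells with two soma peaks are split into two records", {
  f <- makeDiskFrame(rbind(c(90, 100), c(104, 100)), areas = c(60, 60),
                     seed = 2L)
  cells <- segmentCells(f)
  expect_identical(nrow(cells), 2L)
  expect_true(all(abs(cells$soma_area_um2 - 60) / 60 < 0.25))
})

test_that("segmentation on a dense phantom meets recall and precision targets", {
  ph <- generateRetinaPhantom(retinaPhantomParams(seed = 31L))
  cells <- segmentCells(ph$frame)
  ev <- evaluateSegmentation(cells, ph$truth)
  expect_gte(ev$recall, 0.95)
  expect_gte(ev$precision, 0.95)
  expect_lte(ev$somaAbsRelError, 0.15)
  # no two records share a centroid
  expect_false(anyDuplicated(cells[c("x_um", "y_um")]) > 0)
})

test_that("sector assignment follows the angle and boundary conventions", {
  f <- retinaFrame(matrix(0, 150, 150), 10, c(750, 750))
  cfg <- morphometryConfig()
  # at the center and at the exclusion boundary: excluded
  expect_true(is.na(assignSector(750, 750, frame = f, config = cfg)))
  expect_true(is.na(assignSector(750 + 125, 750, frame = f, config = cfg)))
  # due east just outside the exclusion: sector 0
  expect_identical(assignSector(750 + 300, 750, frame = f, config = cfg), 0L)
  # due north (y decreasing) is 90 degrees CCW: sector 2
  expect_identical(assignSector(750, 750 - 300, frame = f, config = cfg), 2L)
  # at exactly the outer radius: included
  expect_identical(
    assignSector(750 + cfg@analysisOuterRadius, 750, frame = f, config = cfg),
    0L)
  expect_true(is.na(assignSector(750 + cfg@analysisOuterRadius + 1, 750,
                                 frame = f, config = cfg)))
})

test_that("cells placed two per sector are summarized two per sector", {
  f <- retinaFrame(matrix(0, 150, 150), 10, c(750, 750))
  cfg <- morphometryConfig()
  ang <- rep((0:7) * 45 + c(10, 30), each = 1)  # two angles inside each wedge
  ang <- as.vector(outer(c(10, 30), (0:7) * 45, "+"))
  x <- 750 + 300 * cos(ang * pi / 180)
  y <- 750 - 300 * sin(ang * pi / 180)
  cells <- data.frame(x_um = x, y_um = y,
                      sector = assignSector(x, y, frame = f, config = cfg),
                      class = rep(c("activated", "non_activated"), 8))
  s <- summarizeSectors(cells, cfg)
  expect_identical(s$total_cells, rep(2L, 8))
  expect_identical(s$activated_cells, rep(1L, 8))
})

test_that("sector totals conserve the number of sector-assigned cells", {
  ph <- generateRetinaPhantom(smallRetinaParams(seed = 41L,
                                                nParenchymalCells = 60L))
  cfg <- morphometryConfig(analysisOuterRadius = 180)
  cells <- segmentCells(ph$frame, cfg)
  s <- summarizeSectors(cells, cfg)
  expect_identical(sum(s$total_cells), sum(!is.na(cells$sector)))
  expect_true(all(s$activated_cells <= s$total_cells))

  # empty input: all sectors zero
  s0 <- summarizeSectors(cells[0, ], cfg)
  expect_identical(s0$total_cells, rep(0L, 8))
})

test_that("sector counts are exactly invariant under a 90-degree rotation", {
  ph <- generateRetinaPhantom(retinaPhantomParams(seed = 12L))
  cfg <- morphometryConfig(analysisOuterRadius = 700)
  n <- nrow(imageData2d(ph$frame))
  m <- imageData2d(ph$frame)
  # rotate the grid by +90 degrees: pixel (x, y) -> (n-1-y, x)
  rot <- t(m)[, n:1]
  ctr <- onhCenter(ph$frame)
  ctrRot <- c((n - 1) * pixelScale(ph$frame) - ctr[2L], ctr[1L])
  fRot <- retinaFrame(rot, pixelScale(ph$frame), ctrRot)

  s1 <- summarizeSectors(segmentCells(ph$frame, cfg), cfg)$total_cells
  s2 <- summarizeSectors(segmentCells(fRot, cfg), cfg)$total_cells
  # a quarter-turn shifts every cell by exactly two 45-degree sectors
  expect_identical(s2, s1[c(3:8, 1:2)])
})
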