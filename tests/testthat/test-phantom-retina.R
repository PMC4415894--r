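test_that("an empty phantom is pure noise with empty ground truth", {
  p <- smallRetinaParams(seed = 3L, nParenchymalCells = 0L, nOnhCells = 0L)
  ph <- generateRetinaPhantom(p)
  expect_identical(nrow(ph$truth), 0L)
  img <- imageData2d(ph$frame)
  expect_true(all(img >= 0))
  # noise only: intensities fluctuate around the background level
  expect_lt(abs(mean(img) - 30), 2)
  expect_gt(stats::sd(img), 4)
})

test_that("identical parameters and seed give bit-identical phantoms", {
  p <- smallRetinaParams(seed = 17L)
  a <- generateRetinaPhantom(p)
  b <- generateRetinaPhantom(p)
  expect_identical(imageData2d(a$frame), imageData2d(b$frame))
  expect_identical(a$truth, b$truth)
})

test_that("cell bookkeeping, ONH membership, spacing and class labels hold", {
  ph <- generateRetinaPhantom(retinaPhantomParams(seed = 21L))
  tr <- ph$truth
  expect_identical(nrow(tr), 265L)
  expect_identical(sum(tr$in_onh), 15L)

  ctr <- onhCenter(ph$frame)
  d <- sqrt((tr$x_um - ctr[1L])^2 + (tr$y_um - ctr[2L])^2)
  expect_true(all(d[tr$in_onh] <= 100))
  expect_true(all(d[!tr$in_onh] > 100))

  # pairwise spacing respects the configured minimum
  expect_gte(min(stats::dist(cbind(tr$x_um, tr$y_um))), 20)

  # ground-truth class is consistent with the soma-area bins
  expect_identical(tr$true_class,
                   unname(classifyActivation(tr$true_soma_area_um2)))
  expect_true(all(tr$true_soma_area_um2 > 0))
})

test_that("placement fails cleanly when density is too high for the spacing", {
  p <- retinaPhantomParams(fieldWidthPx = 100L, fieldHeightPx = 100L,
                           nParenchymalCells = 200L, nOnhCells = 0L,
                           onhCenter = c(50, 50), onhRadius = 10,
                           minCenterSpacing = 30, seed = 1L)
  expect_error(generateRetinaPhantom(p), "placement failed")
})

test_that("parameter invariants are enforced", {
  expect_error(retinaPhantomParams(pixelScale = 0), "pixelScale")
  expect_error(retinaPhantomParams(nParenchymalCells = -1L), "counts")
  expect_error(retinaPhantomParams(somaAreaWeights = c(1, 1)), "mixture")
})
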