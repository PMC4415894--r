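smallNerveParams <- function(seed = 1L, ...) {
  nervePhantomParams(nerveRadiusPx = 120L, seed = seed, ...)
}

test_that("zero target gives an empty glial mask", {
  ph <- generateNervePhantom(smallNerveParams(targetGlialFraction = 0))
  expect_false(any(ph$gliaTruth))
})

test_that("the glia mask hits the construction target without exclusions", {
  ph <- generateNervePhantom(smallNerveParams(targetGlialFraction = 50,
                                              nVessels = 0L,
                                              meningesThickness = 0))
  frac <- 100 * sum(ph$gliaTruth) / sum(ph$section@nerveMask)
  expect_gte(frac, 49.5)
  expect_lte(frac, 50.5)
})

test_that("recomputing the fraction from returned masks reproduces the target", {
  ph <- generateNervePhantom(smallNerveParams(targetGlialFraction = 30,
                                              nVessels = 3L, seed = 9L))
  sec <- ph$section
  eligible <- sec@nerveMask & !sec@vesselMask & !sec@meningesMask
  frac <- 100 * sum(ph$gliaTruth & eligible) / sum(eligible)
  expect_lt(abs(frac - 30), 0.5)

  # masks are disjoint from glia and nested in the nerve
  expect_false(any(ph$gliaTruth & sec@vesselMask))
  expect_false(any(ph$gliaTruth & sec@meningesMask))
  expect_true(all(which(ph$gliaTruth) %in% which(eligible)))
})

test_that("identical parameters and seed give bit-identical sections", {
  p <- smallNerveParams(targetGlialFraction = 35, seed = 4L)
  a <- generateNervePhantom(p)
  b <- generateNervePhantom(p)
  expect_identical(imageData2d(a$section), imageData2d(b$section))
  expect_identical(a$gliaTruth, b$gliaTruth)
})

test_that("over-constrained geometry is an explicit error", {
  expect_error(
    generateNervePhantom(smallNerveParams(meningesThickness = 1000)),
    "over-constrained")
  expect_error(nervePhantomParams(targetGlialFraction = 120), "\\[0, 100\\]")
})
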