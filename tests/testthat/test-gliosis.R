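test_that("damage categories match the published group means and boundaries", {
  expect_identical(unname(classifyDamage(15.24)), "low")
  expect_identical(unname(classifyDamage(30.38)), "medium")
  expect_identical(unname(classifyDamage(59.05)), "high")
  # middle bin is closed on both sides
  expect_identical(unname(classifyDamage(20)), "medium")
  expect_identical(unname(classifyDamage(40)), "medium")
  expect_identical(unname(classifyDamage(19.999)), "low")
  expect_identical(unname(classifyDamage(40.001)), "high")
  expect_error(classifyDamage(101), "\\[0, 100\\]")
  expect_error(classifyDamage(-1), "\\[0, 100\\]")

  sweep <- seq(0, 100, by = 0.25)
  cls <- classifyDamage(sweep)
  expect_identical(rle(unname(cls))$values, c("low", "medium", "high"))
})

test_that("the glial fraction is pixel-count arithmetic on the eligible area", {
  n <- 60L
  nerve <- matrix(TRUE, n, n)
  img <- matrix(0.5, n, n)
  sec <- nerveSection(img, 1, nerveMask = nerve)

  half <- matrix(FALSE, n, n); half[, seq_len(n / 2)] <- TRUE
  expect_equal(glialFraction(computeGlialFraction(half, sec)), 50)
  expect_equal(glialFraction(computeGlialFraction(nerve, sec)), 100)
  expect_identical(damageCategory(computeGlialFraction(half, sec)), "high")

  # vessels occupying 10% of the nerve; glia 27% of the nerve outside them
  vessels <- matrix(FALSE, n, n); vessels[seq_len(6L), ] <- TRUE   # 360 px = 10%
  sec2 <- nerveSection(img, 1, nerveMask = nerve, vesselMask = vessels)
  glia <- matrix(FALSE, n, n)
  glia[6L + seq_len(972L %/% n), ] <- TRUE            # 960 px
  glia[6L + 972L %/% n + 1L, seq_len(972L %% n)] <- TRUE  # + 12 px = 972 = 27%
  expect_equal(glialFraction(computeGlialFraction(glia, sec2)), 30)
  expect_equal(eligibleArea(computeGlialFraction(glia, sec2)), 3240)

  expect_error(computeGlialFraction(glia, nerveSection(img, 1)), "zero")
})

test_that("excluded-pixel intensities never change the fraction", {
  ph <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
                                                targetGlialFraction = 30,
                                                seed = 2L))
  sec <- ph$section
  f1 <- glialFraction(scoreNerveSection(sec))
  sec2 <- sec
  sec2@pixels[sec2@vesselMask] <- 0
  sec2@pixels[sec2@meningesMask] <- 1
  f2 <- glialFraction(scoreNerveSection(sec2))
  expect_identical(f1, f2)
})

test_that("segmentation recovers the constructed glial fraction", {
  # a glia-free nerve yields an essentially empty mask
  ph0 <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
                                                 targetGlialFraction = 0,
                                                 seed = 3L))
  m0 <- segmentNonaxonal(ph0$section)
  expect_lte(sum(m0) / sum(ph0$section@nerveMask), 0.01)

  ph <- generateNervePhantom(nervePhantomParams(targetGlialFraction = 50,
                                                nVessels = 0L, seed = 3L))
  expect_lt(abs(glialFraction(scoreNerveSection(ph$section)) - 50), 3)

  phv <- generateNervePhantom(nervePhantomParams(targetGlialFraction = 30,
                                                 nVessels = 3L, seed = 4L))
  expect_lt(abs(glialFraction(scoreNerveSection(phv$section)) - 30), 3)
})

test_that("recovered fraction grows monotonically with the true patch size", {
  fr <- vapply(c(10, 30, 50), function(tg)
    glialFraction(scoreNerveSection(generateNervePhantom(
      nervePhantomParams(nerveRadiusPx = 120L, targetGlialFraction = tg,
                         seed = 6L))$section)),
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("repeatability is zero for identical raters and exact for known areas", {
  ph <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
                                                targetGlialFraction = 30,
                                                seed = 7L))
  secs <- list(ph$section, ph$section)
  expect_identical(repeatabilityCheck(secs, gliosisConfig("otsu"),
                                      gliosisConfig("otsu")), 0)

  # banded section: threshold 0.7 keeps 30 rows (A = 3000), 0.5 keeps 33
  # (B = 3300); |A-B|/mean = 300/3150
  banded <- makeBandedSection()
  a <- gliosisConfig("fixed", fixedThreshold = 0.7)
  b <- gliosisConfig("fixed", fixedThreshold = 0.5)
  expect_equal(repeatabilityCheck(list(banded, banded), a, b),
               100 * 300 / 3150, tolerance = 1e-10)
})
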