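# Shared fixtures: all built in code, no files on disk.

# Small, fast retina phantom parameters for unit tests.
smallRetinaParams <- function(seed = 1L, nParenchymalCells = 30L,
                              nOnhCells = 5L, ...) {
  retinaPhantomParams(fieldWidthPx = 400L, fieldHeightPx = 400L,
                      nParenchymalCells = nParenchymalCells,
                      nOnhCells = nOnhCells,
                      onhCenter = c(200, 200), seed = seed, ...)
}

# Render a frame containing disks of given soma areas (um^2) at given
# centers (um), with the phantom's default optics (blur + noise), directly --
# independent of the phantom generator's placement logic.
makeDiskFrame <- function(centers, areas, n = 200L, pixelScale = 1,
                          onhCenter = c(10, 10), bg = 30, peak = 150,
                          noiseSd = 8, blurSigma = 0.8, seed = 1L) {
  img <- matrix(bg, n, n)
  if (length(areas)) {
    for (i in seq_along(areas)) {
      r <- sqrt(areas[i] / pi) / pixelScale
      cx <- centers[i, 1L] / pixelScale
      cy <- centers[i, 2L] / pixelScale
      d2 <- outer(((seq_len(n) - 1) - cy)^2, ((seq_len(n) - 1) - cx)^2, "+")
      img[d2 <= r^2] <- peak
    }
  }
  if (blurSigma > 0)
    img <- as.matrix(EBImage::gblur(img, blurSigma, boundary = "replicate"))
  if (noiseSd > 0) {
    img <- withr::with_seed(seed,
      img + matrix(stats::rnorm(n * n, 0, noiseSd), n, n))
  }
  retinaFrame(pmax(img, 0), pixelScale, onhCenter)
}

# A synthetic nerve section whose eligible-region intensities are exact bands,
# so fixed thresholds produce exactly known glial areas.
makeBandedSection <- function(n = 100L, highRows = 30L, midRows = 3L,
                              pixelScale = 1) {
  img <- matrix(0.3, n, n)
  img[seq_len(highRows), ] <- 0.9
  if (midRows > 0L) img[highRows + seq_len(midRows), ] <- 0.6
  nerveSection(img, pixelScale, nerveMask = matrix(TRUE, n, n))
}

# Independent brute-force oracle: all permutations of 1..n, written as a
# simple recursive insertion (distinct from the package's generator).
oraclePerms <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- oraclePerms(n - 1L)
  out <- list()
  for (p in smaller) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
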