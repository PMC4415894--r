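#' NervePhantomParams: configuration of the synthetic nerve-section generator
#'
#' Describes a synthetic optic-nerve cross-section as seen in PPD/Toluidine
#' Blue plastic histology imaged in RGB: a circular nerve bounded by a
#' meningeal ring, a dark mottled axonal field, brighter glial/scar patches
#' grown to a requested area fraction, and bright vascular lumina. Intensities
#' model the red channel on [0, 1], where axon-free (glial) tissue is brighter
#' than the myelinated axonal field.
#'
#' @slot nerveRadiusPx nerve radius in pixels.
#' @slot pixelScale micrometres per pixel.
#' @slot targetGlialFraction target glial percent of the eligible nerve area
#'   (nerve minus vessels and meninges), in [0, 100].
#' @slot nVessels number of vascular lumina.
#' @slot vesselRadiusRange vessel radius range, micrometres.
#' @slot meningesThickness thickness (um) of the peripheral meningeal ring.
#' @slot axonTextureScale correlation length (um) of the axonal mottling.
#' @slot blurSigmaPx Gaussian blur sigma (px) emulating optical spread.
#' @slot noiseSd additive Gaussian noise sd (intensity units).
#' @slot seed RNG seed.
#' @seealso [nervePhantomParams()], [generateNervePhantom()]
#' @export
setClass("NervePhantomParams",
  representation(
    nerveRadiusPx = "integer", pixelScale = "numeric",
    targetGlialFraction = "numeric",
    nVessels = "integer", vesselRadiusRange = "numeric",
    meningesThickness = "numeric", axonTextureScale = "numeric",
    blurSigmaPx = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("NervePhantomParams", function(object) {
  msg <- character()
  if (object@nerveRadiusPx <= 0L)
    msg <- c(msg, "nerveRadiusPx must be > 0")
  if (object@pixelScale <= 0)
    msg <- c(msg, "pixelScale must be > 0")
  if (object@targetGlialFraction < 0 || object@targetGlialFraction > 100)
    msg <- c(msg, "targetGlialFraction must be in [0, 100]")
  if (object@nVessels < 0L)
    msg <- c(msg, "nVessels must be >= 0")
  if (length(object@vesselRadiusRange) != 2L ||
      any(object@vesselRadiusRange <= 0) ||
      object@vesselRadiusRange[1L] > object@vesselRadiusRange[2L])
    msg <- c(msg, "vesselRadiusRange must be a non-decreasing positive pair")
  if (object@meningesThickness < 0)
    msg <- c(msg, "meningesThickness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameters for a synthetic optic-nerve cross-section
#'
#' Defaults give a nerve of 175 um radius (mouse-like) sampled at 0.5 um/px,
#' with three vascular lumina and a 10-um meningeal ring.
#'
#' @param nerveRadiusPx nerve radius in pixels (default 350).
#' @param pixelScale um per pixel (default 0.5).
#' @param targetGlialFraction percent (default 20).
#' @param nVessels count (default 3).
#' @param vesselRadiusRange um (default c(8, 20)).
#' @param meningesThickness um (default 10).
#' @param axonTextureScale um (default 3).
#' @param blurSigmaPx optical blur sigma in px (default 1).
#' @param noiseSd intensity sd (default 0.02).
#' @param seed RNG seed (default 1).
#' @return A [NervePhantomParams-class] object.
#' @export
nervePhantomParams <- function(nerveRadiusPx = 350L, pixelScale = 0.5,
                               targetGlialFraction = 20,
                               nVessels = 3L, vesselRadiusRange = c(8, 20),
                               meningesThickness = 10, axonTextureScale = 3,
                               blurSigmaPx = 1, noiseSd = 0.02, seed = 1L) {
  new("NervePhantomParams",
      nerveRadiusPx = as.integer(nerveRadiusPx), pixelScale = pixelScale,
      targetGlialFraction = targetGlialFraction,
      nVessels = as.integer(nVessels), vesselRadiusRange = vesselRadiusRange,
      meningesThickness = meningesThickness,
      axonTextureScale = axonTextureScale, blurSigmaPx = blurSigmaPx,
      noiseSd = noiseSd, seed = as.integer(seed))
}

## Grow a glial ground-truth mask inside `eligible` until it occupies exactly
## `targetPx` pixels: seeded patches dilated shell by shell, with the final
## shell subsampled to land on the target pixel count.
growGliaMask <- function(eligible, targetPx, nSeeds) {
  mask <- matrix(FALSE, nrow(eligible), ncol(eligible))
  if (targetPx <= 0L) return(mask)
  eligIdx <- which(eligible)
  seeds <- sample(eligIdx, min(nSeeds, length(eligIdx)))
  mask[seeds] <- TRUE
  kern <- EBImage::makeBrush(3L, shape = "box")
  while (sum(mask) < targetPx) {
    grown <- EBImage::dilate(mask + 0, kern) > 0 & eligible
    shell <- which(grown & !mask)
    if (length(shell) == 0L)
      stop("glial patch growth exhausted the eligible region before ",
           "reaching the target fraction")
    need <- targetPx - sum(mask)
    if (length(shell) > need)
      shell <- sample(shell, need)
    mask[shell] <- TRUE
  }
  mask
}

#' Generate a synthetic nerve cross-section with ground-truth masks
#'
#' Builds the nerve, meninges and vessel masks geometrically, grows a glial
#' ground-truth mask by iterative patch growth to occupy the requested
#' fraction of the eligible area (nerve minus vessels and meninges) to within
#' one pixel, then renders the red-channel image: dark mottled axonal field,
#' brighter glia, bright vessel lumina and meninges, white background, plus
#' additive Gaussian noise clipped to [0, 1]. Deterministic for a fixed seed.
#'
#' @param params a [NervePhantomParams-class] object.
#' @param sectionId identifier stored in the returned section.
#' @return A list with elements `section` (a [NerveSection-class]) and
#'   `gliaTruth` (logical matrix, the ground-truth glial mask).
#' @examples
#' ph <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
#'   targetGlialFraction = 30, seed = 3L))
#' mean(ph$gliaTruth[ph$section@nerveMask])
#' @export
generateNervePhantom <- function(params, sectionId = "phantom") {
  stopifnot(is(params, "NervePhantomParams"))
  validObject(params)
  withSeed(params@seed, {
    scale <- params@pixelScale
    R <- params@nerveRadiusPx
    margin <- 8L
    n <- 2L * (R + margin)
    ctr <- (n - 1) / 2
    d2 <- pixelDist2(n, n, ctr, ctr)
    nerve <- d2 <= R^2
    menThickPx <- params@meningesThickness / scale
    menInner <- R - menThickPx
    meninges <- if (params@meningesThickness <= 0) {
      matrix(FALSE, n, n)
    } else if (menInner <= 0) {
      nerve                         # sheath swallows the whole cross-section
    } else {
      nerve & d2 > menInner^2
    }

    ## vessels: random lumina strictly inside the meningeal ring
    vessels <- matrix(FALSE, n, n)
    if (params@nVessels > 0L) {
      for (k in seq_len(params@nVessels)) {
        vr <- stats::runif(1, params@vesselRadiusRange[1L],
                           params@vesselRadiusRange[2L]) / scale
        maxR <- max(0, R - menThickPx - vr - 2)
        rr <- maxR * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        vx <- ctr + rr * cos(th)
        vy <- ctr + rr * sin(th)
        vessels <- vessels | (pixelDist2(n, n, vx, vy) <= vr^2)
      }
      vessels <- vessels & nerve & !meninges
    }

    eligible <- nerve & !vessels & !meninges
    if (!any(eligible))
      stop("over-constrained geometry: no eligible nerve area after exclusions")
    targetPx <- round(params@targetGlialFraction / 100 * sum(eligible))
    if (targetPx > sum(eligible))
      stop("target glial fraction infeasible after exclusions")
    nSeeds <- max(1L, round(params@targetGlialFraction / 10))
    glia <- growGliaMask(eligible, targetPx, nSeeds)

    ## render the red channel
    img <- matrix(0.95, n, n)                      # background (white-ish)
    texture <- matrix(stats::rnorm(n * n, 0, 1), n, n)
    sigmaPx <- max(params@axonTextureScale / scale, 0.5)
    texture <- as.matrix(EBImage::gblur(texture, sigma = sigmaPx,
                                        boundary = "replicate"))
    texture <- 0.06 * texture / max(stats::sd(texture), 1e-9)
    axonal <- eligible & !glia
    img[axonal] <- 0.35 + texture[axonal]          # dark myelinated field
    img[glia] <- 0.75 + 0.3 * texture[glia]        # brighter axon-free tissue
    img[meninges] <- 0.85
    img[vessels] <- 0.9
    if (params@blurSigmaPx > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = params@blurSigmaPx,
                                      boundary = "replicate"))
    if (params@noiseSd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, params@noiseSd), n, n)
    img <- pmin(pmax(img, 0), 1)

    section <- nerveSection(img, scale, nerveMask = nerve,
                            vesselMask = vessels, meningesMask = meninges,
                            sectionId = sectionId)
    list(section = section, gliaTruth = glia)
  })
}
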