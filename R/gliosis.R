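#' Classify optic-nerve damage from the glial area fraction
#'
#' Nerves with a glial (non-axonal) territory below 20% of the eligible nerve
#' area are `low` (comparable to non-glaucomatous controls), those on
#' [20, 40]% are `medium`, and those above 40% are `high`. The middle bin is
#' closed: fractions of exactly 20 and exactly 40 are `medium`. The three
#' categories are exhaustive and mutually exclusive on [0, 100].
#'
#' @param glialFraction percent value(s) in [0, 100].
#' @param lowMax,mediumMax bin edges (defaults 20 and 40).
#' @return Character vector of `"low"`, `"medium"` or `"high"`.
#' @examples
#' classifyDamage(c(15.24, 30.38, 59.05))
#' @export
classifyDamage <- function(glialFraction, lowMax = 20, mediumMax = 40) {
  if (any(!is.finite(glialFraction)) ||
      any(glialFraction < 0) || any(glialFraction > 100))
    stop("glial fraction must lie in [0, 100]")
  ifelse(glialFraction < lowMax, "low",
         ifelse(glialFraction <= mediumMax, "medium", "high"))
}

## Eligible region: nerve minus vascular lumina and meninges.
eligibleMask <- function(section) {
  section@nerveMask & !section@vesselMask & !section@meningesMask
}

#' Segment non-axonal (glial) area in a nerve cross-section
#'
#' Thresholds the red-channel image over the eligible nerve region (nerve
#' minus vessels and meninges), where glia and gliotic scar are brighter than
#' the myelinated axonal field. The threshold is automatic (Otsu's method
#' computed on the eligible pixels only) or a fixed override. Glial components
#' smaller than `minObjectArea` are removed as speckle and holes smaller than
#' `minHoleArea` are filled before the mask is returned. Deterministic for
#' fixed input and configuration.
#'
#' If the section carries no nerve mask, the nerve is derived as the largest
#' connected foreground component after an Otsu threshold on overall
#' intensity. (Phantom sections always carry their mask.)
#'
#' @param section a [NerveSection-class].
#' @param config a [GliosisConfig-class].
#' @return Logical glial mask, a subset of the eligible region.
#' @examples
#' ph <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
#'   targetGlialFraction = 40, seed = 5L))
#' mask <- segmentNonaxonal(ph$section)
#' @export
segmentNonaxonal <- function(section, config = gliosisConfig()) {
  stopifnot(is(section, "NerveSection"))
  validObject(section)
  validObject(config)
  px <- section@pixels
  if (!any(section@nerveMask)) {
    ## derive the nerve as the largest foreground component
    thr <- EBImage::otsu(EBImage::Image(pmin(pmax(px, 0), 1)))
    fg <- EBImage::bwlabel((px > thr) + 0)
    fg <- matrix(as.integer(fg), nrow(px), ncol(px))
    if (!any(fg > 0L)) stop("empty nerve mask and no derivable foreground")
    big <- which.max(tabulate(fg[fg > 0L]))
    nerve <- EBImage::fillHull((fg == big) + 0) > 0
    section@nerveMask <- matrix(nerve, nrow(px), ncol(px))
  }
  elig <- eligibleMask(section)
  if (!any(elig)) stop("eligible nerve area is empty")

  vals <- px[elig]
  if (config@method == "fixed") {
    thr <- config@fixedThreshold
  } else {
    thr <- EBImage::otsu(EBImage::Image(matrix(pmin(pmax(vals, 0), 1))))
    ## Otsu always splits the histogram, even a unimodal one (a nerve with no
    ## glia at all). Accept the split only if the two classes are genuinely
    ## separated: class-mean distance of at least 4 pooled within-class sds.
    ## Splitting a single Gaussian mode yields about 2.6, a real axonal/glial
    ## bimodal histogram 6 or more.
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    if (length(lo) < 2L || length(hi) < 2L) {
      sep <- 0
    } else {
      pooledVar <- ((length(lo) - 1) * stats::var(lo) +
                    (length(hi) - 1) * stats::var(hi)) /
                   (length(vals) - 2)
      sep <- (mean(hi) - mean(lo)) / sqrt(max(pooledVar, 1e-12))
    }
    if (sep < 4) thr <- Inf  # no glial mode present
  }
  mask <- elig & (px > thr)

  scale2 <- section@pixelScale^2
  ## speckle removal
  if (any(mask) && config@minObjectArea > 0) {
    lab <- EBImage::bwlabel(mask + 0)
    lab <- matrix(as.integer(lab), nrow(px), ncol(px))
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * scale2 < config@minObjectArea)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  ## fill small holes
  if (any(mask) && config@minHoleArea > 0) {
    filled <- EBImage::fillHull(mask + 0) > 0
    holes <- filled & !mask
    if (any(holes)) {
      hl <- EBImage::bwlabel(holes + 0)
      hl <- matrix(as.integer(hl), nrow(px), ncol(px))
      hs <- tabulate(hl[hl > 0L])
      fill <- which(hs * scale2 < config@minHoleArea)
      if (length(fill)) mask[hl %in% fill] <- TRUE
    }
    mask <- mask & elig
  }
  mask
}

#' Compute the glial area fraction of a nerve section
#'
#' The fraction is `100 * |glial AND eligible| / |eligible|` where eligible is
#' the nerve mask minus vessel and meninges masks; changing the intensity of
#' excluded pixels can therefore never change the fraction. The damage
#' category is assigned with [classifyDamage()].
#'
#' @param glialMask logical matrix (e.g. from [segmentNonaxonal()]).
#' @param section a [NerveSection-class].
#' @return A [GliosisResult-class].
#' @examples
#' ph <- generateNervePhantom(nervePhantomParams(nerveRadiusPx = 120L,
#'   targetGlialFraction = 50, nVessels = 0L, seed = 5L))
#' computeGlialFraction(ph$gliaTruth, ph$section)
#' @export
computeGlialFraction <- function(glialMask, section) {
  stopifnot(is(section, "NerveSection"))
  if (!identical(dim(glialMask), dim(section@pixels)))
    stop("glial mask dimensions do not match the section")
  elig <- eligibleMask(section)
  nElig <- sum(elig)
  if (nElig == 0L) stop("eligible nerve area is zero")
  frac <- 100 * sum(glialMask & elig) / nElig
  new("GliosisResult",
      sectionId = section@sectionId,
      glialFraction = frac,
      eligibleArea = nElig * section@pixelScale^2,
      category = classifyDamage(frac))
}

#' Score a nerve section end to end
#'
#' Convenience wrapper: [segmentNonaxonal()] then [computeGlialFraction()].
#'
#' @inheritParams segmentNonaxonal
#' @return A [GliosisResult-class].
#' @export
scoreNerveSection <- function(section, config = gliosisConfig()) {
  computeGlialFraction(segmentNonaxonal(section, config), section)
}

#' Inter-parameterization repeatability of glial area measurement
#'
#' Segment every section with two configurations standing in for two
#' independent raters and report the mean relative difference in measured
#' glial area, `|A - B| / mean(A, B)`, averaged over sections, in percent.
#'
#' @param sections list of [NerveSection-class] objects (>= 2).
#' @param configA,configB the two [GliosisConfig-class] parameterizations.
#' @return Mean relative difference in percent.
#' @export
repeatabilityCheck <- function(sections, configA = gliosisConfig("otsu"),
                               configB = gliosisConfig("fixed")) {
  if (length(sections) < 2L) stop("need at least 2 sections")
  rel <- vapply(sections, function(sec) {
    scale2 <- sec@pixelScale^2
    a <- sum(segmentNonaxonal(sec, configA)) * scale2
    b <- sum(segmentNonaxonal(sec, configB)) * scale2
    m <- mean(c(a, b))
    if (m == 0) stop("degenerate zero-area measurement in section '",
                     sec@sectionId, "'")
    abs(a - b) / m
  }, numeric(1))
  100 * mean(rel)
}
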