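#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core image containers
## ---------------------------------------------------------------------------

#' RetinaFrame: an in-vivo retinal fluorescence image with physical calibration
#'
#' A single 2D grayscale fluorescence frame of the central retina, as produced
#' by confocal scanning laser ophthalmoscopy (cSLO), together with the physical
#' pixel scale, the annotated optic-disc (ONH) center, and the identity of the
#' imaged eye. Coordinates follow the image convention: origin at the top-left
#' pixel center, x rightward along columns, y downward along rows, 0-based
#' pixels; physical micrometres = pixel index times `pixelScale`.
#'
#' @slot pixels numeric matrix of non-negative intensities (rows = y, cols = x).
#' @slot pixelScale micrometres per pixel (> 0).
#' @slot onhCenter numeric length-2, (x, y) of the optic-disc center in um.
#' @slot eyeId character identifier of the eye.
#' @slot ageMonths age at imaging, months.
#'
#' @seealso [retinaFrame()] for the user-facing constructor.
#' @export
setClass("RetinaFrame",
  representation(
    pixels = "matrix",
    pixelScale = "numeric",
    onhCenter = "numeric",
    eyeId = "character",
    ageMonths = "numeric"
  )
)

setValidity("RetinaFrame", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else {
    if (any(!is.finite(object@pixels)))
      msg <- c(msg, "'pixels' contains non-finite values")
    else if (any(object@pixels < 0))
      msg <- c(msg, "'pixels' contains negative intensities")
  }
  if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0)
    msg <- c(msg, "'pixelScale' must be a single positive number (um/px)")
  if (length(object@onhCenter) != 2L || any(!is.finite(object@onhCenter)))
    msg <- c(msg, "'onhCenter' must be numeric (x, y) in um")
  else if (length(object@pixelScale) == 1L && is.finite(object@pixelScale) &&
           object@pixelScale > 0) {
    lim <- (dim(object@pixels)[c(2L, 1L)] - 1L) * object@pixelScale
    if (any(object@onhCenter < 0) || any(object@onhCenter > lim))
      msg <- c(msg, "'onhCenter' lies outside the image bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RetinaFrame
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelScale micrometres per pixel.
#' @param onhCenter numeric (x, y) optic-disc center in micrometres.
#' @param eyeId eye identifier.
#' @param ageMonths age at imaging in months.
#' @return A [RetinaFrame-class] object.
#' @examples
#' f <- retinaFrame(matrix(0, 64, 64), pixelScale = 2, onhCenter = c(63, 63))
#' pixelScale(f)
#' @export
retinaFrame <- function(pixels, pixelScale, onhCenter,
                        eyeId = "eye1", ageMonths = NA_real_) {
  new("RetinaFrame", pixels = pixels, pixelScale = as.numeric(pixelScale),
      onhCenter = as.numeric(onhCenter), eyeId = as.character(eyeId),
      ageMonths = as.numeric(ageMonths))
}

#' NerveSection: an optic-nerve cross-section image with masks
#'
#' Holds a histology image of an optic-nerve cross-section (the red channel of
#' an RGB acquisition, or a grayscale image treated as the red channel), the
#' physical pixel scale, the nerve outline mask and optional exclusion masks
#' for vascular lumina and meninges. Intensities are on [0, 1].
#'
#' @slot pixels numeric matrix, red-channel intensities in [0, 1].
#' @slot pixelScale micrometres per pixel (> 0).
#' @slot nerveMask logical matrix delimiting the nerve cross-section.
#' @slot vesselMask logical matrix of vascular lumina to exclude (may be all
#'   FALSE).
#' @slot meningesMask logical matrix of the meningeal sheath to exclude (may be
#'   all FALSE).
#' @slot sectionId character identifier.
#' @seealso [nerveSection()], [segmentNonaxonal()], [computeGlialFraction()]
#' @export
setClass("NerveSection",
  representation(
    pixels = "matrix",
    pixelScale = "numeric",
    nerveMask = "matrix",
    vesselMask = "matrix",
    meningesMask = "matrix",
    sectionId = "character"
  )
)

setValidity("NerveSection", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (any(!is.finite(object@pixels)))
    msg <- c(msg, "'pixels' contains non-finite values")
  if (length(object@pixelScale) != 1L || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0)
    msg <- c(msg, "'pixelScale' must be a single positive number (um/px)")
  for (nm in c("nerveMask", "vesselMask", "meningesMask")) {
    m <- slot(object, nm)
    if (!is.logical(m) || !identical(dim(m), d))
      msg <- c(msg, sprintf("'%s' must be a logical matrix with image dimensions", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a NerveSection
#'
#' Exclusion masks are intersected with the nerve mask, so a sloppy hand
#' annotation extending past the nerve outline is harmless.
#'
#' @param pixels numeric matrix of intensities in [0, 1] (red channel).
#' @param pixelScale micrometres per pixel.
#' @param nerveMask logical matrix delimiting the nerve; if `NULL` it is
#'   derived later by [segmentNonaxonal()] as the largest foreground component.
#' @param vesselMask,meningesMask optional logical exclusion masks.
#' @param sectionId identifier.
#' @return A [NerveSection-class] object.
#' @export
nerveSection <- function(pixels, pixelScale, nerveMask = NULL,
                         vesselMask = NULL, meningesMask = NULL,
                         sectionId = "section1") {
  d <- dim(pixels)
  blank <- matrix(FALSE, d[1L], d[2L])
  if (is.null(nerveMask)) nerveMask <- blank
  nerveMask <- nerveMask & TRUE  # coerce to logical matrix
  vesselMask <- if (is.null(vesselMask)) blank else (vesselMask & nerveMask)
  meningesMask <- if (is.null(meningesMask)) blank else (meningesMask & nerveMask)
  new("NerveSection", pixels = pixels, pixelScale = as.numeric(pixelScale),
      nerveMask = nerveMask, vesselMask = vesselMask,
      meningesMask = meningesMask, sectionId = as.character(sectionId))
}

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' MorphometryConfig: parameters for cell/soma segmentation and sector mapping
#'
#' @slot cellThresholdK cell detection threshold, in multiples of the median
#'   absolute deviation (MAD) above the median background intensity.
#' @slot somaRelativeThreshold soma mask threshold, as a fraction of the peak
#'   intensity of each segmented component.
#' @slot activationAreaMin soma area (um^2) above which a cell is classed
#'   `activated`.
#' @slot nonactivatedAreaMin soma area (um^2) below which a cell is classed
#'   `small`.
#' @slot matchRadius centroid matching radius (um) for ground-truth evaluation.
#' @slot sectorCount number of radial sectors around the optic disc.
#' @slot analysisOuterRadius outer radius (um) of the sector annulus.
#' @slot onhExclusionRadius inner radius (um) excluding the ONH from sectors.
#' @slot minComponentPx smallest connected component (pixels) kept as a cell.
#' @slot peakSeparationMin minimum separation (um) between soma-level peaks for
#'   a component to be split into several cells.
#' @seealso [morphometryConfig()]
#' @export
setClass("MorphometryConfig",
  representation(
    cellThresholdK = "numeric",
    somaRelativeThreshold = "numeric",
    activationAreaMin = "numeric",
    nonactivatedAreaMin = "numeric",
    matchRadius = "numeric",
    sectorCount = "integer",
    analysisOuterRadius = "numeric",
    onhExclusionRadius = "numeric",
    minComponentPx = "integer",
    peakSeparationMin = "numeric"
  )
)

setValidity("MorphometryConfig", function(object) {
  msg <- character()
  if (!(object@nonactivatedAreaMin > 0 &&
        object@nonactivatedAreaMin < object@activationAreaMin))
    msg <- c(msg, "need 0 < nonactivatedAreaMin < activationAreaMin")
  if (object@sectorCount < 1L)
    msg <- c(msg, "sectorCount must be >= 1")
  if (object@somaRelativeThreshold <= 0 || object@somaRelativeThreshold >= 1)
    msg <- c(msg, "somaRelativeThreshold must be in (0, 1)")
  if (object@onhExclusionRadius < 0 ||
      object@analysisOuterRadius <= object@onhExclusionRadius)
    msg <- c(msg, "need 0 <= onhExclusionRadius < analysisOuterRadius")
  if (length(msg)) msg else TRUE
})

#' Build a morphometry configuration
#'
#' Defaults implement a robust two-level intensity-threshold scheme: the cell
#' mask is `pixels > median + k * MAD`, and within each connected component the
#' soma mask keeps pixels above a fixed fraction of that component's
#' background-subtracted peak. Activation bins follow soma area: `activated`
#' above 50 um^2, `non_activated` on [10, 50] um^2, `small` below 10 um^2.
#' The eight default sectors are 45-degree wedges over the annulus between the
#' ONH exclusion radius (125 um) and an outer radius chosen so the annulus
#' covers about 1.6 mm^2 of central retina.
#'
#' @param cellThresholdK MAD multiples above the median background (default 5).
#' @param somaRelativeThreshold fraction of component peak (default 0.6).
#' @param activationAreaMin um^2, lower soma-area bound of `activated`
#'   (default 50).
#' @param nonactivatedAreaMin um^2, lower bound of `non_activated` (default 10).
#' @param matchRadius um, ground-truth matching radius (default 10).
#' @param sectorCount radial sectors (default 8).
#' @param analysisOuterRadius um, outer sector radius (default 724.5, giving an
#'   annulus of ~1.6 mm^2 with the default exclusion radius).
#' @param onhExclusionRadius um, ONH exclusion radius (default 125).
#' @param minComponentPx minimum component size in pixels (default 3).
#' @param peakSeparationMin um, peak separation for splitting touching cells
#'   (default 5).
#' @return A [MorphometryConfig-class] object.
#' @examples
#' cfg <- morphometryConfig()
#' classifyActivation(55, cfg)
#' @export
morphometryConfig <- function(cellThresholdK = 5,
                              somaRelativeThreshold = 0.6,
                              activationAreaMin = 50,
                              nonactivatedAreaMin = 10,
                              matchRadius = 10,
                              sectorCount = 8L,
                              analysisOuterRadius = 724.5,
                              onhExclusionRadius = 125,
                              minComponentPx = 3L,
                              peakSeparationMin = 5) {
  new("MorphometryConfig",
      cellThresholdK = as.numeric(cellThresholdK),
      somaRelativeThreshold = as.numeric(somaRelativeThreshold),
      activationAreaMin = as.numeric(activationAreaMin),
      nonactivatedAreaMin = as.numeric(nonactivatedAreaMin),
      matchRadius = as.numeric(matchRadius),
      sectorCount = as.integer(sectorCount),
      analysisOuterRadius = as.numeric(analysisOuterRadius),
      onhExclusionRadius = as.numeric(onhExclusionRadius),
      minComponentPx = as.integer(minComponentPx),
      peakSeparationMin = as.numeric(peakSeparationMin))
}

#' GliosisConfig: parameters for non-axonal area segmentation
#'
#' @slot method `"otsu"` (automatic threshold on the red channel restricted to
#'   the eligible nerve region) or `"fixed"` (use `fixedThreshold`).
#' @slot fixedThreshold intensity threshold in [0, 1] used when
#'   `method = "fixed"`.
#' @slot minObjectArea um^2; glial components smaller than this are removed as
#'   speckle.
#' @slot minHoleArea um^2; holes smaller than this are filled.
#' @seealso [gliosisConfig()], [segmentNonaxonal()]
#' @export
setClass("GliosisConfig",
  representation(
    method = "character",
    fixedThreshold = "numeric",
    minObjectArea = "numeric",
    minHoleArea = "numeric"
  )
)

setValidity("GliosisConfig", function(object) {
  msg <- character()
  if (!object@method %in% c("otsu", "fixed"))
    msg <- c(msg, "method must be 'otsu' or 'fixed'")
  if (object@fixedThreshold < 0 || object@fixedThreshold > 1)
    msg <- c(msg, "fixedThreshold must lie in [0, 1]")
  if (object@minObjectArea < 0 || object@minHoleArea < 0)
    msg <- c(msg, "cleanup areas must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Build a gliosis segmentation configuration
#'
#' @param method `"otsu"` or `"fixed"`.
#' @param fixedThreshold threshold in [0, 1] for `method = "fixed"`
#'   (default 0.55).
#' @param minObjectArea um^2, speckle removal size (default 20).
#' @param minHoleArea um^2, hole fill size (default 20).
#' @return A [GliosisConfig-class] object.
#' @export
gliosisConfig <- function(method = c("otsu", "fixed"), fixedThreshold = 0.55,
                          minObjectArea = 20, minHoleArea = 20) {
  method <- match.arg(method)
  new("GliosisConfig", method = method, fixedThreshold = fixedThreshold,
      minObjectArea = minObjectArea, minHoleArea = minHoleArea)
}

## ---------------------------------------------------------------------------
## Result objects
## ---------------------------------------------------------------------------

#' GliosisResult: glial area fraction of one nerve section
#'
#' @slot sectionId character identifier.
#' @slot glialFraction percent of the eligible nerve area (nerve minus vessels
#'   and meninges) occupied by glia / gliotic scar.
#' @slot eligibleArea eligible nerve area in um^2.
#' @slot category damage category: `"low"` (< 20 percent), `"medium"`
#'   ([20, 40] percent) or `"high"` (> 40 percent).
#' @seealso [computeGlialFraction()], [classifyDamage()]
#' @export
setClass("GliosisResult",
  representation(
    sectionId = "character",
    glialFraction = "numeric",
    eligibleArea = "numeric",
    category = "character"
  )
)

setValidity("GliosisResult", function(object) {
  msg <- character()
  if (object@glialFraction < 0 || object@glialFraction > 100)
    msg <- c(msg, "glialFraction must be in [0, 100]")
  if (!object@category %in% c("low", "medium", "high"))
    msg <- c(msg, "category must be low/medium/high")
  if (!identical(object@category, classifyDamage(object@glialFraction)))
    msg <- c(msg, "category inconsistent with glialFraction bins")
  if (length(msg)) msg else TRUE
})

#' EyeTimeline: longitudinal ONH counts for one eye joined to its late outcome
#'
#' @slot eyeId character identifier.
#' @slot ages ages at imaging in months, strictly increasing.
#' @slot counts ONH cell counts at those ages.
#' @slot treated logical, whether the eye received treatment.
#' @slot lateGlialFraction late non-axonal area fraction (percent), or `NA`.
#' @slot lateCategory late damage category, or `NA`.
#' @seealso [buildTimelines()]
#' @export
setClass("EyeTimeline",
  representation(
    eyeId = "character",
    ages = "numeric",
    counts = "numeric",
    treated = "logical",
    lateGlialFraction = "numeric",
    lateCategory = "character"
  )
)

setValidity("EyeTimeline", function(object) {
  msg <- character()
  if (length(object@ages) != length(object@counts))
    msg <- c(msg, "ages and counts must have equal length")
  if (length(object@ages) > 1L && any(diff(object@ages) <= 0))
    msg <- c(msg, "ages must be strictly increasing")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TreatmentComparison: pre/post treatment comparison of ONH counts
#'
#' @slot nPairs number of eyes.
#' @slot meanPre,meanPost mean counts before / after treatment.
#' @slot meanDifference mean(post - pre); negative means a drop.
#' @slot nDecreased number of eyes whose count dropped post-treatment.
#' @slot statistic unpaired two-tailed Student t statistic.
#' @slot pValue its p-value.
#' @slot pairedStatistic,pairedPValue the paired t-test, reported in addition
#'   because the design is pre/post on the same eyes.
#' @seealso [compareTreatment()]
#' @export
setClass("TreatmentComparison",
  representation(
    nPairs = "integer",
    meanPre = "numeric",
    meanPost = "numeric",
    meanDifference = "numeric",
    nDecreased = "integer",
    statistic = "numeric",
    pValue = "numeric",
    pairedStatistic = "numeric",
    pairedPValue = "numeric"
  )
)

setValidity("TreatmentComparison", function(object) {
  if (object@nDecreased > object@nPairs)
    "nDecreased cannot exceed nPairs" else TRUE
})

#' StatResult: one statistical test outcome
#'
#' @slot name test name.
#' @slot statisticName symbol of the statistic (t, H, rho, ...).
#' @slot statistic its value.
#' @slot pValue p-value in [0, 1] (NA when degenerate).
#' @slot n sample size(s) used.
#' @slot method note on how the p-value was obtained (exact vs approximate).
#' @slot note extra detail (degeneracies, fallbacks).
#' @export
setClass("StatResult",
  representation(
    name = "character",
    statisticName = "character",
    statistic = "numeric",
    pValue = "numeric",
    n = "numeric",
    method = "character",
    note = "character"
  ),
  prototype(note = "")
)

setValidity("StatResult", function(object) {
  p <- object@pValue
  if (length(p) == 1L && !is.na(p) && (p < 0 || p > 1))
    "pValue must lie in [0, 1]" else TRUE
})

statResult <- function(name, statisticName, statistic, pValue, n,
                       method, note = "") {
  new("StatResult", name = name, statisticName = statisticName,
      statistic = as.numeric(statistic), pValue = as.numeric(pValue),
      n = as.numeric(n), method = method, note = note)
}
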