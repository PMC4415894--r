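#' Accessors for gliotrack objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a gliotrack S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelScale", function(object) standardGeneric("pixelScale"))
#' @rdname accessors
#' @export
setGeneric("onhCenter", function(object) standardGeneric("onhCenter"))
#' @rdname accessors
#' @export
setGeneric("eyeId", function(object) standardGeneric("eyeId"))
#' @rdname accessors
#' @export
setGeneric("ageMonths", function(object) standardGeneric("ageMonths"))
#' @rdname accessors
#' @export
setGeneric("imageData2d", function(object) standardGeneric("imageData2d"))
#' @rdname accessors
#' @export
setGeneric("glialFraction", function(object) standardGeneric("glialFraction"))
#' @rdname accessors
#' @export
setGeneric("damageCategory", function(object) standardGeneric("damageCategory"))
#' @rdname accessors
#' @export
setGeneric("eligibleArea", function(object) standardGeneric("eligibleArea"))
#' @rdname accessors
#' @export
setGeneric("statValue", function(object) standardGeneric("statValue"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
setMethod("pixelScale", "RetinaFrame", function(object) object@pixelScale)
#' @rdname accessors
setMethod("pixelScale", "NerveSection", function(object) object@pixelScale)
#' @rdname accessors
setMethod("onhCenter", "RetinaFrame", function(object) object@onhCenter)
#' @rdname accessors
setMethod("eyeId", "RetinaFrame", function(object) object@eyeId)
#' @rdname accessors
setMethod("eyeId", "EyeTimeline", function(object) object@eyeId)
#' @rdname accessors
setMethod("ageMonths", "RetinaFrame", function(object) object@ageMonths)
#' @rdname accessors
setMethod("ageMonths", "EyeTimeline", function(object) object@ages)
#' @rdname accessors
setMethod("imageData2d", "RetinaFrame", function(object) object@pixels)
#' @rdname accessors
setMethod("imageData2d", "NerveSection", function(object) object@pixels)
#' @rdname accessors
setMethod("glialFraction", "GliosisResult", function(object) object@glialFraction)
#' @rdname accessors
setMethod("damageCategory", "GliosisResult", function(object) object@category)
#' @rdname accessors
setMethod("eligibleArea", "GliosisResult", function(object) object@eligibleArea)
#' @rdname accessors
setMethod("statValue", "StatResult", function(object) object@statistic)
#' @rdname accessors
setMethod("pValue", "StatResult", function(object) object@pValue)
#' @rdname accessors
setMethod("pValue", "TreatmentComparison", function(object) object@pValue)

## show methods ---------------------------------------------------------------

setMethod("show", "RetinaFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RetinaFrame '%s' (age %s mo): %d x %d px at %.3g um/px, ONH at (%.0f, %.0f) um\n",
              object@eyeId, format(object@ageMonths), d[2L], d[1L],
              object@pixelScale, object@onhCenter[1L], object@onhCenter[2L]))
})

setMethod("show", "NerveSection", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NerveSection '%s': %d x %d px at %.3g um/px; nerve %.3g mm^2, vessels %d px, meninges %d px\n",
              object@sectionId, d[2L], d[1L], object@pixelScale,
              sum(object@nerveMask) * object@pixelScale^2 / 1e6,
              sum(object@vesselMask), sum(object@meningesMask)))
})

setMethod("show", "GliosisResult", function(object) {
  cat(sprintf("GliosisResult '%s': glial fraction %.2f%% of %.3g um^2 eligible nerve area -> %s gliosis\n",
              object@sectionId, object@glialFraction, object@eligibleArea,
              object@category))
})

setMethod("show", "EyeTimeline", function(object) {
  cat(sprintf("EyeTimeline '%s'%s: counts [%s] at months [%s]; late glial fraction %s (%s)\n",
              object@eyeId, if (isTRUE(object@treated)) " (treated)" else "",
              paste(object@counts, collapse = ", "),
              paste(object@ages, collapse = ", "),
              ifelse(is.na(object@lateGlialFraction), "NA",
                     sprintf("%.1f%%", object@lateGlialFraction)),
              object@lateCategory))
})

setMethod("show", "TreatmentComparison", function(object) {
  cat(sprintf("TreatmentComparison: n = %d eyes, mean pre %.2f, post %.2f (difference %.2f); %d/%d decreased\n",
              object@nPairs, object@meanPre, object@meanPost,
              object@meanDifference, object@nDecreased, object@nPairs))
  cat(sprintf("  unpaired two-tailed t = %.3f, p = %.4g; paired t = %.3f, p = %.4g\n",
              object@statistic, object@pValue,
              object@pairedStatistic, object@pairedPValue))
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult '%s': %s = %.4g, p = %.4g (n = %s; %s)%s\n",
              object@name, object@statisticName, object@statistic,
              object@pValue, paste(object@n, collapse = "/"), object@method,
              if (nzchar(object@note)) paste0(" [", object@note, "]") else ""))
})
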