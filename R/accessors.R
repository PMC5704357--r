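#' Accessors for BMEquant objects
#'
#' Small accessor functions in place of direct slot access.
#'
#' \describe{
#'   \item{voxels}{The raw 3D array of an [ImageVolume-class] or
#'     [RegionMask-class].}
#'   \item{spacing, sliceGapFraction, volumeId}{Voxel geometry and id of an
#'     [ImageVolume-class].}
#'   \item{roiCoords}{Coordinate matrix of a [ReferenceROI-class].}
#'   \item{lesions, nLesions}{Per-lesion records / count of a
#'     [LesionSet-class] or [QuantResult-class].}
#'   \item{volumeHyper, relIntensitySummary, threshold}{Summary metrics of a
#'     [QuantResult-class].}
#'   \item{rocPoints, rocAUC, optimalK}{Curve, area and Youden-optimal k of
#'     a [ThresholdROC-class].}
#'   \item{sensitivity, specificity}{TP/(TP+FN) and TN/(TN+FP) of an
#'     [AgreementTable-class]; NA when the denominator is 0.}
#' }
#'
#' @param x The object.
#' @param ... Further arguments (unused).
#' @return The slot value or derived scalar described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("voxels", "RegionMask", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("sliceGapFraction", "ImageVolume", function(x, ...) x@sliceGapFraction)

#' @rdname accessors
#' @export
setMethod("volumeId", "ImageVolume", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("volumeId", "RegionMask", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("roiCoords", "ReferenceROI", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("lesions", "LesionSet", function(x) x@lesions)

#' @rdname accessors
#' @export
setMethod("lesions", "QuantResult", function(x) x@lesions@lesions)

#' @rdname accessors
#' @export
setMethod("nLesions", "LesionSet", function(x) length(x@lesions))

#' @rdname accessors
#' @export
setMethod("nLesions", "QuantResult", function(x) x@nObjects)

#' @rdname accessors
#' @export
setMethod("volumeHyper", "QuantResult", function(x) x@volumeHyper)

#' @rdname accessors
#' @export
setMethod("relIntensitySummary", "QuantResult", function(x) x@relSummary)

#' @rdname accessors
#' @export
setMethod("threshold", "QuantResult", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("rocPoints", "ThresholdROC", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("rocAUC", "ThresholdROC", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("optimalK", "ThresholdROC", function(x) x@optimalK)

#' @rdname accessors
#' @export
setMethod("sensitivity", "AgreementTable", function(x) {
  if (x@TP + x@FN == 0L) NA_real_ else x@TP / (x@TP + x@FN)
})

#' @rdname accessors
#' @export
setMethod("specificity", "AgreementTable", function(x) {
  if (x@TN + x@FP == 0L) NA_real_ else x@TN / (x@TN + x@FP)
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume '%s': %d x %d x %d voxels\n",
              object@id, d[1], d[2], d[3]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, slice gap %.0f%%\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              100 * object@sliceGapFraction))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RegionMask '%s': %d x %d x %d, %d voxels set\n",
              object@id, d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "ReferenceROI", function(object) {
  cat(sprintf("ReferenceROI: %d voxels\n", nrow(object@coords)))
})

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet: %d lesion(s), voxel volume %.4g cm^3\n",
              length(object@lesions), object@voxelVolume))
})

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult '%s'\n", object@id))
  cat(sprintf("  threshold T = %.4g (ROI mean %.4g + k = %.3g x SD %.4g, n = %d)\n",
              object@threshold, object@roiMean, object@k, object@roiSD,
              object@roiN))
  cat(sprintf("  lesions: %d, volume_hyper = %.4g cm^3\n",
              object@nObjects, object@volumeHyper))
  if (object@nObjects > 0L) {
    s <- object@relSummary
    cat(sprintf("  S_RelHyper: mean %.3f, median %.3f, p75 %.3f, p90 %.3f\n",
                s["mean"], s["median"], s["p75"], s["p90"]))
  } else {
    cat("  S_RelHyper: absent (no lesions)\n")
  }
})

setMethod("show", "ThresholdROC", function(object) {
  cat(sprintf("ThresholdROC: %d grid points, %d positive / %d negative cases\n",
              nrow(object@points), object@nPositive, object@nNegative))
  cat(sprintf("  AUC = %.3f, optimal k (Youden) = %.3g\n",
              object@auc, object@optimalK))
})

setMethod("show", "AgreementTable", function(object) {
  cat("AgreementTable (reference in columns)\n")
  m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  cat(sprintf("  sensitivity = %.3f, specificity = %.3f\n",
              sensitivity(object), specificity(object)))
})
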