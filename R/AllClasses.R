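#' @import methods
NULL

#' ImageVolume: a 3D scalar MR volume with voxel geometry
#'
#' Container for one STIR image volume: a 3D array of non-negative signal
#' intensities together with the voxel spacing in mm and the inter-slice
#' gap expressed as a fraction of the slice thickness.
#'
#' All voxel indices in this package are 1-based \code{(row, column, slice)}
#' triplets on the array lattice; images and masks must share one lattice
#' (no resampling is provided).
#'
#' @slot voxels 3D numeric array of finite intensities.
#' @slot spacing Numeric length-3, (row, column, slice) spacing in mm; all
#'   components strictly positive. The slice component is the slice
#'   \emph{thickness}; any inter-slice gap is carried separately.
#' @slot sliceGapFraction Single non-negative number: gap between slices as
#'   a fraction of slice thickness (0.1 for a "10\% gap" protocol).
#' @slot id Opaque identifier string.
#'
#' @seealso [ImageVolume()], [readVolume()], [voxelVolume()]
#' @export
setClass("ImageVolume",
  representation(
    voxels = "array",
    spacing = "numeric",
    sliceGapFraction = "numeric",
    id = "character"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@voxels) && !all(is.finite(object@voxels)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive numbers (mm)")
  if (length(dim(object@voxels)) == 3L && any(dim(object@voxels) < 1L))
    msg <- c(msg, "grid dimensions must be >= 1 in each axis")
  if (length(object@sliceGapFraction) != 1L ||
      !is.finite(object@sliceGapFraction) || object@sliceGapFraction < 0)
    msg <- c(msg, "sliceGapFraction must be a single number >= 0")
  if (length(object@id) != 1L)
    msg <- c(msg, "id must be a single string")
  if (length(msg)) msg else TRUE
})

#' RegionMask: a binary 3D mask on an image lattice
#'
#' Binary mask on the same lattice as an [ImageVolume-class]: the manually
#' outlined bone-marrow segmentation, or a derived lesion mask.
#'
#' @slot voxels 3D logical array.
#' @slot id Opaque identifier string.
#'
#' @seealso [RegionMask()], [readMask()], [maskHyperintense()]
#' @export
setClass("RegionMask",
  representation(voxels = "array", id = "character")
)

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!is.logical(object@voxels))
    msg <- c(msg, "voxels must be logical")
  if (anyNA(object@voxels))
    msg <- c(msg, "mask may not contain NA")
  if (length(object@id) != 1L)
    msg <- c(msg, "id must be a single string")
  if (length(msg)) msg else TRUE
})

#' ReferenceROI: the normal-bone-marrow reference region
#'
#' Set of voxel coordinates placed in visibly healthy marrow (a circular ROI
#' of at least 200 voxels at a healthy vertebra, in the original protocol).
#' Its mean and SD define the lesion threshold \eqn{T = mean + k \cdot SD}
#' once evaluated on an image via [roiStats()].
#'
#' @slot coords Integer matrix, one row per voxel, columns
#'   (row, column, slice), 1-based, unique rows.
#'
#' @seealso [ReferenceROI()], [sphericalROI()], [roiStats()]
#' @export
setClass("ReferenceROI", representation(coords = "matrix"))

setValidity("ReferenceROI", function(object) {
  msg <- character()
  co <- object@coords
  if (ncol(co) != 3L)
    msg <- c(msg, "coords must have 3 columns (row, column, slice)")
  if (nrow(co) == 0L)
    msg <- c(msg, "ROI must contain at least one voxel")
  else {
    if (anyNA(co) || any(co < 1L) || any(co != round(co)))
      msg <- c(msg, "coords must be positive integer indices")
    if (anyDuplicated(co))
      msg <- c(msg, "coords must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' LesionSet: connected hyper-intense components surviving the size filter
#'
#' The labelled lesions of one image set. Each element of \code{lesions} is
#' a list with fields \code{label}, \code{coords} (n x 3 integer matrix),
#' \code{size} (voxel count), \code{volume} (cm^3), \code{sHyper} (voxel
#' intensities) and \code{sRelHyper} (relative intensities).
#'
#' @slot lesions List of per-lesion records (possibly empty).
#' @slot voxelVolume Single positive number, cm^3 per voxel used for the
#'   per-lesion volumes.
#'
#' @seealso [filterSmall()], [quantifyEdema()]
#' @export
setClass("LesionSet",
  representation(lesions = "list", voxelVolume = "numeric")
)

setValidity("LesionSet", function(object) {
  msg <- character()
  if (length(object@voxelVolume) != 1L || object@voxelVolume <= 0)
    msg <- c(msg, "voxelVolume must be a single positive number")
  ok <- vapply(object@lesions, function(l) {
    is.list(l) && all(c("label", "coords", "size", "volume",
                        "sHyper", "sRelHyper") %in% names(l))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each lesion needs label, coords, size, volume, sHyper, sRelHyper")
  if (length(msg)) msg else TRUE
})

#' QuantResult: thresholding summary for one image set
#'
#' Result of the full quantification pipeline on one image set: surviving
#' lesions, total hyper-intense volume, object count, pooled relative
#' intensity summaries, and a snapshot of the reference-ROI statistics and
#' threshold that produced them.
#'
#' With no surviving lesions, \code{volumeHyper} is 0 and the four relative
#' intensity summaries are \code{NA} (absent, not zero), so cohort means can
#' include zeros for volume but restrict intensity summaries to
#' lesion-positive sets.
#'
#' @slot lesions A [LesionSet-class].
#' @slot volumeHyper Total lesion volume, cm^3.
#' @slot nObjects Number of surviving lesions.
#' @slot relSummary Named numeric: \code{mean}, \code{median}, \code{p75},
#'   \code{p90} of the pooled per-voxel relative intensities (NA when no
#'   lesions).
#' @slot roiMean,roiSD,roiN Reference-ROI statistics used.
#' @slot threshold The absolute intensity threshold \eqn{T = mean + k\,SD}.
#' @slot k SD multiplier used.
#' @slot id Image-set identifier.
#'
#' @seealso [quantifyEdema()], [volumeHyper()], [relIntensitySummary()]
#' @export
setClass("QuantResult",
  representation(
    lesions = "LesionSet",
    volumeHyper = "numeric",
    nObjects = "integer",
    relSummary = "numeric",
    roiMean = "numeric",
    roiSD = "numeric",
    roiN = "integer",
    threshold = "numeric",
    k = "numeric",
    id = "character"
  )
)

setValidity("QuantResult", function(object) {
  msg <- character()
  if (!identical(names(object@relSummary), c("mean", "median", "p75", "p90")))
    msg <- c(msg, "relSummary must be named mean, median, p75, p90")
  if (object@nObjects != length(object@lesions@lesions))
    msg <- c(msg, "nObjects must equal the number of lesions")
  if (object@nObjects == 0L) {
    if (object@volumeHyper != 0)
      msg <- c(msg, "volumeHyper must be 0 with no lesions")
    if (!all(is.na(object@relSummary)))
      msg <- c(msg, "relSummary must be NA (absent) with no lesions")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdROC: ROC curve over the SD-multiplier grid
#'
#' ROC curve produced by sweeping the SD multiplier k over a grid and
#' classifying each case as test-positive when at least one lesion survives
#' the pipeline. Sensitivity is non-increasing and specificity non-decreasing
#' in k (threshold monotonicity).
#'
#' @slot points data.frame with columns \code{k}, \code{sensitivity},
#'   \code{specificity}, \code{youden}, ordered by increasing k.
#' @slot auc Trapezoidal area under the (1 - specificity, sensitivity)
#'   curve with the (0,0) and (1,1) corners appended.
#' @slot optimalK The k maximizing Youden's J; ties broken toward larger k.
#' @slot nPositive,nNegative Case counts behind the curve.
#'
#' @seealso [sweepK()], [rocAUC()], [optimalK()]
#' @export
setClass("ThresholdROC",
  representation(
    points = "data.frame",
    auc = "numeric",
    optimalK = "numeric",
    nPositive = "integer",
    nNegative = "integer"
  )
)

setValidity("ThresholdROC", function(object) {
  msg <- character()
  p <- object@points
  need <- c("k", "sensitivity", "specificity", "youden")
  if (!all(need %in% names(p)))
    msg <- c(msg, "points needs columns k, sensitivity, specificity, youden")
  else {
    if (is.unsorted(p$k, strictly = TRUE))
      msg <- c(msg, "k must be strictly increasing")
    if (any(p$sensitivity < 0 | p$sensitivity > 1) ||
        any(p$specificity < 0 | p$specificity > 1))
      msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' AgreementTable: 2x2 confusion counts against a reference standard
#'
#' Cross-tabulation of a binary test (thresholding: any lesion present)
#' against a binary reference (e.g. SPARCC score > 0), with sensitivity
#' TP/(TP+FN) and specificity TN/(TN+FP). A zero denominator yields NA
#' (undefined), never 0/0 coerced to a number.
#'
#' @slot TP,FP,FN,TN Non-negative integer cell counts.
#'
#' @seealso [confusionTable()], [confusionFromCounts()], [sensitivity()],
#'   [specificity()]
#' @export
setClass("AgreementTable",
  representation(TP = "integer", FP = "integer", FN = "integer",
                 TN = "integer")
)

setValidity("AgreementTable", function(object) {
  cells <- c(object@TP, object@FP, object@FN, object@TN)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0L))
    "TP, FP, FN, TN must be single non-negative integers"
  else TRUE
})

#' PhantomConfig: parameters of the synthetic STIR phantom
#'
#' Describes a synthetic STIR-like volume: homogeneous marrow inside a
#' rectangular bone region, surrounding soft tissue, bright ellipsoidal
#' lesions of controlled contrast, an optional smooth multiplicative bias
#' field (coil inhomogeneity), and additive Gaussian or Rician noise.
#'
#' @slot dim Integer length-3 grid dimensions (rows, columns, slices).
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot sliceGapFraction Inter-slice gap as a fraction of slice thickness.
#' @slot muBone,sigmaBone Marrow mean intensity and noise SD (sigmaBone > 0).
#' @slot muBackground,sigmaBackground Soft-tissue mean and noise SD.
#' @slot boneBox Integer length-6 (r1, r2, c1, c2, s1, s2): inclusive bounds
#'   of the bone region.
#' @slot lesions List of lesions, each a list with \code{center} (length-3),
#'   \code{semiAxes} (length-3, voxels, each >= 1) and \code{delta}
#'   (contrast as a multiple of sigmaBone).
#' @slot biasAmplitude Peak fractional intensity gain beta of the bias field
#'   (0 disables it).
#' @slot biasCenter Numeric length-3 bump center (voxel units).
#' @slot biasScale Numeric length-3 Gaussian smoothness scale (voxels).
#' @slot noiseModel "gaussian" or "rician".
#' @slot roiCenter,roiRadius,roiSlices Reference-ROI placement: an in-plane
#'   disc of the given radius stacked over \code{roiSlices} slices.
#'
#' @seealso [phantomConfig()], [generatePhantom()]
#' @export
setClass("PhantomConfig",
  representation(
    dim = "integer",
    spacing = "numeric",
    sliceGapFraction = "numeric",
    muBone = "numeric",
    sigmaBone = "numeric",
    muBackground = "numeric",
    sigmaBackground = "numeric",
    boneBox = "integer",
    lesions = "list",
    biasAmplitude = "numeric",
    biasCenter = "numeric",
    biasScale = "numeric",
    noiseModel = "character",
    roiCenter = "numeric",
    roiRadius = "numeric",
    roiSlices = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (object@sigmaBone <= 0)
    msg <- c(msg, "sigmaBone must be > 0")
  if (object@biasAmplitude < 0)
    msg <- c(msg, "biasAmplitude must be >= 0")
  if (length(object@boneBox) != 6L)
    msg <- c(msg, "boneBox must be 6 integers (r1, r2, c1, c2, s1, s2)")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'rician'")
  for (les in object@lesions) {
    if (!all(c("center", "semiAxes", "delta") %in% names(les))) {
      msg <- c(msg, "each lesion needs center, semiAxes, delta")
      break
    }
    if (any(les$semiAxes < 1))
      msg <- c(msg, "lesion semi-axes must be >= 1 voxel")
  }
  if (length(msg)) msg else TRUE
})
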