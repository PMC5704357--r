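#' Configure a synthetic STIR phantom
#'
#' Builds a [PhantomConfig-class] describing a synthetic STIR-like volume:
#' a rectangular bone-marrow region of homogeneous mean intensity inside
#' darker soft tissue, bright ellipsoidal edema lesions of controlled
#' contrast, an optional smooth multiplicative bias field emulating coil
#' proximity, and additive Gaussian (default) or Rician noise.
#'
#' Defaults mirror a typical spine STIR acquisition: 64 x 64 in-plane
#' voxels of 1 x 1 mm over 16 slices of 4 mm with a 10\% inter-slice gap;
#' marrow at 100 +/- 10 arbitrary units against soft tissue at 60 +/- 10,
#' and a 227-voxel circular reference ROI in lesion-free marrow
#' (the protocol asks for at least 200).
#'
#' @param dim Grid dimensions (rows, columns, slices).
#' @param spacing Voxel spacing in mm.
#' @param sliceGapFraction Gap between slices / slice thickness.
#' @param muBone,sigmaBone Marrow mean intensity and noise SD.
#' @param muBackground,sigmaBackground Soft-tissue mean and noise SD.
#' @param boneBox Inclusive bounds (r1, r2, c1, c2, s1, s2) of the bone
#'   region.
#' @param lesions List of lesions: each \code{list(center, semiAxes,
#'   delta)} with center and semi-axes in voxels and contrast delta in
#'   multiples of \code{sigmaBone}.
#' @param biasAmplitude Peak fractional gain beta of the bias field (0
#'   disables).
#' @param biasCenter,biasScale Center and Gaussian scale (voxels) of the
#'   bias bump.
#' @param noiseModel "gaussian" or "rician" (magnitude MR noise).
#' @param roiCenter,roiRadius,roiSlices Reference-ROI placement: in-plane
#'   disc replicated over the given slices.
#' @return A validated [PhantomConfig-class].
#' @export
phantomConfig <- function(dim = c(64L, 64L, 16L), spacing = c(1, 1, 4),
                          sliceGapFraction = 0.1,
                          muBone = 100, sigmaBone = 10,
                          muBackground = 60, sigmaBackground = 10,
                          boneBox = c(17L, 48L, 17L, 48L, 2L, 15L),
                          lesions = list(),
                          biasAmplitude = 0,
                          biasCenter = dim / 2, biasScale = dim,
                          noiseModel = c("gaussian", "rician"),
                          roiCenter = c(32, 32), roiRadius = 8.5,
                          roiSlices = 3L) {
  noiseModel <- match.arg(noiseModel)
  new("PhantomConfig", dim = as.integer(dim), spacing = as.numeric(spacing),
      sliceGapFraction = as.numeric(sliceGapFraction),
      muBone = as.numeric(muBone), sigmaBone = as.numeric(sigmaBone),
      muBackground = as.numeric(muBackground),
      sigmaBackground = as.numeric(sigmaBackground),
      boneBox = as.integer(boneBox), lesions = lesions,
      biasAmplitude = as.numeric(biasAmplitude),
      biasCenter = as.numeric(biasCenter), biasScale = as.numeric(biasScale),
      noiseModel = noiseModel, roiCenter = as.numeric(roiCenter),
      roiRadius = as.numeric(roiRadius), roiSlices = as.integer(roiSlices))
}

.ellipsoidMask <- function(dim, center, semiAxes) {
  r <- seq_len(dim[1]); c <- seq_len(dim[2]); s <- seq_len(dim[3])
  dr2 <- ((r - center[1]) / semiAxes[1])^2
  dc2 <- ((c - center[2]) / semiAxes[2])^2
  ds2 <- ((s - center[3]) / semiAxes[3])^2
  arr <- outer(outer(dr2, dc2, `+`), ds2, `+`)
  arr <= 1
}

#' Generate a synthetic STIR phantom with ground truth
#'
#' Realizes a [PhantomConfig-class] into an image volume, the bone-marrow
#' mask, the ground-truth lesion mask (the geometric ellipsoids, not the
#' post-noise supra-threshold set) and a [ReferenceROI-class] in
#' lesion-free marrow. Lesion voxels have expected intensity
#' \eqn{\mu_{bone} (1 + bias) + \Delta \sigma_{bone}}. Output is
#' deterministic for a fixed seed.
#'
#' A lesion reaching outside the bone region, or an ROI overlapping a
#' lesion or leaving the bone region, is an error: the reference ROI must
#' sample healthy marrow.
#'
#' @param config A [PhantomConfig-class].
#' @param seed Integer RNG seed; NULL uses the current RNG state.
#' @return List with elements \code{image} ([ImageVolume-class]),
#'   \code{bone} ([RegionMask-class]), \code{truth} ([RegionMask-class],
#'   the lesion ellipsoids), \code{roi} ([ReferenceROI-class]).
#' @examples
#' ph <- generatePhantom(phantomConfig(), seed = 7)
#' ph$image
#' @export
generatePhantom <- function(config, seed = NULL) {
  stopifnot(is(config, "PhantomConfig"))
  if (!is.null(seed)) set.seed(seed)
  d <- config@dim
  bb <- config@boneBox
  if (bb[1] < 1L || bb[3] < 1L || bb[5] < 1L ||
      bb[2] > d[1] || bb[4] > d[2] || bb[6] > d[3] ||
      bb[1] > bb[2] || bb[3] > bb[4] || bb[5] > bb[6])
    stop("boneBox outside grid or degenerate")

  bone <- array(FALSE, dim = d)
  bone[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6]] <- TRUE

  truth <- array(FALSE, dim = d)
  for (les in config@lesions) {
    m <- .ellipsoidMask(d, les$center, les$semiAxes)
    if (any(m & !bone))
      stop("lesion extends outside the bone region")
    truth <- truth | m
  }

  base <- array(config@muBackground, dim = d)
  base[bone] <- config@muBone
  if (config@biasAmplitude > 0) {
    r <- seq_len(d[1]); c <- seq_len(d[2]); s <- seq_len(d[3])
    gr <- exp(-0.5 * ((r - config@biasCenter[1]) / config@biasScale[1])^2)
    gc <- exp(-0.5 * ((c - config@biasCenter[2]) / config@biasScale[2])^2)
    gs <- exp(-0.5 * ((s - config@biasCenter[3]) / config@biasScale[3])^2)
    bias <- 1 + config@biasAmplitude * outer(outer(gr, gc), gs)
    base <- base * bias
  }
  # additive lesion contrast on top of the (bias-scaled) marrow signal;
  # overlapping lesions take the larger contrast, not the sum
  if (length(config@lesions)) {
    add <- array(0, dim = d)
    for (les in config@lesions) {
      m <- .ellipsoidMask(d, les$center, les$semiAxes)
      add[m] <- pmax(add[m], les$delta * config@sigmaBone)
    }
    base <- base + add
  }

  sigma <- array(config@sigmaBackground, dim = d)
  sigma[bone] <- config@sigmaBone
  if (config@noiseModel == "gaussian") {
    img <- base + stats::rnorm(length(base), 0, 1) * sigma
    img <- pmax(img, 0)
  } else {
    a <- stats::rnorm(length(base), 0, 1) * sigma
    b <- stats::rnorm(length(base), 0, 1) * sigma
    img <- sqrt((base + a)^2 + b^2)
  }
  img <- array(img, dim = d)

  roi <- sphericalROI(config@roiCenter, config@roiRadius, config@roiSlices, d)
  co <- roiCoords(roi)
  if (any(!bone[co]))
    stop("reference ROI leaves the bone region")
  if (any(truth[co]))
    stop("reference ROI overlaps a lesion; place it in healthy marrow")

  list(
    image = ImageVolume(img, spacing = config@spacing,
                        sliceGapFraction = config@sliceGapFraction,
                        id = "phantom"),
    bone = new("RegionMask", voxels = bone, id = "phantom_bone"),
    truth = new("RegionMask", voxels = truth, id = "phantom_truth"),
    roi = roi
  )
}

#' Generate a labelled phantom cohort for calibration
#'
#' Convenience wrapper producing \code{nPositive} phantoms carrying one
#' ellipsoidal lesion of contrast \code{delta} (position and size mildly
#' jittered) and \code{nNegative} lesion-free phantoms, each as a case
#' ready for [sweepK()].
#'
#' @param nPositive,nNegative Case counts.
#' @param delta Lesion contrast in multiples of the marrow noise SD.
#' @param seed Integer seed controlling all randomness.
#' @param config Base [PhantomConfig-class]; its lesion list is replaced
#'   per case.
#' @return List of cases (image, bone, roi, truth, positive).
#' @export
phantomCohort <- function(nPositive, nNegative, delta = 10, seed = 1,
                          config = phantomConfig()) {
  set.seed(seed)
  n <- nPositive + nNegative
  caseSeeds <- sample.int(.Machine$integer.max, n)
  bb <- config@boneBox
  # lesion placement derived from the bone region, kept clear of the
  # reference-ROI slices so the ROI always samples healthy marrow
  axIn <- c(3.5, 4.5); axSl <- c(1.5, 2)
  midR <- (bb[1] + bb[2]) / 2; midC <- (bb[3] + bb[4]) / 2
  sliceLo <- max(config@roiSlices) + max(axSl) + 1.6
  sliceHi <- bb[6] - max(axSl) - 0.1
  if (sliceLo >= sliceHi)
    stop("bone region too thin to place lesions clear of the ROI slices")
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    positive <- i <= nPositive
    cfg <- config
    if (positive) {
      ctr <- c(midR + stats::runif(1, -2, 2), midC + stats::runif(1, -2, 2),
               stats::runif(1, sliceLo, sliceHi))
      ax <- c(stats::runif(1, axIn[1], axIn[2]),
              stats::runif(1, axIn[1], axIn[2]),
              stats::runif(1, axSl[1], axSl[2]))
      cfg@lesions <- list(list(center = ctr, semiAxes = ax, delta = delta))
    } else {
      cfg@lesions <- list()
    }
    ph <- generatePhantom(cfg, seed = caseSeeds[i])
    cases[[i]] <- list(image = ph$image, bone = ph$bone, roi = ph$roi,
                       truth = ph$truth, positive = positive)
  }
  cases
}
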