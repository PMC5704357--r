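#' Reference-ROI statistics
#'
#' Mean, SD (sample SD, n - 1 denominator) and voxel count of the image
#' intensities inside the reference normal-bone-marrow ROI. These define
#' the lesion threshold via [computeThreshold()]. ROIs smaller than the
#' protocol's 200 voxels trigger a warning: the SD, and hence the
#' threshold, is then less stable.
#'
#' @param image [ImageVolume-class].
#' @param roi [ReferenceROI-class]; all coordinates must lie inside the
#'   image grid.
#' @return Named list: \code{mean}, \code{sd}, \code{n}.
#' @export
roiStats <- function(image, roi) {
  co <- roiCoords(roi)
  d <- dim(voxels(image))
  if (any(co[, 1] > d[1] | co[, 2] > d[2] | co[, 3] > d[3]))
    stop("ROI coordinates outside image grid")
  vals <- voxels(image)[co]
  n <- length(vals)
  if (n < 200L)
    warning(sprintf("reference ROI has only %d voxels (< 200)", n))
  list(mean = mean(vals), sd = stats::sd(vals), n = n)
}

#' Lesion threshold from ROI statistics
#'
#' The signal-intensity threshold consistent with inflammation:
#' \eqn{T = mean + k \cdot SD} of the reference normal-bone-marrow ROI.
#' The calibrated multipliers are k = 4.15 for the spine and k = 2.64 for
#' the sacroiliac joints (see [presetK()]).
#'
#' @param mean,sd ROI mean and SD (sd >= 0).
#' @param k Non-negative SD multiplier.
#' @return The threshold T.
#' @examples
#' computeThreshold(100, 10, 4.15)  # 141.5
#' @export
computeThreshold <- function(mean, sd, k) {
  if (!is.finite(sd) || sd < 0) stop("sd must be a finite number >= 0")
  if (!is.finite(k) || k < 0) stop("k must be a finite number >= 0")
  mean + k * sd
}

#' Calibrated SD multipliers per anatomy
#'
#' @param preset "spine" (k = 4.15) or "si" (sacroiliac joints, k = 2.64).
#' @return The default k for that anatomy.
#' @export
presetK <- function(preset = c("spine", "si")) {
  preset <- match.arg(preset)
  c(spine = 4.15, si = 2.64)[[preset]]
}

#' Supra-threshold voxels within the bone mask
#'
#' Selects the voxels consistent with inflammation: inside the bone-marrow
#' mask AND with intensity strictly greater than the threshold T (a voxel
#' exactly at T is not selected).
#'
#' @param image [ImageVolume-class].
#' @param bone [RegionMask-class] on the same grid.
#' @param T Intensity threshold.
#' @return A [RegionMask-class] of hyper-intense bone voxels.
#' @export
maskHyperintense <- function(image, bone, T) {
  .checkSameGrid(dim(voxels(bone)), dim(voxels(image)))
  sel <- voxels(bone) & (voxels(image) > T)
  new("RegionMask", voxels = sel, id = paste0(volumeId(image), "_hyper"))
}

.offsets3d <- function(connectivity) {
  g <- as.matrix(expand.grid(r = -1:1, c = -1:1, s = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    "4" = rowSums(abs(g)) == 1 & g[, 3] == 0,
    "8" = rowSums(abs(g) > 0) >= 1 & g[, 3] == 0,
    stop("connectivity must be 6, 18 or 26 (3D) or 4, 8 (per-slice 2D)"))
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Label connected components of a binary mask
#'
#' Partitions the TRUE voxels into maximal connected sets under the chosen
#' adjacency. 3D connectivities 6, 18 and 26 operate across slices; 4 and 8
#' operate within each slice only (per-slice 2D mode: voxels in different
#' slices are never connected).
#'
#' @param mask [RegionMask-class].
#' @param connectivity One of 6, 18, 26 (3D) or 4, 8 (2D in-plane).
#' @return Integer 3D array of the mask's dimensions: 0 for background,
#'   1..K labelling the K components.
#' @export
labelComponents <- function(mask, connectivity = 26) {
  v <- voxels(mask)
  lab <- cc_label(as.logical(v), as.integer(dim(v)),
                  .offsets3d(connectivity))
  array(lab, dim = dim(v))
}

#' Remove components smaller than a minimum voxel count
#'
#' Components with fewer than \code{minSize} voxels are considered noise
#' artefacts and dropped (default 10: a 10-voxel object survives, a 9-voxel
#' object does not). Survivors are relabelled 1..K in order of their
#' original labels.
#'
#' @param labels Integer label array from [labelComponents()].
#' @param minSize Minimum voxel count (>= 1).
#' @return Integer label array of the surviving components.
#' @export
filterSmall <- function(labels, minSize = 10L) {
  minSize <- as.integer(minSize)
  if (minSize < 1L) stop("minSize must be >= 1")
  K <- max(labels)
  if (K == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = K)
  keep <- which(sizes >= minSize)
  remap <- integer(K)
  remap[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  out
}

#' Relative signal intensity of a hyper-intense voxel
#'
#' Normalizes a hyper-intense signal to the reference normal-bone-marrow
#' mean: \eqn{S_{RelHyper} = (S_{hyper} - \bar S_{bone}) / \bar S_{bone}}.
#' A voxel at the marrow mean scores 0; one at twice the mean scores 1.
#'
#' @param sHyper Voxel intensity (vectorized).
#' @param roiMean Reference-ROI mean intensity (> 0).
#' @return Relative intensity value(s).
#' @export
relativeIntensity <- function(sHyper, roiMean) {
  if (!is.finite(roiMean) || roiMean <= 0)
    stop("roiMean must be a positive number")
  (sHyper - roiMean) / roiMean
}

#' Build a LesionSet from filtered component labels
#'
#' Collects each surviving component's voxel coordinates, intensities and
#' relative intensities into a [LesionSet-class].
#'
#' @param labels Filtered integer label array (see [filterSmall()]).
#' @param image [ImageVolume-class] the labels were derived from.
#' @param roiMean Reference-ROI mean used for relative intensities.
#' @param vv Voxel volume in cm^3 (see [voxelVolume()]).
#' @return A [LesionSet-class].
#' @export
lesionSetFromLabels <- function(labels, image, roiMean, vv) {
  K <- max(labels)
  les <- vector("list", K)
  if (K > 0L) {
    idx <- which(labels > 0L)
    ord <- order(labels[idx])
    idx <- idx[ord]
    labv <- labels[idx]
    co <- arrayInd(idx, dim(labels))
    vals <- voxels(image)[idx]
    splitIdx <- split(seq_along(idx), labv)
    for (j in seq_len(K)) {
      ii <- splitIdx[[j]]
      cm <- co[ii, , drop = FALSE]
      colnames(cm) <- c("row", "col", "slice")
      les[[j]] <- list(
        label = j,
        coords = cm,
        size = length(ii),
        volume = length(ii) * vv,
        sHyper = vals[ii],
        sRelHyper = relativeIntensity(vals[ii], roiMean)
      )
    }
  }
  new("LesionSet", lesions = les, voxelVolume = vv)
}

#' Summarize a LesionSet into a QuantResult
#'
#' Total hyper-intense volume (surviving voxel count times voxel volume),
#' object count, and the mean, median, 75th and 90th percentile of the
#' relative intensities pooled over ALL surviving voxels of the image set
#' (not per-lesion means). Percentiles interpolate linearly between order
#' statistics at rank \eqn{p (n - 1) + 1}. With no lesions the volume is 0
#' and the intensity summaries are NA (absent).
#'
#' @param lesionSet [LesionSet-class].
#' @param roiMean,roiSD,roiN,threshold,k Snapshot of the ROI statistics and
#'   threshold that produced the lesions.
#' @param id Image-set identifier.
#' @return A [QuantResult-class].
#' @export
summarizeLesions <- function(lesionSet, roiMean = NA_real_, roiSD = NA_real_,
                             roiN = NA_integer_, threshold = NA_real_,
                             k = NA_real_, id = "set") {
  les <- lesions(lesionSet)
  nObj <- length(les)
  if (nObj > 0L) {
    pooled <- unlist(lapply(les, `[[`, "sRelHyper"), use.names = FALSE)
    nvox <- sum(vapply(les, `[[`, integer(1), "size"))
    vol <- nvox * lesionSet@voxelVolume
    qs <- stats::quantile(pooled, c(0.75, 0.90), type = 7, names = FALSE)
    rel <- c(mean = mean(pooled), median = stats::median(pooled),
             p75 = qs[1], p90 = qs[2])
  } else {
    vol <- 0
    rel <- c(mean = NA_real_, median = NA_real_, p75 = NA_real_,
             p90 = NA_real_)
  }
  new("QuantResult", lesions = lesionSet, volumeHyper = vol,
      nObjects = nObj, relSummary = rel, roiMean = as.numeric(roiMean),
      roiSD = as.numeric(roiSD), roiN = as.integer(roiN),
      threshold = as.numeric(threshold), k = as.numeric(k),
      id = as.character(id))
}

#' Quantify bone marrow edema in one image set
#'
#' The full thresholding pipeline for one image set: reference-ROI
#' statistics, threshold \eqn{T = mean + k \cdot SD}, supra-threshold
#' masking within the bone-marrow segmentation, connected-component
#' labelling, removal of components below \code{minSize} voxels, and
#' volumetric / relative-intensity summaries.
#'
#' @param image [ImageVolume-class]; histogram-match it first with
#'   [matchHistogram()] when combining sets of differing brightness.
#' @param bone [RegionMask-class] bone-marrow segmentation, same grid.
#' @param roi [ReferenceROI-class] in healthy marrow.
#' @param preset "spine" (k = 4.15), "si" (k = 2.64) or "custom".
#' @param k SD multiplier; overrides the preset default when given.
#' @param connectivity Component adjacency (6/18/26 in 3D, 4/8 per-slice).
#' @param minSize Minimum component size in voxels (default 10).
#' @param includeGap Include the inter-slice gap in voxel volume?
#' @param id Identifier for the result; defaults to the image id.
#' @return A [QuantResult-class].
#' @examples
#' ph <- generatePhantom(phantomConfig(
#'   lesions = list(list(center = c(32, 32, 8), semiAxes = c(6, 6, 3),
#'                       delta = 10))), seed = 1)
#' quantifyEdema(ph$image, ph$bone, ph$roi, preset = "spine")
#' @export
quantifyEdema <- function(image, bone, roi, preset = c("custom", "spine", "si"),
                          k = NULL, connectivity = 26, minSize = 10L,
                          includeGap = FALSE, id = NULL) {
  preset <- match.arg(preset)
  if (is.null(k)) {
    if (preset == "custom")
      stop("supply k or choose preset 'spine' or 'si'")
    k <- presetK(preset)
  }
  rs <- roiStats(image, roi)
  T <- computeThreshold(rs$mean, rs$sd, k)
  hyper <- maskHyperintense(image, bone, T)
  labels <- filterSmall(labelComponents(hyper, connectivity), minSize)
  vv <- voxelVolume(image, includeGap = includeGap)
  ls <- lesionSetFromLabels(labels, image, rs$mean, vv)
  summarizeLesions(ls, roiMean = rs$mean, roiSD = rs$sd, roiN = rs$n,
                   threshold = T, k = k,
                   id = if (is.null(id)) volumeId(image) else id)
}

#' Tidy per-set metrics table
#'
#' Flattens a list of [QuantResult-class] objects into one data.frame row
#' per image set, ready for joining with reference scores and for external
#' mixed-model tools.
#'
#' @param results List of [QuantResult-class].
#' @return data.frame with columns id, volume_hyper, n_objects,
#'   rel_mean, rel_median, rel_p75, rel_p90, roi_mean, roi_sd, roi_n,
#'   threshold, k.
#' @export
quantTable <- function(results) {
  rows <- lapply(results, function(r) {
    s <- relIntensitySummary(r)
    data.frame(id = r@id, volume_hyper = volumeHyper(r),
               n_objects = nLesions(r), rel_mean = s[["mean"]],
               rel_median = s[["median"]], rel_p75 = s[["p75"]],
               rel_p90 = s[["p90"]], roi_mean = r@roiMean, roi_sd = r@roiSD,
               roi_n = r@roiN, threshold = r@threshold, k = r@k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
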