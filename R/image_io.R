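#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing Numeric length-3 voxel spacing (row, column, slice) in mm.
#' @param sliceGapFraction Inter-slice gap as a fraction of slice thickness
#'   (0.1 for the typical "10\% gap" STIR protocol).
#' @param id Identifier string.
#' @return A validated [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(array(100, c(4, 4, 2)), spacing = c(1, 1, 4))
#' spacing(vol)
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), sliceGapFraction = 0,
                        id = "volume") {
  voxels <- array(as.double(voxels), dim = dim(voxels))
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      sliceGapFraction = as.numeric(sliceGapFraction), id = as.character(id))
}

#' Construct a RegionMask
#'
#' Any nonzero voxel is treated as inside the mask.
#'
#' @param voxels 3D array; coerced to logical via \code{!= 0}.
#' @param id Identifier string.
#' @param reference Optional [ImageVolume-class] whose grid the mask must
#'   match; a dimension mismatch is an error listing both shapes.
#' @return A validated [RegionMask-class].
#' @export
RegionMask <- function(voxels, id = "mask", reference = NULL) {
  v <- if (is.logical(voxels)) array(as.vector(voxels), dim = dim(voxels))
       else array(as.numeric(voxels) != 0, dim = dim(voxels))
  if (!is.null(reference)) .checkSameGrid(dim(v), dim(voxels(reference)))
  new("RegionMask", voxels = v, id = as.character(id))
}

.checkSameGrid <- function(dimMask, dimRef) {
  if (!identical(as.integer(dimMask), as.integer(dimRef)))
    stop(sprintf("grid mismatch: mask is %s but image is %s",
                 paste(dimMask, collapse = "x"),
                 paste(dimRef, collapse = "x")))
  invisible(TRUE)
}

#' Construct a ReferenceROI from voxel coordinates
#'
#' The reference normal-bone-marrow region. The original protocol used a
#' circular ROI of at least 200 pixels at a healthy vertebra; a smaller ROI
#' is accepted with a warning (its SD estimate is less stable).
#'
#' @param coords Integer matrix with one (row, column, slice) triplet per
#'   voxel, 1-based.
#' @return A validated [ReferenceROI-class].
#' @seealso [sphericalROI()] to build coordinates from a center and radius.
#' @export
ReferenceROI <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("row", "col", "slice")
  obj <- new("ReferenceROI", coords = coords)
  if (nrow(coords) < 200L)
    warning(sprintf("reference ROI has only %d voxels (< 200); threshold may be unstable",
                    nrow(coords)))
  obj
}

#' Build a disc/sphere-like ROI from center, radius and slices
#'
#' In-plane disc of the given radius (in voxels) around \code{center},
#' replicated over the listed slices — the digital analogue of the circular
#' ROI drawn on one or a few slices.
#'
#' @param center Length-2 (row, column) in-plane center.
#' @param radius In-plane radius in voxels.
#' @param slices Integer vector of slice indices.
#' @param dim Grid dimensions used for bounds checking.
#' @return A [ReferenceROI-class].
#' @export
sphericalROI <- function(center, radius, slices, dim) {
  rr <- seq_len(dim[1]); cc <- seq_len(dim[2])
  inPlane <- which(outer((rr - center[1])^2, (cc - center[2])^2, `+`)
                   <= radius^2, arr.ind = TRUE)
  if (nrow(inPlane) == 0L) stop("ROI radius selects no voxels")
  if (any(slices < 1L) || any(slices > dim[3]))
    stop("ROI slices outside grid")
  coords <- do.call(rbind, lapply(as.integer(slices), function(s)
    cbind(inPlane, s)))
  ReferenceROI(coords)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into an [ImageVolume-class], taking the voxel
#' spacing from the header pixdim. NIfTI stores one slice spacing and no
#' separate slice thickness, so the inter-slice gap is not derivable from
#' the header; it defaults to 0 with a note, and can be supplied explicitly
#' (see [deriveSliceGap()] for deriving it from DICOM-style metadata).
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param sliceGapFraction Gap fraction to attach; NULL means 0 with a note.
#' @param id Identifier; defaults to the file name.
#' @return An [ImageVolume-class].
#' @export
readVolume <- function(path, sliceGapFraction = NULL, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read '%s' as NIfTI: %s", path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) > 3L) {
    if (prod(dim(arr)[-(1:3)]) != 1L)
      stop(sprintf("'%s' has %d dimensions; expected a 3D volume",
                   path, length(dim(arr))))
    dim(arr) <- dim(arr)[1:3]
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (anyNA(sp) || any(!is.finite(sp)))
    stop(sprintf("'%s': missing voxel spacing (pixdim) in header", path))
  if (any(sp <= 0))
    stop(sprintf("'%s': non-positive voxel spacing in header", path))
  if (is.null(sliceGapFraction)) {
    message("slice gap not stored in NIfTI header; using 0")
    sliceGapFraction <- 0
  }
  if (is.null(id)) id <- basename(path)
  ImageVolume(arr, spacing = sp, sliceGapFraction = sliceGapFraction, id = id)
}

#' Write a volume or mask as NIfTI
#'
#' @param x An [ImageVolume-class] or [RegionMask-class].
#' @param path Output path (.nii or .nii.gz).
#' @param spacing Spacing to store for a mask (masks carry none; defaults
#'   to 1 mm isotropic).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path, spacing = c(1, 1, 1)) {
  if (is(x, "ImageVolume")) {
    arr <- voxels(x); sp <- spacing(x)
  } else if (is(x, "RegionMask")) {
    arr <- array(as.integer(voxels(x)), dim = dim(voxels(x))); sp <- spacing
  } else stop("x must be an ImageVolume or RegionMask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask matching a reference volume
#'
#' Any nonzero voxel becomes TRUE. The mask must live on the same lattice
#' as the reference image; no resampling is attempted.
#'
#' @param path NIfTI file.
#' @param reference The [ImageVolume-class] the mask annotates.
#' @param id Identifier; defaults to the file name.
#' @return A [RegionMask-class].
#' @export
readMask <- function(path, reference, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read '%s' as NIfTI: %s", path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  .checkSameGrid(dim(arr), dim(voxels(reference)))
  if (is.null(id)) id <- basename(path)
  RegionMask(arr, id = id)
}

#' Derive the slice-gap fraction from slice spacing and thickness
#'
#' DICOM series carry SpacingBetweenSlices and SliceThickness separately;
#' the gap fraction is their relative difference,
#' \eqn{(spacing - thickness) / thickness}. A 4.4 mm spacing over 4.0 mm
#' slices gives the typical 10\% gap.
#'
#' @param spacingBetweenSlices Center-to-center slice distance, mm.
#' @param sliceThickness Excited slice thickness, mm.
#' @return The gap fraction (>= 0; negative overlap is an error).
#' @export
deriveSliceGap <- function(spacingBetweenSlices, sliceThickness) {
  if (sliceThickness <= 0) stop("sliceThickness must be > 0")
  g <- (spacingBetweenSlices - sliceThickness) / sliceThickness
  if (g < 0) stop("slice spacing smaller than thickness (overlapping slices)")
  g
}

#' Physical volume of one voxel in cm^3
#'
#' Product of the in-plane spacings and the slice thickness, divided by
#' 1000 (mm^3 to cm^3). By default the inter-slice gap is excluded: lesion
#' signal is only sampled within the excited slice. With
#' \code{includeGap = TRUE} the slice dimension is inflated by
#' \code{1 + sliceGapFraction}, attributing the gap to the adjacent slice.
#'
#' @param volume An [ImageVolume-class].
#' @param includeGap Include the inter-slice gap in the per-voxel volume?
#' @return Voxel volume in cm^3.
#' @examples
#' v <- ImageVolume(array(0, c(2, 2, 2)), spacing = c(1, 1, 4),
#'                  sliceGapFraction = 0.1)
#' voxelVolume(v)                    # 0.004
#' voxelVolume(v, includeGap = TRUE) # 0.0044
#' @export
voxelVolume <- function(volume, includeGap = FALSE) {
  sp <- spacing(volume)
  f <- if (includeGap) 1 + sliceGapFraction(volume) else 1
  sp[1] * sp[2] * sp[3] * f / 1000
}

#' Read a reference-label table
#'
#' CSV with header \code{subject,image_set,slice,score}; \code{slice} is
#' empty for per-set scores. The binary reference label \code{positive} is
#' derived as \code{score > 0} (a positive SPARCC score marks the case
#' positive for bone marrow inflammatory edema).
#'
#' @param path CSV path.
#' @return data.frame with columns subject, image_set, slice, score,
#'   positive.
#' @export
readLabelTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "image_set", "slice", "score")
  if (!all(need %in% names(df)))
    stop(sprintf("label table must have columns %s",
                 paste(need, collapse = ", ")))
  if (anyNA(df$score) || any(df$score < 0))
    stop("scores must be non-negative numbers")
  df$slice <- suppressWarnings(as.integer(df$slice))
  df$positive <- df$score > 0
  df
}
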