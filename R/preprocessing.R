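#' Histogram-matching intensity normalization
#'
#' Transforms the intensity histogram of \code{image} to match that of
#' \code{reference}, so that image sets acquired with different overall
#' brightness become comparable before a single intensity threshold is
#' applied. The whole 3D volume is treated as one sample (per-slice
#' matching would break inter-slice intensity consistency).
#'
#' The mapping is a monotone quantile transform: intensities are binned on
#' \code{nBins} equal-width bins spanning the joint range of both volumes;
#' each voxel receives the cumulative probability of the image's binned
#' histogram, interpolated linearly inside its bin, and the output
#' intensity is the reference sample's inverse empirical CDF (type-1
#' quantile) at that probability. Rank order is preserved, so the
#' downstream supra-threshold voxel set is invariant to any strictly
#' monotone pre-transformation of the input followed by matching to the
#' same reference.
#'
#' A constant image maps to the reference median; a constant reference with
#' a non-constant image has no well-defined target histogram and is an
#' error.
#'
#' @param image [ImageVolume-class] to normalize.
#' @param reference [ImageVolume-class] providing the target histogram.
#' @param nBins Number of histogram bins (>= 2); default 256.
#' @return An [ImageVolume-class] on the grid of \code{image}.
#' @examples
#' set.seed(1)
#' ref <- ImageVolume(array(rnorm(1000, 200, 20), c(10, 10, 10)))
#' img <- ImageVolume(array(rnorm(1000, 50, 5), c(10, 10, 10)))
#' matched <- matchHistogram(img, ref)
#' range(voxels(matched))  # now on the reference intensity scale
#' @export
matchHistogram <- function(image, reference, nBins = 256L) {
  stopifnot(is(image, "ImageVolume"), is(reference, "ImageVolume"))
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  x <- as.vector(voxels(image))
  r <- as.vector(voxels(reference))
  if (!length(x) || !length(r)) stop("empty volume")

  constImg <- diff(range(x)) == 0
  constRef <- diff(range(r)) == 0
  if (constRef && !constImg)
    stop("reference volume is constant: target histogram undefined")
  if (constImg) {
    out <- array(stats::quantile(r, 0.5, type = 1, names = FALSE),
                 dim = dim(voxels(image)))
    return(ImageVolume(out, spacing = spacing(image),
                       sliceGapFraction = sliceGapFraction(image),
                       id = volumeId(image)))
  }

  lo <- min(x, r); hi <- max(x, r)
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  w <- breaks[2] - breaks[1]
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  # binned CDF, interpolated linearly within each voxel's bin
  cumLeft <- c(0, cumsum(counts))[bin]
  frac <- (x - breaks[bin]) / w
  p <- pmin(1, pmax(0, (cumLeft + frac * counts[bin]) / length(x)))
  mapped <- stats::quantile(r, p, type = 1, names = FALSE)
  out <- array(mapped, dim = dim(voxels(image)))
  ImageVolume(out, spacing = spacing(image),
              sliceGapFraction = sliceGapFraction(image),
              id = volumeId(image))
}
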