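#' Trapezoidal area under an ROC curve
#'
#' Area under the (1 - specificity, sensitivity) polyline after appending
#' the corner points (0, 0) and (1, 1), by the trapezoid rule. Vertical
#' segments (tied false-positive rates) contribute zero width.
#'
#' @param sensitivity,specificity Equal-length vectors of operating points.
#' @return AUC in [0, 1].
#' @examples
#' trapezoidAUC(1, 1)          # perfect single point -> 1
#' trapezoidAUC(0.6, 0.4)      # a chance-line point -> 0.5
#' @export
trapezoidAUC <- function(sensitivity, specificity) {
  if (!length(sensitivity) || length(sensitivity) != length(specificity))
    stop("sensitivity and specificity must be non-empty, equal length")
  fpr <- c(0, 1 - specificity, 1)
  tpr <- c(0, sensitivity, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden-optimal operating point
#'
#' The k maximizing Youden's J = sensitivity + specificity - 1; ties are
#' broken toward the larger k (the more specific threshold).
#'
#' @param k Candidate multipliers.
#' @param sensitivity,specificity Operating characteristics at each k.
#' @return The chosen k.
#' @export
youdenOptimalK <- function(k, sensitivity, specificity) {
  if (length(k) != length(sensitivity) || length(k) != length(specificity))
    stop("k, sensitivity, specificity must have equal length")
  J <- sensitivity + specificity - 1
  cand <- which(J == max(J))
  k[cand[which.max(k[cand])]]
}

#' Sweep the SD multiplier k and build an ROC curve
#'
#' Runs the full quantification pipeline on every case at every k of the
#' grid. A case is test-positive when at least one lesion survives the
#' size filter (\code{nLesions >= 1}); sensitivity and specificity at each
#' k are computed against the cases' reference labels. By threshold
#' monotonicity, the supra-threshold voxel set shrinks as k grows, so
#' sensitivity is non-increasing and specificity non-decreasing along the
#' grid.
#'
#' An alternative positivity rule based on total lesion volume is
#' available via \code{minVolume} (a case is then positive when
#' volume_hyper exceeds it); the default 0 reduces to the object-count
#' rule.
#'
#' @param cases List of cases; each a list with elements \code{image}
#'   ([ImageVolume-class]), \code{bone} ([RegionMask-class]), \code{roi}
#'   ([ReferenceROI-class]) and \code{positive} (logical reference label).
#'   At least one positive and one negative case are required.
#' @param kGrid Strictly increasing k values; the default 0.25..6 by 0.05
#'   covers both calibrated anatomies (4.15 spine, 2.64 SI).
#' @param connectivity,minSize,includeGap Passed to the pipeline.
#' @param minVolume Volume-based positivity cutoff in cm^3 (0 = off).
#' @return A [ThresholdROC-class].
#' @export
sweepK <- function(cases, kGrid = seq(0.25, 6, by = 0.05),
                   connectivity = 26, minSize = 10L, includeGap = FALSE,
                   minVolume = 0) {
  if (!length(cases)) stop("no cases")
  if (length(kGrid) < 1L || is.unsorted(kGrid, strictly = TRUE))
    stop("kGrid must be strictly increasing")
  labels <- vapply(cases, function(cs) isTRUE(cs$positive), logical(1))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC undefined: need at least one positive and one negative case")

  testPos <- matrix(NA, nrow = length(cases), ncol = length(kGrid))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    rs <- suppressWarnings(roiStats(cs$image, cs$roi))
    for (j in seq_along(kGrid)) {
      T <- computeThreshold(rs$mean, rs$sd, kGrid[j])
      hyper <- maskHyperintense(cs$image, cs$bone, T)
      lab <- filterSmall(labelComponents(hyper, connectivity), minSize)
      if (minVolume > 0) {
        vv <- voxelVolume(cs$image, includeGap = includeGap)
        testPos[i, j] <- sum(lab > 0L) * vv > minVolume
      } else {
        testPos[i, j] <- any(lab > 0L)
      }
    }
  }

  sens <- colSums(testPos & labels) / nPos
  spec <- colSums(!testPos & !labels) / nNeg
  pts <- data.frame(k = kGrid, sensitivity = sens, specificity = spec,
                    youden = sens + spec - 1)
  new("ThresholdROC", points = pts,
      auc = trapezoidAUC(sens, spec),
      optimalK = youdenOptimalK(kGrid, sens, spec),
      nPositive = as.integer(nPos), nNegative = as.integer(nNeg))
}
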