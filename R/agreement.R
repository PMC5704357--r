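#' Confusion table from per-unit labels
#'
#' Standard 2x2 cross-tabulation of a binary test against a binary
#' reference over the same units (image sets or slices).
#'
#' @param reference Logical vector of reference labels (e.g. SPARCC > 0).
#' @param test Logical vector of test labels (thresholding found lesions),
#'   same length.
#' @return An [AgreementTable-class].
#' @export
confusionTable <- function(reference, test) {
  if (length(reference) != length(test))
    stop(sprintf("length mismatch: reference has %d, test has %d",
                 length(reference), length(test)))
  if (length(reference) < 1L) stop("need at least one unit")
  reference <- as.logical(reference); test <- as.logical(test)
  if (anyNA(reference) || anyNA(test)) stop("labels may not be NA")
  new("AgreementTable",
      TP = sum(test & reference), FP = sum(test & !reference),
      FN = sum(!test & reference), TN = sum(!test & !reference))
}

#' Confusion table implied by marginal counts
#'
#' Reconstructs the 2x2 table from the counts a study report typically
#' prints: total units, reference-positive units, test-positive units, and
#' units where both methods agree on absence (true negatives). The
#' remaining cells follow by arithmetic:
#' FP = (total - refPos) - TN, TP = testPos - FP, FN = refPos - TP.
#' Inconsistent counts (any implied cell negative) are an error naming the
#' offending cell.
#'
#' @param nTotal Total units compared.
#' @param nRefPos Units positive by the reference method.
#' @param nTestPos Units positive by the test method.
#' @param nAgreeNeg Units negative by both methods.
#' @return An [AgreementTable-class].
#' @examples
#' # spine, per image set: 85 sets, 60 SPARCC-positive, 56 with lesions
#' # by thresholding, 19 agreed negative -> sensitivity 83%, specificity 76%
#' tab <- confusionFromCounts(85, 60, 56, 19)
#' round(100 * c(sensitivity(tab), specificity(tab)))
#' @export
confusionFromCounts <- function(nTotal, nRefPos, nTestPos, nAgreeNeg) {
  TN <- nAgreeNeg
  FP <- (nTotal - nRefPos) - TN
  if (FP < 0) stop(sprintf("inconsistent counts: implied FP = %d < 0", FP))
  TP <- nTestPos - FP
  if (TP < 0) stop(sprintf("inconsistent counts: implied TP = %d < 0", TP))
  FN <- nRefPos - TP
  if (FN < 0) stop(sprintf("inconsistent counts: implied FN = %d < 0", FN))
  new("AgreementTable", TP = as.integer(TP), FP = as.integer(FP),
      FN = as.integer(FN), TN = as.integer(TN))
}

#' Spearman rank correlation
#'
#' Spearman's rho between two scalar series: the Pearson correlation of
#' mid-ranks (ties receive average ranks), as used to relate reference
#' scores to lesion volume and intensity metrics. Invariant under any
#' strictly increasing transform of either variable. Zero rank variance in
#' either variable leaves rho undefined (NA with a warning).
#'
#' @param x,y Numeric vectors, equal length >= 3.
#' @return Spearman's rho, or NA when undefined.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("rank variance is zero; Spearman's rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Cohort mean and range, with or without the zero (lesion-free) sets
#'
#' Study reports quote metric means two ways: over the lesion-positive
#' sets only, and over all sets with lesion-free sets contributing zeros.
#' Given the positive-set values, this reconstructs either. With
#' \code{includeZeros = TRUE} the mean is \code{sum(values) / nTotal} and
#' the range extends to 0 whenever any lesion-free set exists.
#'
#' @param values Metric values of the positive sets.
#' @param nTotal Total number of sets in the cohort (>= length(values)).
#' @param includeZeros Spread the mean over all sets, zeros included?
#' @param nPositive Number of positive sets; must equal
#'   \code{length(values)} (redundant, kept as a consistency check).
#' @return Named numeric: mean, min, max.
#' @examples
#' # 60 reader-positive spine sets with mean score 10.5 among 85 sets:
#' aggregateCohort(rep(10.5, 60), nTotal = 85)[["mean"]]  # 7.41
#' @export
aggregateCohort <- function(values, nTotal, includeZeros = TRUE,
                            nPositive = length(values)) {
  if (nTotal == 0L) stop("nTotal must be >= 1")
  if (nPositive != length(values))
    stop("nPositive must equal length(values)")
  if (nTotal < nPositive) stop("nTotal must be >= the number of values")
  if (includeZeros) {
    lo <- if (nTotal > nPositive) 0 else min(values)
    c(mean = sum(values) / nTotal, min = min(lo, values), max = max(values))
  } else {
    c(mean = mean(values), min = min(values), max = max(values))
  }
}

#' Agreement of quantification results with reference labels
#'
#' Joins a tidy results table (see [quantTable()]) with a reference label
#' table on \code{id}/\code{image_set} and cross-tabulates
#' lesion presence (n_objects >= 1) against reference positivity.
#'
#' @param results data.frame from [quantTable()].
#' @param labels data.frame from [readLabelTable()] (per-set rows).
#' @return List: \code{table} ([AgreementTable-class]), \code{merged}
#'   (the joined data.frame), \code{spearman} (rho between score and
#'   volume_hyper, NA if undefined).
#' @export
agreementStats <- function(results, labels) {
  m <- merge(results, labels, by.x = "id", by.y = "image_set")
  if (!nrow(m)) stop("no overlapping image-set ids between results and labels")
  tab <- confusionTable(m$positive, m$n_objects >= 1L)
  rho <- if (nrow(m) >= 3L) suppressWarnings(spearmanRho(m$score, m$volume_hyper))
         else NA_real_
  list(table = tab, merged = m, spearman = rho)
}
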