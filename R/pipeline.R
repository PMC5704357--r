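#' Run the quantification pipeline over an inventory of image sets
#'
#' Batch driver: for each inventory row it loads the image and bone mask,
#' builds the reference ROI, optionally histogram-matches the image to a
#' reference volume, runs [quantifyEdema()], and collects tidy per-set
#' metrics. Per-set failures (unreadable files, mismatched grids) are
#' recorded and do not abort the batch.
#'
#' @param inventory data.frame with columns \code{id}, \code{image} (NIfTI
#'   path), \code{mask} (NIfTI path), \code{roi_row}, \code{roi_col},
#'   \code{roi_radius}, \code{roi_slice} (in-plane ROI disc placement).
#' @param reference Optional [ImageVolume-class] (or NIfTI path) to
#'   histogram-match every image to before thresholding.
#' @param preset,k,connectivity,minSize,includeGap Passed to
#'   [quantifyEdema()].
#' @param nBins Histogram bins for matching.
#' @return List: \code{results} (data.frame as [quantTable()]),
#'   \code{failures} (data.frame id, error), \code{quantResults} (list of
#'   [QuantResult-class] for the successful sets).
#' @export
runPipeline <- function(inventory, reference = NULL,
                        preset = c("custom", "spine", "si"), k = NULL,
                        connectivity = 26, minSize = 10L,
                        includeGap = FALSE, nBins = 256L) {
  preset <- match.arg(preset)
  need <- c("id", "image", "mask", "roi_row", "roi_col", "roi_radius",
            "roi_slice")
  if (!nrow(inventory)) {
    warning("empty inventory: nothing to do")
    return(list(results = data.frame(), failures = data.frame(),
                quantResults = list()))
  }
  if (!all(need %in% names(inventory)))
    stop(sprintf("inventory must have columns %s", paste(need, collapse = ", ")))
  if (is.character(reference)) reference <- readVolume(reference)

  results <- list(); failures <- list(); qrs <- list()
  for (i in seq_len(nrow(inventory))) {
    row <- inventory[i, ]
    res <- tryCatch({
      img <- suppressMessages(readVolume(row$image, id = row$id))
      bone <- readMask(row$mask, img)
      roi <- suppressWarnings(sphericalROI(
        c(row$roi_row, row$roi_col), row$roi_radius, row$roi_slice,
        dim(voxels(img))))
      if (!is.null(reference))
        img <- matchHistogram(img, reference, nBins = nBins)
      if (!any(voxels(bone)))
        warning(sprintf("set '%s': bone mask is empty", row$id))
      quantifyEdema(img, bone, roi, preset = preset, k = k,
                    connectivity = connectivity, minSize = minSize,
                    includeGap = includeGap, id = row$id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(id = row$id, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      qrs[[length(qrs) + 1L]] <- res
    }
  }
  list(
    results = if (length(qrs)) quantTable(qrs) else data.frame(),
    failures = if (length(failures)) do.call(rbind, failures)
               else data.frame(),
    quantResults = qrs
  )
}
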