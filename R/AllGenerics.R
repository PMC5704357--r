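#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("sliceGapFraction", function(x, ...) standardGeneric("sliceGapFraction"))

#' @rdname accessors
#' @export
setGeneric("volumeId", function(x) standardGeneric("volumeId"))

#' @rdname accessors
#' @export
setGeneric("roiCoords", function(x) standardGeneric("roiCoords"))

#' @rdname accessors
#' @export
setGeneric("nLesions", function(x) standardGeneric("nLesions"))

#' @rdname accessors
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))

#' @rdname accessors
#' @export
setGeneric("volumeHyper", function(x) standardGeneric("volumeHyper"))

#' @rdname accessors
#' @export
setGeneric("relIntensitySummary", function(x) standardGeneric("relIntensitySummary"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))

#' @rdname accessors
#' @export
setGeneric("optimalK", function(x) standardGeneric("optimalK"))

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
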