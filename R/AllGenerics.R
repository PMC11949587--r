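#' @rdname accessors
#' @export
setGeneric("regionCount", function(x) standardGeneric("regionCount"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("atlasCentroids", function(x) standardGeneric("atlasCentroids"))

#' @rdname accessors
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))

#' @rdname accessors
#' @export
setGeneric("maskRegions", function(x) standardGeneric("maskRegions"))

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))

#' @rdname accessors
#' @export
setGeneric("pliValues", function(x) standardGeneric("pliValues"))

#' @rdname accessors
#' @export
setGeneric("pliSource", function(x) standardGeneric("pliSource"))

#' @rdname accessors
#' @export
setGeneric("pliThreshold", function(x) standardGeneric("pliThreshold"))

#' @rdname accessors
#' @export
setGeneric("isThresholded", function(x) standardGeneric("isThresholded"))

#' @rdname fitgrid-accessors
#' @export
setGeneric("meanSurface", function(x) standardGeneric("meanSurface"))

#' @rdname fitgrid-accessors
#' @export
setGeneric("curveMean", function(x) standardGeneric("curveMean"))

#' @rdname fitgrid-accessors
#' @export
setGeneric("curveSd", function(x) standardGeneric("curveSd"))

#' @rdname connectotomy
#' @export
setGeneric("differenceOfChanges", function(x) standardGeneric("differenceOfChanges"))
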