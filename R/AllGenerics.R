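#' @rdname MirnaCohort-accessors
#' @export
setGeneric("rpm", function(x) standardGeneric("rpm"))

#' @rdname MirnaCohort-accessors
#' @export
setGeneric("logExpr", function(x) standardGeneric("logExpr"))

#' @rdname MirnaCohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname MirnaCohort-accessors
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' @rdname EventTable-accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))

#' @rdname EventTable-accessors
#' @export
setGeneric("nDeaths", function(x) standardGeneric("nDeaths"))

#' @rdname EventTable-accessors
#' @export
setGeneric("nAtRisk", function(x) standardGeneric("nAtRisk"))

#' @rdname curve-evaluation
#' @export
setGeneric("curveAt", function(x, t) standardGeneric("curveAt"))

#' @rdname StarSets-accessors
#' @export
setGeneric("fourStar", function(x) standardGeneric("fourStar"))

#' @rdname StarSets-accessors
#' @export
setGeneric("oneStar", function(x) standardGeneric("oneStar"))
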