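#' @rdname ControlPolygon-class
#' @param object a ControlPolygon or ClosedCubicSpline.
#' @export
setGeneric("controlPoints", function(object) standardGeneric("controlPoints"))

#' @rdname ControlPolygon-class
#' @export
setGeneric("nControlPoints", function(object) standardGeneric("nControlPoints"))

#' @rdname ClosedCubicSpline-class
#' @param object a ClosedCubicSpline.
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname PropagationResult-class
#' @param object a PropagationResult.
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))

#' @rdname PropagationResult-class
#' @export
setGeneric("maskStack", function(object) standardGeneric("maskStack"))

#' @rdname PhantomVolume-class
#' @param object a PhantomVolume.
#' @param k slice index (1-based).
#' @export
setGeneric("phantomSlice", function(object, k) standardGeneric("phantomSlice"))

#' @rdname PhantomVolume-class
#' @export
setGeneric("truthSlice", function(object, k) standardGeneric("truthSlice"))
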