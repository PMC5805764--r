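#' @rdname GrayscaleSlice-class
#' @param object,x a \code{GrayscaleSlice}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname GrayscaleSlice-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname GrayscaleSlice-class
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))

#' @rdname PhantomGroundTruth-class
#' @export
setGeneric("fiberTable", function(x) standardGeneric("fiberTable"))

#' @rdname PatencyConfig-class
#' @export
setGeneric("nominalLumenArea", function(x) standardGeneric("nominalLumenArea"))

#' @rdname PatencyConfig-class
#' @export
setGeneric("thresholdFraction",
    function(x) standardGeneric("thresholdFraction"))

#' @rdname ReproducibilityReport-class
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname ReproducibilityReport-class
#' @export
setGeneric("reportMaxima", function(x) standardGeneric("reportMaxima"))
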