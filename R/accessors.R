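#' @rdname GrayscaleSlice-class
#' @aliases intensities pixelSize sliceId
#' @export
setMethod("intensities", "GrayscaleSlice", function(x) x@intensities)

#' @rdname GrayscaleSlice-class
#' @export
setMethod("pixelSize", "GrayscaleSlice", function(x) x@pixelSize)

#' @rdname PhantomSpec-class
#' @param x a \code{PhantomSpec}.
#' @export
setMethod("pixelSize", "PhantomSpec", function(x) x@pixelSize)

#' @rdname GrayscaleSlice-class
#' @export
setMethod("sliceId", "GrayscaleSlice", function(x) x@sliceId)

#' @rdname PhantomGroundTruth-class
#' @param x,object a \code{PhantomGroundTruth}.
#' @aliases fiberTable
#' @export
setMethod("fiberTable", "PhantomGroundTruth", function(x) x@fibers)

#' @rdname PhantomGroundTruth-class
#' @export
setMethod("nominalLumenArea", "PhantomGroundTruth",
    function(x) x@nominalLumenArea)

#' @rdname PatencyConfig-class
#' @param x,object a \code{PatencyConfig}.
#' @aliases nominalLumenArea thresholdFraction
#' @export
setMethod("nominalLumenArea", "PatencyConfig", function(x) x@nominalLumenArea)

#' @rdname PatencyConfig-class
#' @export
setMethod("thresholdFraction", "PatencyConfig", function(x) x@thresholdFraction)

#' @rdname PhantomSpec-class
#' @export
setMethod("nominalLumenArea", "PhantomSpec", function(x) x@nominalLumenArea)

#' @rdname ReproducibilityReport-class
#' @param x,object a \code{ReproducibilityReport}.
#' @aliases reportTable reportMaxima
#' @export
setMethod("reportTable", "ReproducibilityReport", function(x) x@table)

#' @rdname ReproducibilityReport-class
#' @export
setMethod("reportMaxima", "ReproducibilityReport", function(x) x@maxima)

setMethod("show", "GrayscaleSlice", function(object) {
    d <- dim(object@intensities)
    cat(sprintf(
        "GrayscaleSlice '%s': %d x %d px at %.3g um/px (%.1f x %.1f mm)\n",
        object@sliceId, d[1], d[2], object@pixelSize,
        d[1] * object@pixelSize / 1000, d[2] * object@pixelSize / 1000))
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
        min(object@intensities), max(object@intensities)))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %d x %d px at %g um/px, bundle radius %g mm, pitch %g um\n",
        object@imageShape[1], object@imageShape[2], object@pixelSize,
        object@bundleRadius, object@latticePitch))
    cat(sprintf(
        "  lumen area %.6f mm^2; blocked %.2f, partial %.2f (%s pattern)\n",
        object@nominalLumenArea, object@blockedFraction,
        object@partialFraction, object@pattern))
    cat(sprintf("  blur %g um, noise %g, seed %d\n",
        object@blurSigma, object@noiseSigma, object@seed))
})

setMethod("show", "PhantomGroundTruth", function(object) {
    tab <- table(factor(object@fibers$label,
                        levels = c("open", "partial", "blocked")))
    cat(sprintf(
        "PhantomGroundTruth: %d fibers (%d open, %d partial, %d blocked)\n",
        nrow(object@fibers), tab[["open"]], tab[["partial"]],
        tab[["blocked"]]))
})

setMethod("show", "PatencyConfig", function(object) {
    cat(sprintf(
        "PatencyConfig: area > %.0f%% of %.6f mm^2 (= %.6f mm^2), circularity [%.2f, %.2f]\n",
        100 * object@thresholdFraction, object@nominalLumenArea,
        object@thresholdFraction * object@nominalLumenArea,
        object@circularityMin, object@circularityMax))
    cat(sprintf("  reference total fibers: %d\n",
        object@totalFibersReference))
})

setMethod("show", "ReproducibilityReport", function(object) {
    cat(sprintf("ReproducibilityReport: %d comparisons, %d dialyzers\n",
        nrow(object@table), length(unique(object@table$dialyzer_id))))
    cat(sprintf(
        "  max slice-offset difference: %.1f%%; max threshold difference: %.1f%%\n",
        object@maxima[["max_slice_offset_pct"]],
        object@maxima[["max_threshold_pct"]]))
})
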