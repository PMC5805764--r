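#' @import methods
NULL

#' GrayscaleSlice: one reconstructed CT cross-section
#'
#' A single 2D grayscale cross-section of the dialyzer potting region at a
#' known physical pixel size. Intensities are stored as a numeric matrix
#' (rows = image rows, columns = image columns) on an arbitrary non-negative
#' scale; images read from 8/16-bit TIFF or PNG arrive scaled to [0, 1].
#' Physical coordinates are in mm with the origin at the image centre,
#' x along columns and y along rows.
#'
#' @slot intensities numeric matrix of pixel intensities (non-negative).
#' @slot pixelSize physical size of one pixel side, in micrometres.
#' @slot sliceId free-text tag identifying the slice (e.g. "reference",
#'   "offset_2.5mm").
#'
#' @exportClass GrayscaleSlice
setClass("GrayscaleSlice",
    representation(
        intensities = "matrix",
        pixelSize   = "numeric",
        sliceId     = "character"
    ),
    prototype(pixelSize = 25, sliceId = "reference")
)

setValidity("GrayscaleSlice", function(object) {
    msg <- NULL
    if (!is.numeric(object@intensities))
        msg <- c(msg, "intensities must be a numeric matrix")
    if (length(object@intensities) == 0L)
        msg <- c(msg, "intensities must be non-empty")
    else if (any(!is.finite(object@intensities)) ||
             any(object@intensities < 0))
        msg <- c(msg, "intensities must be finite and non-negative")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number (um)")
    if (length(object@sliceId) != 1L)
        msg <- c(msg, "sliceId must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' PhantomSpec: parameters of a synthetic potting cross-section
#'
#' Describes the imaging regime being emulated: a roughly circular bundle of
#' hollow fibers whose open lumens appear as dark disks on a brighter potting
#' background. Defaults are sized to an FX600-class dialyzer imaged at
#' 25 um/pixel: bundle radius 16.5 mm and hexagonal lattice pitch 303 um give
#' about 10,750 fibers, and the nominal open-lumen area 0.029143 mm^2 is the
#' 70%-threshold calibration area 0.0204 mm^2 divided by 0.70.
#'
#' @slot imageShape integer(2), image rows and columns in pixels.
#' @slot pixelSize um per pixel (default 25).
#' @slot bundleRadius fiber-bundle radius in mm.
#' @slot latticePitch centre-to-centre fiber spacing in um.
#' @slot nominalLumenArea full open-lumen cross-sectional area in mm^2.
#' @slot nFibers optional exact fiber count; if finite, only the nFibers
#'   lattice sites closest to the bundle centre are kept.
#' @slot blockedFraction proportion of fully blocked fibers in [0, 1].
#' @slot partialFraction proportion of partially occluded fibers in [0, 1]
#'   (blockedFraction + partialFraction must not exceed 1).
#' @slot partialOcclusionRange numeric(2) in [0, 1]: range of the retained
#'   lumen-area fraction for partially occluded fibers.
#' @slot pattern spatial pattern of blockage: "uniform" (random positions)
#'   or "peripheral" (blocked fibers concentrated at the bundle rim).
#' @slot intensityBackground intensity outside the bundle.
#' @slot intensityPotting intensity of the potting inside the bundle.
#' @slot intensityLumen intensity of open lumens (must be darker than the
#'   potting: dark-dot polarity).
#' @slot blurSigma Gaussian blur sigma in um (0 disables).
#' @slot noiseSigma additive Gaussian noise sigma in intensity units
#'   (0 disables).
#' @slot jitterFraction lattice jitter radius as a fraction of the pitch
#'   (at most 0.1 to keep neighbouring lumens from overlapping).
#' @slot supersample linear supersampling factor for anti-aliased disk
#'   rendering.
#' @slot seed integer seed controlling jitter, patency assignment and noise.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(
        imageShape            = "integer",
        pixelSize             = "numeric",
        bundleRadius          = "numeric",
        latticePitch          = "numeric",
        nominalLumenArea      = "numeric",
        nFibers               = "numeric",
        blockedFraction       = "numeric",
        partialFraction       = "numeric",
        partialOcclusionRange = "numeric",
        pattern               = "character",
        intensityBackground   = "numeric",
        intensityPotting      = "numeric",
        intensityLumen        = "numeric",
        blurSigma             = "numeric",
        noiseSigma            = "numeric",
        jitterFraction        = "numeric",
        supersample           = "integer",
        seed                  = "integer"
    )
)

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    s <- object
    if (length(s@imageShape) != 2L || any(s@imageShape < 1L))
        msg <- c(msg, "imageShape must be two positive integers (rows, cols)")
    if (s@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (s@bundleRadius < 0) msg <- c(msg, "bundleRadius must be >= 0")
    extent <- min(s@imageShape) * s@pixelSize / 1000 # mm
    if (s@bundleRadius > extent / 2)
        msg <- c(msg, sprintf(
            "bundle must fit inside the image: bundleRadius %.3f mm > %.3f mm",
            s@bundleRadius, extent / 2))
    if (s@latticePitch <= 0) msg <- c(msg, "latticePitch must be positive")
    lumenDiam <- 2 * sqrt(s@nominalLumenArea / pi) * 1000 # um
    if (s@latticePitch < lumenDiam)
        msg <- c(msg, sprintf(
            "latticePitch (%.1f um) smaller than lumen diameter (%.1f um): fibers would overlap",
            s@latticePitch, lumenDiam))
    if (s@nominalLumenArea <= 0)
        msg <- c(msg, "nominalLumenArea must be positive")
    if (s@blockedFraction < 0 || s@blockedFraction > 1)
        msg <- c(msg, "blockedFraction must be in [0, 1]")
    if (s@partialFraction < 0 || s@partialFraction > 1 ||
        s@blockedFraction + s@partialFraction > 1 + 1e-12)
        msg <- c(msg, "partialFraction must be in [0, 1] with blockedFraction + partialFraction <= 1")
    por <- s@partialOcclusionRange
    if (length(por) != 2L || any(por < 0) || any(por > 1) || por[1] > por[2])
        msg <- c(msg, "partialOcclusionRange must be an interval inside [0, 1]")
    if (!s@pattern %in% c("uniform", "peripheral"))
        msg <- c(msg, "pattern must be 'uniform' or 'peripheral'")
    if (!(s@intensityLumen < s@intensityPotting))
        msg <- c(msg, "intensityLumen must be below intensityPotting (open fibers are dark dots)")
    if (s@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
    if (s@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (s@jitterFraction < 0 || s@jitterFraction > 0.1)
        msg <- c(msg, "jitterFraction must be in [0, 0.1]")
    if (s@supersample < 1L) msg <- c(msg, "supersample must be >= 1")
    if (is.finite(s@nFibers) && s@nFibers < 1)
        msg <- c(msg, "nFibers must be >= 1 when given")
    if (is.null(msg)) TRUE else msg
})

#' PhantomGroundTruth: exact per-fiber patency of a phantom
#'
#' One row per fiber: centre coordinates in mm (origin at the image centre),
#' the rendered open-lumen area in mm^2 (0 for fully blocked fibers) and a
#' patency label. Serves as the oracle against which pipeline counts are
#' checked.
#'
#' @slot fibers data.frame with columns id, x_mm, y_mm, open_area_mm2, label
#'   (label is one of "open", "partial", "blocked").
#' @slot nominalLumenArea the full open-lumen area in mm^2 used to generate
#'   the phantom.
#'
#' @exportClass PhantomGroundTruth
setClass("PhantomGroundTruth",
    representation(
        fibers           = "data.frame",
        nominalLumenArea = "numeric"
    )
)

setValidity("PhantomGroundTruth", function(object) {
    msg <- NULL
    fb <- object@fibers
    need <- c("id", "x_mm", "y_mm", "open_area_mm2", "label")
    if (!all(need %in% names(fb)))
        msg <- c(msg, paste("fibers must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(fb$open_area_mm2 < 0) ||
            any(fb$open_area_mm2 > object@nominalLumenArea + 1e-9))
            msg <- c(msg, "open_area_mm2 must lie in [0, nominalLumenArea]")
        if (!all(fb$label %in% c("open", "partial", "blocked")))
            msg <- c(msg, "label must be open/partial/blocked")
        if (any(fb$label == "blocked" & fb$open_area_mm2 > 0))
            msg <- c(msg, "blocked fibers must have open_area_mm2 == 0")
    }
    if (length(object@nominalLumenArea) != 1L || object@nominalLumenArea <= 0)
        msg <- c(msg, "nominalLumenArea must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' PatencyConfig: the open-fiber classification rule
#'
#' A segmented particle counts as an open (patent) fiber when its
#' circularity lies in [circularityMin, circularityMax] and its area is
#' strictly greater than thresholdFraction times the nominal open-lumen
#' area, but no larger than areaMaxFactor times the nominal area (larger
#' particles are merged regions or artifacts, not single lumens). The
#' nominal area is calibrated from the 70%-threshold area: at the default
#' 0.0204 mm^2 for the 70% rule, one full lumen is 0.0204 / 0.70 =
#' 0.029143 mm^2.
#'
#' @slot thresholdFraction proportion of the nominal lumen area above which
#'   a particle counts as open (default 0.70).
#' @slot areaAt70 the calibrated particle area corresponding to the 70%
#'   rule, in mm^2 (default 0.0204).
#' @slot nominalLumenArea full lumen area in mm^2, areaAt70 / 0.70.
#' @slot circularityMin,circularityMax inclusive circularity bounds
#'   (defaults 0.5 and 1.0).
#' @slot areaMaxFactor particles with area above areaMaxFactor times the
#'   nominal lumen area are rejected as non-fiber objects (default 2).
#' @slot totalFibersReference total fiber count of a non-used dialyzer,
#'   the denominator of reproducibility percent differences (default 10748).
#'
#' @exportClass PatencyConfig
setClass("PatencyConfig",
    representation(
        thresholdFraction    = "numeric",
        areaAt70             = "numeric",
        nominalLumenArea     = "numeric",
        circularityMin       = "numeric",
        circularityMax       = "numeric",
        areaMaxFactor        = "numeric",
        totalFibersReference = "integer"
    )
)

setValidity("PatencyConfig", function(object) {
    msg <- NULL
    if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
        msg <- c(msg, "thresholdFraction must be in (0, 1]")
    if (object@areaAt70 <= 0) msg <- c(msg, "areaAt70 must be positive")
    if (object@nominalLumenArea <= 0)
        msg <- c(msg, "nominalLumenArea must be positive")
    if (!(object@circularityMin < object@circularityMax) ||
        object@circularityMax > 1)
        msg <- c(msg, "need circularityMin < circularityMax <= 1")
    if (object@areaMaxFactor <= 1)
        msg <- c(msg, "areaMaxFactor must exceed 1")
    if (object@totalFibersReference <= 0L)
        msg <- c(msg, "totalFibersReference must be positive")
    if (is.null(msg)) TRUE else msg
})

#' ReproducibilityReport: percent differences against the reference count
#'
#' Produced by [reproducibilityReport()]. The table holds, for every
#' non-reference (slice, threshold) combination of every dialyzer, the
#' percent difference of its open-fiber count against the dialyzer's
#' reference-slice count at the reference threshold, expressed relative to
#' the total fiber count of a non-used dialyzer. The maxima slot separates
#' the slice-offset comparison (reliability) from the threshold-variation
#' comparisons (validity).
#'
#' @slot table data.frame with columns dialyzer_id, slice_id,
#'   threshold_fraction, n_open, reference_n_open, pct_diff.
#' @slot maxima named numeric: max_slice_offset_pct, max_threshold_pct
#'   (computed from percent differences rounded to one decimal, the
#'   reporting precision).
#'
#' @exportClass ReproducibilityReport
setClass("ReproducibilityReport",
    representation(
        table  = "data.frame",
        maxima = "numeric"
    )
)
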