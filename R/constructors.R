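#' Construct a GrayscaleSlice
#'
#' @param intensities numeric matrix of non-negative pixel intensities.
#' @param pixelSize physical pixel size in micrometres (default 25, the
#'   resolution the counting method was developed at).
#' @param sliceId free-text slice tag.
#' @return a [GrayscaleSlice-class] object.
#' @examples
#' s <- grayscaleSlice(matrix(runif(100), 10), pixelSize = 25)
#' pixelSize(s)
#' @export
grayscaleSlice <- function(intensities, pixelSize = 25,
                           sliceId = "reference") {
    new("GrayscaleSlice", intensities = intensities,
        pixelSize = as.numeric(pixelSize), sliceId = as.character(sliceId))
}

#' Construct a PhantomSpec
#'
#' Defaults describe the full FX600-scale imaging regime: 25 um pixels, a
#' 16.5 mm bundle of ~10,750 fibers on a 303 um hexagonal lattice, full
#' lumen area 0.029143 mm^2 (the 0.0204 mm^2 70%-threshold area divided by
#' 0.70), mild blur (half a pixel) and additive noise. See
#' [PhantomSpec-class] for slot meanings.
#'
#' @param imageShape image size in pixels (rows, cols). By default sized to
#'   hold the bundle with a 1 mm margin.
#' @param pixelSize um per pixel.
#' @param bundleRadius bundle radius in mm.
#' @param latticePitch fiber spacing in um.
#' @param nominalLumenArea full open-lumen area in mm^2.
#' @param nFibers optional exact fiber count (innermost lattice sites kept).
#' @param blockedFraction,partialFraction expected proportions of fully and
#'   partially blocked fibers.
#' @param partialOcclusionRange retained-area fraction range for partially
#'   occluded fibers.
#' @param pattern "uniform" or "peripheral" blockage placement.
#' @param intensityBackground,intensityPotting,intensityLumen intensity
#'   levels on the [0, 1] scale; lumens must be darker than potting.
#' @param blurSigma Gaussian blur sigma in um.
#' @param noiseSigma additive Gaussian noise sigma (intensity units).
#' @param jitterFraction lattice jitter radius as a fraction of the pitch.
#' @param supersample linear supersampling factor for rendering.
#' @param seed integer seed.
#' @return a validated [PhantomSpec-class].
#' @examples
#' sp <- phantomSpec(bundleRadius = 2, nFibers = 100, seed = 7)
#' sp
#' @export
phantomSpec <- function(imageShape = NULL,
                        pixelSize = 25,
                        bundleRadius = 16.5,
                        latticePitch = 303,
                        nominalLumenArea = 0.0204 / 0.70,
                        nFibers = NA_real_,
                        blockedFraction = 0,
                        partialFraction = 0,
                        partialOcclusionRange = c(0.2, 0.6),
                        pattern = c("uniform", "peripheral"),
                        intensityBackground = 0.85,
                        intensityPotting = 0.70,
                        intensityLumen = 0.10,
                        blurSigma = 12.5,
                        noiseSigma = 0.02,
                        jitterFraction = 0.1,
                        supersample = 8L,
                        seed = 1L) {
    pattern <- match.arg(pattern)
    if (is.null(imageShape)) {
        sidePx <- ceiling(2 * (bundleRadius + 1) * 1000 / pixelSize)
        imageShape <- c(sidePx, sidePx)
    }
    new("PhantomSpec",
        imageShape = as.integer(imageShape),
        pixelSize = as.numeric(pixelSize),
        bundleRadius = as.numeric(bundleRadius),
        latticePitch = as.numeric(latticePitch),
        nominalLumenArea = as.numeric(nominalLumenArea),
        nFibers = as.numeric(nFibers),
        blockedFraction = as.numeric(blockedFraction),
        partialFraction = as.numeric(partialFraction),
        partialOcclusionRange = as.numeric(partialOcclusionRange),
        pattern = pattern,
        intensityBackground = as.numeric(intensityBackground),
        intensityPotting = as.numeric(intensityPotting),
        intensityLumen = as.numeric(intensityLumen),
        blurSigma = as.numeric(blurSigma),
        noiseSigma = as.numeric(noiseSigma),
        jitterFraction = as.numeric(jitterFraction),
        supersample = as.integer(supersample),
        seed = as.integer(seed))
}

#' Construct a PatencyConfig
#'
#' The area rule is calibrated, not free: the particle area corresponding to
#' the 70% threshold is 0.0204 mm^2, so a full non-used lumen measures
#' 0.0204 / 0.70 = 0.029143 mm^2 and any other threshold fraction f maps to
#' the area f * 0.029143 mm^2.
#'
#' @param thresholdFraction proportion of a full lumen above which a
#'   particle counts as open (default 0.70).
#' @param areaAt70 particle area at the 70% threshold in mm^2
#'   (default 0.0204).
#' @param circularityMin,circularityMax inclusive circularity bounds.
#' @param areaMaxFactor upper area cut in units of the nominal lumen area.
#' @param totalFibersReference total fiber count of a non-used dialyzer.
#' @return a validated [PatencyConfig-class].
#' @examples
#' cfg <- patencyConfig()
#' thresholdArea(0.6, cfg)
#' @export
patencyConfig <- function(thresholdFraction = 0.70,
                          areaAt70 = 0.0204,
                          circularityMin = 0.5,
                          circularityMax = 1.0,
                          areaMaxFactor = 2.0,
                          totalFibersReference = 10748L) {
    new("PatencyConfig",
        thresholdFraction = as.numeric(thresholdFraction),
        areaAt70 = as.numeric(areaAt70),
        nominalLumenArea = as.numeric(areaAt70) / 0.70,
        circularityMin = as.numeric(circularityMin),
        circularityMax = as.numeric(circularityMax),
        areaMaxFactor = as.numeric(areaMaxFactor),
        totalFibersReference = as.integer(totalFibersReference))
}
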