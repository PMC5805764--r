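#' Particle area corresponding to a threshold fraction
#'
#' Maps a threshold fraction to the calibrated particle area: fraction
#' times the nominal open-lumen area. At the defaults, 0.70 maps to
#' 0.0204 mm^2 (the calibration anchor) and 0.60 to 0.017486 mm^2.
#'
#' @param fraction threshold fraction in (0, 1].
#' @param cfg a [PatencyConfig-class].
#' @return area in mm^2.
#' @examples
#' thresholdArea(0.7, patencyConfig())
#' @export
thresholdArea <- function(fraction, cfg = patencyConfig()) {
    if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction > 1))
        stop("fraction must be in (0, 1]")
    fraction * cfg@nominalLumenArea
}

#' Classify measured particles as open fibers
#'
#' Retains particles whose circularity lies inside
#' [circularityMin, circularityMax] (inclusive) and whose area is strictly
#' greater than the threshold area but at most areaMaxFactor times the
#' nominal lumen area (larger objects are merged regions or artifacts, not
#' single lumens). Input order is preserved.
#'
#' @param particles data.frame from [measureParticles()].
#' @param cfg a [PatencyConfig-class].
#' @return the retained subset of \code{particles}.
#' @export
classifyOpen <- function(particles, cfg = patencyConfig()) {
    aMin <- thresholdArea(cfg@thresholdFraction, cfg)
    aMax <- cfg@areaMaxFactor * cfg@nominalLumenArea
    keep <- particles$circularity >= cfg@circularityMin &
            particles$circularity <= cfg@circularityMax &
            particles$area_mm2 > aMin &
            particles$area_mm2 <= aMax
    particles[keep, , drop = FALSE]
}

#' Count open fibers in one cross-section
#'
#' The full pipeline: dark-dot thresholding, bundle-ROI detection (unless
#' an ROI mask is supplied), distance-transform watershed, particle
#' measurement, centroid-in-ROI retention and patency classification.
#' Deterministic for a fixed input image.
#'
#' @param slice a [GrayscaleSlice-class].
#' @param cfg a [PatencyConfig-class].
#' @param roi optional logical ROI mask (same shape as the slice); when
#'   NULL the ROI is detected from the mask.
#' @param dialyzerId free-text id stored in the result.
#' @param thresholdMethod,thresholdValue see [thresholdDark()].
#' @param minSeparationUm watershed seed separation; defaults to half the
#'   expected lumen diameter implied by \code{cfg}.
#' @param closingRadiusUm ROI closing radius, see [detectBundleRoi()].
#' @param refine if TRUE (default) and the threshold is Otsu's, any dark
#'   component implausibly large for a fiber lumen (more than a quarter of
#'   the image) is re-thresholded internally, so that a global split landing
#'   between potting and outside background on mostly-blocked sections does
#'   not flood the bundle into one giant particle.
#' @param details if TRUE, return a list with the count, the measured
#'   particle table (with \code{in_roi} and \code{open} flags) and the ROI.
#' @return one-row data.frame (dialyzer_id, slice_id, threshold_fraction,
#'   n_open), or the detail list.
#' @examples
#' ph <- generatePhantom(phantomSpec(bundleRadius = 1.5, nFibers = 60,
#'                                   imageShape = c(180, 180), seed = 2,
#'                                   noiseSigma = 0, blurSigma = 0))
#' countOpenFibers(ph$slice, dialyzerId = "demo")$n_open
#' truthCount(ph$truth)
#' @export
countOpenFibers <- function(slice, cfg = patencyConfig(), roi = NULL,
                            dialyzerId = "",
                            thresholdMethod = c("otsu", "fixed"),
                            thresholdValue = NULL,
                            minSeparationUm = NULL,
                            closingRadiusUm = 620,
                            refine = TRUE,
                            details = FALSE) {
    thresholdMethod <- match.arg(thresholdMethod)
    validObject(slice); validObject(cfg)
    if (is.null(minSeparationUm))
        minSeparationUm <- 1000 * sqrt(cfg@nominalLumenArea / pi)
    px <- pixelSize(slice)
    mask <- thresholdDark(slice, method = thresholdMethod,
                          value = thresholdValue)
    if (refine && thresholdMethod == "otsu")
        mask <- .refinePlateaus(mask, intensities(slice))
    countRow <- function(n) data.frame(
        dialyzer_id = dialyzerId, slice_id = sliceId(slice),
        threshold_fraction = cfg@thresholdFraction, n_open = as.integer(n),
        stringsAsFactors = FALSE)
    if (!any(mask)) {
        warning("no candidate pixels after thresholding; count is 0")
        return(if (details)
            list(count = countRow(0L), particles = NULL, roi = roi)
        else countRow(0L))
    }
    if (is.null(roi)) {
        roi <- detectBundleRoi(mask, pixelSize = px,
                               closingRadiusUm = closingRadiusUm)
    } else if (!identical(dim(roi), dim(mask)))
        stop("roi shape does not match the slice")
    if (!any(roi)) {
        warning("empty ROI; count is 0")
        return(if (details)
            list(count = countRow(0L), particles = NULL, roi = roi)
        else countRow(0L))
    }
    lab <- watershedSplit(mask, pixelSize = px,
                          minSeparationUm = minSeparationUm)
    particles <- measureParticles(lab, pixelSize = px)
    pxmm <- px / 1000
    cRow <- pmin(pmax(round(particles$y_mm / pxmm + (nrow(mask) + 1) / 2),
                      1L), nrow(mask))
    cCol <- pmin(pmax(round(particles$x_mm / pxmm + (ncol(mask) + 1) / 2),
                      1L), ncol(mask))
    particles$in_roi <- roi[cbind(cRow, cCol)]
    retained <- particles[particles$in_roi, , drop = FALSE]
    open <- classifyOpen(retained, cfg)
    particles$open <- particles$label %in% open$label
    if (details)
        list(count = countRow(nrow(open)), particles = particles, roi = roi)
    else countRow(nrow(open))
}

#' Percent difference of a count against the reference count
#'
#' 100 * |count - reference| / totalFibers: the difference in open fibers
#' versus the reference slice, expressed relative to the total number of
#' fibers of a non-used dialyzer. Reported to one decimal in tables.
#'
#' @param count,referenceCount integer open-fiber counts.
#' @param totalFibers total fiber count (must be positive).
#' @return percent difference (not rounded).
#' @examples
#' round(percentDifference(8290, 7632, 10748), 1)  # 6.1
#' @export
percentDifference <- function(count, referenceCount, totalFibers) {
    if (any(totalFibers <= 0)) stop("totalFibers must be positive")
    100 * abs(count - referenceCount) / totalFibers
}

#' Reproducibility report over slices and thresholds
#'
#' For every dialyzer the reference is its count in the reference slice at
#' the reference threshold fraction; every other (slice, threshold)
#' combination is compared via [percentDifference()]. Comparisons in a
#' different slice measure reliability (slice offset); comparisons at a
#' different threshold in the reference slice measure validity (threshold
#' sensitivity). Column maxima are taken over the per-dialyzer percent
#' differences rounded to one decimal, the reporting precision.
#'
#' @param counts data.frame with columns dialyzer_id, slice_id,
#'   threshold_fraction, n_open (e.g. rows from [countOpenFibers()] or
#'   [table1Counts()]).
#' @param cfg a [PatencyConfig-class]; supplies the total-fiber denominator
#'   and the reference threshold fraction.
#' @param referenceSlice slice_id of the reference slice.
#' @return a [ReproducibilityReport-class].
#' @export
reproducibilityReport <- function(counts, cfg = patencyConfig(),
                                  referenceSlice = "reference") {
    need <- c("dialyzer_id", "slice_id", "threshold_fraction", "n_open")
    if (!all(need %in% names(counts)))
        stop("counts needs columns: ", paste(need, collapse = ", "))
    refFrac <- cfg@thresholdFraction
    total <- cfg@totalFibersReference
    rows <- lapply(split(counts, counts$dialyzer_id), function(d) {
        isRef <- d$slice_id == referenceSlice &
                 abs(d$threshold_fraction - refFrac) < 1e-9
        if (!any(isRef))
            stop("no reference-slice count at threshold ", refFrac,
                 " for dialyzer ", d$dialyzer_id[1])
        ref <- d$n_open[which(isRef)[1]]
        oth <- d[!isRef, , drop = FALSE]
        if (nrow(oth) == 0L) return(NULL)
        data.frame(
            dialyzer_id = oth$dialyzer_id, slice_id = oth$slice_id,
            threshold_fraction = oth$threshold_fraction,
            n_open = oth$n_open, reference_n_open = ref,
            pct_diff = percentDifference(oth$n_open, ref, total),
            stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    offset <- tab$slice_id != referenceSlice
    maxima <- c(
        max_slice_offset_pct = if (any(offset))
            max(round(tab$pct_diff[offset], 1)) else NA_real_,
        max_threshold_pct = if (any(!offset))
            max(round(tab$pct_diff[!offset], 1)) else NA_real_)
    new("ReproducibilityReport", table = tab, maxima = maxima)
}
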