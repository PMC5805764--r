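#' Hexagonal fiber lattice of a phantom bundle
#'
#' Generates hexagonally packed fiber centres at the spec's pitch, confined
#' to the disk of \code{bundleRadius} (centre distance <= radius), with
#' optional uniform jitter inside a disk of radius
#' \code{jitterFraction * latticePitch}. The origin is always a lattice
#' site, so a zero-radius bundle holds exactly one fiber. Deterministic
#' given the spec seed.
#'
#' If \code{nFibers} is set, the sites closest to the bundle centre are
#' kept (error if the lattice holds fewer).
#'
#' @param spec a [PhantomSpec-class].
#' @return data.frame with columns \code{id}, \code{x_mm}, \code{y_mm}.
#' @examples
#' nrow(buildLattice(phantomSpec(bundleRadius = 1, imageShape = c(200, 200))))
#' @export
buildLattice <- function(spec) {
    validObject(spec)
    withSeed(spec@seed, .buildLattice(spec))
}

.buildLattice <- function(spec) {
    pitch <- spec@latticePitch / 1000 # mm
    R <- spec@bundleRadius
    rowStep <- pitch * sqrt(3) / 2
    imax <- floor(R / rowStep) + 1L
    centers <- do.call(rbind, lapply(seq(-imax, imax), function(i) {
        y <- i * rowStep
        xoff <- if (i %% 2 == 0) 0 else pitch / 2
        jmax <- floor((R + pitch) / pitch) + 1L
        x <- seq(-jmax, jmax) * pitch + xoff
        cbind(x = x, y = rep(y, length(x)))
    }))
    keep <- centers[, 1]^2 + centers[, 2]^2 <= R^2 + 1e-12
    centers <- centers[keep, , drop = FALSE]
    # innermost-first ordering makes nFibers trimming well defined
    ord <- order(centers[, 1]^2 + centers[, 2]^2, centers[, 2], centers[, 1])
    centers <- centers[ord, , drop = FALSE]
    if (is.finite(spec@nFibers)) {
        n <- as.integer(spec@nFibers)
        if (nrow(centers) < n)
            stop(sprintf("lattice holds only %d sites but nFibers = %d; enlarge bundleRadius",
                         nrow(centers), n))
        centers <- centers[seq_len(n), , drop = FALSE]
    }
    n <- nrow(centers)
    if (spec@jitterFraction > 0 && n > 0) {
        # uniform in a disk of radius jitterFraction * pitch
        rad <- spec@jitterFraction * pitch * sqrt(stats::runif(n))
        ang <- stats::runif(n, 0, 2 * pi)
        centers[, 1] <- centers[, 1] + rad * cos(ang)
        centers[, 2] <- centers[, 2] + rad * sin(ang)
    }
    data.frame(id = seq_len(n), x_mm = centers[, 1], y_mm = centers[, 2])
}

# Random patency assignment; expects the RNG to be under withSeed control.
.assignPatency <- function(spec, centers) {
    n <- nrow(centers)
    lab <- rep("open", n)
    if (n > 0 && (spec@blockedFraction > 0 || spec@partialFraction > 0)) {
        if (spec@pattern == "uniform") {
            u <- stats::runif(n)
            lab[u < spec@blockedFraction] <- "blocked"
            lab[u >= spec@blockedFraction &
                u < spec@blockedFraction + spec@partialFraction] <- "partial"
        } else {
            # peripheral: blocked fibers are the outermost, partial the next
            # ring inward, mimicking rim-first clotting
            nBlocked <- round(spec@blockedFraction * n)
            nPartial <- round(spec@partialFraction * n)
            nPartial <- min(nPartial, n - nBlocked)
            ord <- order(centers$x_mm^2 + centers$y_mm^2, decreasing = TRUE)
            if (nBlocked > 0) lab[ord[seq_len(nBlocked)]] <- "blocked"
            if (nPartial > 0)
                lab[ord[nBlocked + seq_len(nPartial)]] <- "partial"
        }
    }
    area <- ifelse(lab == "open", spec@nominalLumenArea, 0)
    partial <- lab == "partial"
    if (any(partial)) {
        frac <- stats::runif(sum(partial), spec@partialOcclusionRange[1],
                             spec@partialOcclusionRange[2])
        area[partial] <- frac * spec@nominalLumenArea
    }
    new("PhantomGroundTruth",
        fibers = data.frame(id = centers$id, x_mm = centers$x_mm,
                            y_mm = centers$y_mm, open_area_mm2 = area,
                            label = lab),
        nominalLumenArea = spec@nominalLumenArea)
}

#' Render a phantom cross-section from ground truth
#'
#' Paints the potting disk on the background, then each fiber with positive
#' open area as a dark disk of exactly that area, anti-aliased by
#' supersampled coverage; finally applies Gaussian blur and additive noise
#' per the spec. Intensities are clamped to [0, 1]. Deterministic given the
#' spec seed (only the noise draws are random).
#'
#' @param spec a [PhantomSpec-class].
#' @param truth a [PhantomGroundTruth-class]; all fibers must fall inside
#'   the image.
#' @return a [GrayscaleSlice-class].
#' @export
renderSlice <- function(spec, truth) {
    validObject(spec); validObject(truth)
    withSeed(spec@seed, .renderSlice(spec, truth))
}

.renderSlice <- function(spec, truth) {
    nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
    pxmm <- spec@pixelSize / 1000
    img <- matrix(spec@intensityBackground, nr, nc)

    # potting disk (anti-aliasing unnecessary at bundle scale)
    ys <- pixelToY(seq_len(nr), nr, pxmm)
    xs <- pixelToX(seq_len(nc), nc, pxmm)
    inside <- outer(ys^2, xs^2, "+") <= spec@bundleRadius^2
    img[inside] <- spec@intensityPotting

    fb <- truth@fibers
    fb <- fb[fb$open_area_mm2 > 0, , drop = FALSE]
    ss <- spec@supersample
    off <- (seq_len(ss) - 0.5) / ss - 0.5 # subpixel offsets
    depth <- spec@intensityPotting - spec@intensityLumen
    halfX <- (nc + 1) / 2; halfY <- (nr + 1) / 2
    for (k in seq_len(nrow(fb))) {
        r <- sqrt(fb$open_area_mm2[k] / pi)           # mm
        cx <- fb$x_mm[k] / pxmm + halfX               # pixel coords
        cy <- fb$y_mm[k] / pxmm + halfY
        rpx <- r / pxmm
        r0 <- max(1L, floor(cy - rpx - 1)); r1 <- min(nr, ceiling(cy + rpx + 1))
        c0 <- max(1L, floor(cx - rpx - 1)); c1 <- min(nc, ceiling(cx + rpx + 1))
        if (r0 > r1 || c0 > c1)
            stop("fiber outside image: enlarge imageShape")
        rows <- r0:r1; cols <- c0:c1
        # supersampled coverage of the disk over the bbox
        suby <- rep(rows, each = ss) + rep(off, length(rows)) - cy
        subx <- rep(cols, each = ss) + rep(off, length(cols)) - cx
        insideSub <- outer(suby^2, subx^2, "+") <= rpx^2
        cov <- matrix(0, length(rows), length(cols))
        idxR <- rep(seq_along(rows), each = ss)
        idxC <- rep(seq_along(cols), each = ss)
        # average the ss x ss subsamples into per-pixel coverage
        covFold <- rowsum(insideSub + 0, idxR)                 # fold rows
        covFold <- t(rowsum(t(covFold), idxC)) / (ss * ss)     # fold cols
        cov <- covFold
        img[rows, cols] <- img[rows, cols] - depth * cov
    }

    if (spec@blurSigma > 0) {
        sigmaPx <- spec@blurSigma / spec@pixelSize
        img <- matrix(EBImage::imageData(
            EBImage::gblur(EBImage::Image(img), sigma = sigmaPx)), nr, nc)
    }
    if (spec@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec@noiseSigma), nr, nc)
    img[img < 0] <- 0; img[img > 1] <- 1
    grayscaleSlice(img, pixelSize = spec@pixelSize, sliceId = "phantom")
}

#' Generate a complete phantom: image plus exact ground truth
#'
#' Composes [buildLattice()], random patency assignment (binomial per fiber
#' for the "uniform" pattern; outermost-first for "peripheral") and
#' [renderSlice()]. The same seed yields bit-identical image and truth.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{slice} ([GrayscaleSlice-class]) and
#'   \code{truth} ([PhantomGroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(bundleRadius = 1.2, blockedFraction = 0.3,
#'                                   imageShape = c(150, 150), seed = 3))
#' table(fiberTable(ph$truth)$label)
#' @export
generatePhantom <- function(spec) {
    validObject(spec)
    withSeed(spec@seed, {
        centers <- .buildLattice(spec)
        truth <- .assignPatency(spec, centers)
        slice <- .renderSlice(spec, truth)
        list(slice = slice, truth = truth)
    })
}

#' Ground-truth open-fiber count at a threshold fraction
#'
#' Number of fibers whose open lumen area strictly exceeds
#' \code{fraction * nominalArea}. This is the oracle the image pipeline is
#' compared against; the strict inequality mirrors the classification rule
#' (area of more than the threshold fraction of a full lumen).
#'
#' @param truth a [PhantomGroundTruth-class].
#' @param fraction threshold fraction in (0, 1].
#' @param nominalArea full lumen area in mm^2 (defaults to the truth's own).
#' @return integer count.
#' @export
truthCount <- function(truth, fraction = 0.70,
                       nominalArea = nominalLumenArea(truth)) {
    validObject(truth)
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("fraction must be a single number in (0, 1]")
    sum(truth@fibers$open_area_mm2 > fraction * nominalArea)
}

#' Write a phantom to disk
#'
#' The image goes to 16-bit grayscale TIFF, the ground truth to CSV (one
#' row per fiber: id, x_mm, y_mm, open_area_mm2, label) and the spec to a
#' JSON sidecar.
#'
#' @param phantom list as returned by [generatePhantom()].
#' @param spec the [PhantomSpec-class] used (stored as JSON).
#' @param dir output directory (created if missing).
#' @param basename file stem, default "phantom".
#' @return invisibly, the named character vector of paths written.
#' @export
writePhantom <- function(phantom, spec, dir, basename = "phantom") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        image = file.path(dir, paste0(basename, ".tif")),
        truth = file.path(dir, paste0(basename, "_truth.csv")),
        spec  = file.path(dir, paste0(basename, "_spec.json"))
    )
    writeSliceTiff(phantom$slice, paths[["image"]])
    utils::write.csv(phantom$truth@fibers, paths[["truth"]],
                     row.names = FALSE)
    sp <- spec
    specList <- lapply(slotNames(sp), function(nm) slot(sp, nm))
    names(specList) <- slotNames(sp)
    jsonlite::write_json(specList, paths[["spec"]], digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
    invisible(paths)
}
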