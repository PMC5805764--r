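#' Dark-side intensity thresholding
#'
#' Open lumens are darker than the potting, so the candidate-fiber mask is
#' the dark side of the threshold. Otsu's method (histogram of 256 bins
#' spanning the observed intensity range) is the default; a fixed threshold
#' value can be supplied instead. Because the bins span the observed range,
#' the Otsu mask is invariant to affine intensity rescaling a*I + b, a > 0.
#'
#' @param slice a [GrayscaleSlice-class].
#' @param method "otsu" or "fixed".
#' @param value threshold intensity for \code{method = "fixed"}.
#' @param polarity "dark" (default, lumens below the threshold) or "bright"
#'   for acquisition regimes with inverted contrast.
#' @return logical matrix, TRUE on candidate lumen pixels.
#' @export
thresholdDark <- function(slice, method = c("otsu", "fixed"), value = NULL,
                          polarity = c("dark", "bright")) {
    method <- match.arg(method)
    polarity <- match.arg(polarity)
    validObject(slice)
    m <- intensities(slice)
    if (method == "otsu") {
        rng <- range(m)
        if (diff(rng) == 0)
            stop("constant image: Otsu thresholding needs a bimodal histogram")
        thr <- EBImage::otsu(EBImage::Image(m), range = rng, levels = 256L)
    } else {
        if (is.null(value) || !is.finite(value))
            stop("method = 'fixed' needs a finite threshold value")
        thr <- value
    }
    if (polarity == "dark") m < thr else m > thr
}

# Two-stage threshold refinement for multimodal images. A global Otsu split
# of a mostly-blocked cross-section can land between the potting and the
# outside background, flooding the whole bundle into one giant dark
# component. Any dark component covering more than plateauFraction of the
# image cannot be a fiber lumen; it is re-thresholded internally (Otsu on
# its own pixels). If no dark sub-mode exists (constant plateau, or the
# "dark" side is just the lower half of the noise, > speckleFraction of the
# component), the component is removed entirely.
.refinePlateaus <- function(mask, img, plateauFraction = 0.25,
                            speckleFraction = 0.25) {
    if (!any(mask)) return(mask)
    lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    sizes <- tabulate(lab[lab > 0L])
    big <- which(sizes > plateauFraction * length(mask))
    for (k in big) {
        comp <- which(lab == k)
        vals <- img[comp]
        rng <- range(vals)
        if (diff(rng) == 0) { mask[comp] <- FALSE; next }
        t2 <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1L)),
                            range = rng, levels = 256L)
        sub <- vals < t2
        if (mean(sub) > speckleFraction) mask[comp] <- FALSE
        else mask[comp[!sub]] <- FALSE
    }
    mask
}

#' Detect the fiber-bundle region of interest
#'
#' Morphological closing (disc of \code{closingRadiusUm}, by default about
#' twice the expected fiber pitch) glues the lumen dots into blobs; the
#' largest blob seeds the bundle, and its convex hull becomes the ROI,
#' bordering the entire fiber bundle so that disturbances outside it are
#' excluded from counting. Because heavily clotted sections leave only
#' sparse dots, the hull is then grown iteratively: any mask component
#' lying within \code{expandUm} of the current hull is merged and the hull
#' recomputed, until stable. Components farther away (spurious dark objects
#' outside the bundle) remain excluded. Downstream, particles are retained
#' when their centroid falls inside the ROI.
#'
#' @param mask logical matrix from [thresholdDark()].
#' @param pixelSize um per pixel.
#' @param closingRadiusUm closing radius in um (default 620).
#' @param expandUm hull-expansion reach in um (default twice the closing
#'   radius).
#' @return logical matrix marking the ROI (a single convex region).
#' @export
detectBundleRoi <- function(mask, pixelSize, closingRadiusUm = 620,
                            expandUm = 2 * closingRadiusUm) {
    if (!any(mask)) stop("empty mask: no candidate pixels to border")
    nr <- nrow(mask); nc <- ncol(mask)
    rPx <- max(1L, round(closingRadiusUm / pixelSize))
    brush <- EBImage::makeBrush(2L * rPx + 1L, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(mask + 0), brush) > 0.5
    clab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(closed + 0))),
                   nr, nc)
    # the bundle seed is the closed component holding the most mask pixels
    # (closing clips at image borders, so a closed component is not
    # guaranteed to contain its generators)
    inClosed <- tabulate(clab[mask & clab > 0L])
    if (length(inClosed) == 0L) return(.convexFill(mask))
    seed <- clab == which.max(inClosed)
    # components of the raw mask and their membership in the ROI set
    mlab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask + 0))),
                   nr, nc)
    nComp <- max(mlab)
    inRoi <- logical(nComp)
    inRoi[unique(mlab[mask & seed])] <- TRUE
    expandPx <- expandUm / pixelSize
    member <- mask & (mlab > 0L) & inRoi[pmax(mlab, 1L)]
    for (iter in seq_len(25L)) {
        hull <- .convexFill(member)
        out <- which(!inRoi)
        if (length(out) == 0L) break
        dist <- EBImage::distmap(EBImage::Image(1 - (hull + 0)))
        dist <- matrix(as.numeric(dist), nr, nc)
        outside <- mask & !inRoi[pmax(mlab, 1L)] & mlab > 0L
        dmin <- tapply(dist[outside], mlab[outside], min)
        near <- as.integer(names(dmin))[dmin <= expandPx]
        if (length(near) == 0L) break
        inRoi[near] <- TRUE
        member <- mask & inRoi[pmax(mlab, 1L)]
    }
    hull
}

# Fill the convex hull of the TRUE pixels of a logical matrix by scanline
# intersection with the hull polygon (pixel centres as vertices).
.convexFill <- function(b) {
    idx <- which(b)
    nr <- nrow(b)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    h <- grDevices::chull(cols, rows)
    vx <- cols[h]; vy <- rows[h]
    out <- matrix(FALSE, nr, ncol(b))
    n <- length(vx)
    if (n == 1L) { out[vy, vx] <- TRUE; return(out) }
    if (n == 2L) { # degenerate hull: a segment
        steps <- max(abs(vx[2] - vx[1]), abs(vy[2] - vy[1])) + 1L
        xs <- round(seq(vx[1], vx[2], length.out = steps))
        ys <- round(seq(vy[1], vy[2], length.out = steps))
        out[cbind(ys, xs)] <- TRUE
        return(out)
    }
    for (y0 in seq(min(vy), max(vy))) {
        xs <- numeric(0)
        for (e in seq_len(n)) {
            y1 <- vy[e]; y2 <- vy[if (e == n) 1L else e + 1L]
            x1 <- vx[e]; x2 <- vx[if (e == n) 1L else e + 1L]
            if (y1 == y2) {
                if (y1 == y0) xs <- c(xs, x1, x2)
                next
            }
            tt <- (y0 - y1) / (y2 - y1)
            if (tt >= 0 && tt <= 1) xs <- c(xs, x1 + tt * (x2 - x1))
        }
        if (length(xs))
            out[y0, max(1L, floor(min(xs))):min(ncol(b), ceiling(max(xs)))] <- TRUE
    }
    out
}

#' Watershed separation of touching lumens
#'
#' Distance-transform watershed: the Euclidean distance map of the mask is
#' flooded from its regional maxima, splitting touching particles along the
#' ridge lines while leaving isolated particles untouched. The maxima
#' detection radius corresponds to \code{minSeparationUm}, by default half
#' the expected lumen diameter (~96 um for a 0.029 mm^2 lumen), so one
#' seed survives per fiber-sized particle.
#'
#' @param mask logical matrix of candidate pixels.
#' @param pixelSize um per pixel.
#' @param minSeparationUm minimum seed separation in um.
#' @param tolerance minimum distance-map depth (in pixels) separating two
#'   seeds for them to stay distinct objects.
#' @return integer matrix: 0 background, 1..K particle labels.
#' @export
watershedSplit <- function(mask, pixelSize,
                           minSeparationUm = 1000 * sqrt(0.0204 / 0.70 / pi),
                           tolerance = 1) {
    nr <- nrow(mask); nc <- ncol(mask)
    if (!any(mask)) return(matrix(0L, nr, nc))
    dm <- EBImage::distmap(EBImage::Image(mask + 0))
    ext <- max(1L, round(minSeparationUm / pixelSize))
    w <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
    lab <- matrix(as.integer(w), nr, nc)
    # relabel to a contiguous 1..K in scan order
    u <- sort(unique(lab[lab > 0L]))
    if (length(u) && !identical(u, seq_along(u))) {
        map <- integer(max(u)); map[u] <- seq_along(u)
        pos <- lab > 0L
        lab[pos] <- map[lab[pos]]
    }
    lab
}

# Weighted boundary-step perimeter (in pixels) of a single cropped binary
# particle. Border pixels are classified by their border-pixel neighbourhood
# (kernel value = 1 + 2*straight + 10*diagonal neighbours); straight runs,
# diagonal runs and corners get distinct step lengths, scaled by the
# Vossepoel-Smeulders digitization correction so smooth contours are
# estimated without the systematic overshoot of raw chain-code lengths.
.stepWeights <- local({
    w <- numeric(49)
    corr <- 0.948                    # straight-step correction
    w[c(5, 7, 15, 17, 25, 27) ] <- corr        # straight
    w[c(21, 33)] <- sqrt(2) * corr             # diagonal
    w[c(13, 23)] <- (1 + sqrt(2)) / 2 * corr   # corner
    w
})

.perimeterSteps <- function(b) {
    nr <- nrow(b); nc <- ncol(b)
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- b
    ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
    up    <- p[1:nr,           2:(nc + 1L)]
    down  <- p[3:(nr + 2L),    2:(nc + 1L)]
    left  <- p[2:(nr + 1L),    1:nc]
    right <- p[2:(nr + 1L),    3:(nc + 2L)]
    border <- ctr & !(up & down & left & right)
    if (!any(border)) return(0)
    q <- matrix(FALSE, nr + 2L, nc + 2L)
    q[2:(nr + 1L), 2:(nc + 1L)] <- border
    straight <- q[1:nr, 2:(nc + 1L)] + q[3:(nr + 2L), 2:(nc + 1L)] +
                q[2:(nr + 1L), 1:nc] + q[2:(nr + 1L), 3:(nc + 2L)]
    diagonal <- q[1:nr, 1:nc] + q[1:nr, 3:(nc + 2L)] +
                q[3:(nr + 2L), 1:nc] + q[3:(nr + 2L), 3:(nc + 2L)]
    v <- (1L + 2L * straight + 10L * diagonal)[border]
    sum(.stepWeights[v])
}

#' Measure labelled particles
#'
#' Per label: area (pixel count times pixel area), perimeter (weighted
#' boundary-step estimator, see details), circularity
#' \eqn{\min(1, 4\pi A / P^2)} and centroid (mean of pixel centres, mm,
#' origin at the image centre). Degenerate particles whose boundary is too
#' small to carry steps (single pixels) get circularity 1.
#'
#' @param labeling integer matrix from [watershedSplit()] (or any labelling
#'   with 0 = background).
#' @param pixelSize um per pixel.
#' @return data.frame with columns label, area_mm2, perimeter_mm,
#'   circularity, x_mm, y_mm (empty for an empty labelling).
#' @export
measureParticles <- function(labeling, pixelSize) {
    empty <- data.frame(label = integer(0), area_mm2 = numeric(0),
                        perimeter_mm = numeric(0), circularity = numeric(0),
                        x_mm = numeric(0), y_mm = numeric(0))
    K <- max(labeling)
    if (K < 1L) return(empty)
    nr <- nrow(labeling); nc <- ncol(labeling)
    pxmm <- pixelSize / 1000
    pxArea <- pxmm^2
    idx <- which(labeling > 0L)
    labs <- labeling[idx]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    byLab <- split(seq_along(idx), labs)
    out <- lapply(byLab, function(ii) {
        r <- rows[ii]; cc <- cols[ii]
        r0 <- min(r); c0 <- min(cc)
        crop <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
        crop[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
        per <- .perimeterSteps(crop) * pxmm
        area <- length(ii) * pxArea
        circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
        c(area, per, circ, mean(cc), mean(r))
    })
    out <- do.call(rbind, out)
    data.frame(
        label = as.integer(names(byLab)),
        area_mm2 = out[, 1],
        perimeter_mm = out[, 2],
        circularity = out[, 3],
        x_mm = pixelToX(out[, 4], nc, pxmm),
        y_mm = pixelToY(out[, 5], nr, pxmm),
        row.names = NULL)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labeling integer label matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLabelTiff <- function(labeling, path) {
    tiff::writeTIFF(labeling / max(1L, max(labeling)), path,
                    bits.per.sample = 16L, compression = "none")
    invisible(path)
}
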