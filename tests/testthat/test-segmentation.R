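test_that("thresholding separates a two-level image exactly", {
    m <- matrix(200, 30, 30)
    dark <- cbind(sample(30, 40, TRUE), sample(30, 40, TRUE))
    m[dark] <- 10
    mask <- thresholdDark(grayscaleSlice(m, 25))
    expect_identical(mask, m == 10)
})

test_that("Otsu on a constant image raises a bimodality error", {
    expect_error(thresholdDark(grayscaleSlice(matrix(7, 20, 20), 25)),
                 "bimodal|constant")
})

test_that("fixed thresholding needs a value and respects polarity", {
    m <- matrix(c(0.1, 0.9), 10, 10)
    s <- grayscaleSlice(m, 25)
    expect_error(thresholdDark(s, method = "fixed"), "value")
    expect_identical(thresholdDark(s, method = "fixed", value = 0.5),
                     m < 0.5)
    expect_identical(thresholdDark(s, method = "fixed", value = 0.5,
                                   polarity = "bright"), m > 0.5)
})

test_that("masked dot areas on a clean phantom equal the rendered areas", {
    sp <- smallSpec(seed = 41, bundleRadius = 1.2, partialFraction = 0.3,
                    imageShape = c(150, 150))
    ph <- generatePhantom(sp)
    mask <- thresholdDark(ph$slice)
    lab <- watershedSplit(mask, 25)
    parts <- measureParticles(lab, 25)
    fb <- fiberTable(ph$truth)
    fb <- fb[fb$open_area_mm2 > 0, ]
    expect_identical(nrow(parts), nrow(fb))
    # match by position and compare areas; Otsu places the cut slightly
    # below the mid-level, so anti-aliased edge pixels add a small positive
    # bias (a ring well under half a pixel wide around each dot)
    for (i in seq_len(nrow(fb))) {
        j <- which.min((parts$x_mm - fb$x_mm[i])^2 +
                       (parts$y_mm - fb$y_mm[i])^2)
        expect_lt(abs(parts$area_mm2[j] - fb$open_area_mm2[i]),
                  8 * 0.025^2)
    }
})

test_that("Otsu masks are invariant to affine intensity rescaling", {
    sp <- smallSpec(seed = 43, bundleRadius = 1, imageShape = c(130, 130),
                    noiseSigma = 0.02, blurSigma = 12.5)
    ph <- generatePhantom(sp)
    m <- intensities(ph$slice)
    m1 <- thresholdDark(grayscaleSlice(m, 25))
    m2 <- thresholdDark(grayscaleSlice(2.5 * m + 10, 25))
    expect_identical(m1, m2)
})

test_that("bundle ROI excludes distant disturbances and keeps all fibers", {
    sp <- smallSpec(seed = 47, bundleRadius = 1, imageShape = c(220, 220))
    ph <- generatePhantom(sp)
    m <- intensities(ph$slice)
    # spurious dark blob far outside the bundle (corner, ~2 mm away)
    m[8:14, 8:14] <- sp@intensityLumen
    slice <- grayscaleSlice(m, 25)
    mask <- thresholdDark(slice)
    roi <- detectBundleRoi(mask, 25)
    expect_false(roi[11, 11])
    res <- countOpenFibers(slice, roi = roi)
    expect_identical(res$n_open, truthCount(ph$truth))
    # auto-detected ROI inside the pipeline gives the same answer
    expect_identical(countOpenFibers(slice)$n_open, truthCount(ph$truth))
})

test_that("ROI of a single dot degenerates to that dot", {
    mask <- matrix(FALSE, 50, 50)
    mask[20:23, 30:33] <- TRUE
    roi <- detectBundleRoi(mask, 25)
    expect_true(all(roi[mask]))
    expect_lt(sum(roi), 3 * sum(mask))
})

test_that("ROI area approximates the bundle disk", {
    sp <- smallSpec(seed = 53, bundleRadius = 1.6, imageShape = c(170, 170))
    ph <- generatePhantom(sp)
    roi <- detectBundleRoi(thresholdDark(ph$slice), 25)
    bundlePx <- pi * (1.6 / 0.025)^2
    expect_lt(abs(sum(roi) - bundlePx) / bundlePx, 0.10)
})

test_that("empty masks are rejected by ROI detection", {
    expect_error(detectBundleRoi(matrix(FALSE, 10, 10), 25), "empty")
})

test_that("watershed splits overlapping equal disks into two particles", {
    n <- 100
    d1 <- outer(1:n, 1:n, function(r, c) (r - 50)^2 + (c - 32)^2 <= 400)
    d2 <- outer(1:n, 1:n, function(r, c) (r - 50)^2 + (c - 68)^2 <= 400)
    w <- watershedSplit(d1 | d2, 25, minSeparationUm = 250)
    expect_identical(max(w), 2L)
    areas <- tabulate(w[w > 0])
    expect_true(all(abs(areas - sum(d1)) / sum(d1) < 0.15))
})

test_that("watershed leaves an isolated particle untouched", {
    n <- 60
    d <- outer(1:n, 1:n, function(r, c) (r - 30)^2 + (c - 30)^2 <= 150)
    w <- watershedSplit(d, 25)
    expect_identical(max(w), 1L)
    expect_identical(w > 0, d)
})

test_that("watershed recovers touching fiber pairs exactly", {
    set.seed(1)
    base <- expand.grid(x = seq(-1.2, 1.2, by = 0.48),
                        y = seq(-1.2, 1.2, by = 0.48))
    base <- base[sample(nrow(base), 20), ]
    pairs <- rbind(c(-1.8, 0), c(-1.61, 0), c(1.8, 0.5), c(1.8, 0.69),
                   c(0, 1.9), c(0.19, 1.9))
    tr <- truthAt(rbind(as.matrix(base), pairs))
    sp <- phantomSpec(bundleRadius = 2.6, imageShape = c(240, 240),
                      blurSigma = 12.5, noiseSigma = 0, seed = 3)
    mask <- thresholdDark(renderSlice(sp, tr))
    comps <- max(EBImage::bwlabel(EBImage::Image(mask + 0)))
    expect_lt(comps, nrow(fiberTable(tr)))       # some dots really touch
    w <- watershedSplit(mask, 25)
    expect_identical(max(w), nrow(fiberTable(tr)))
})

test_that("particle measurement matches rasterization oracles", {
    # digital disk, radius 20 px at 25 um/px
    p <- measureParticles(diskLabel(20), 25)
    expect_lt(abs(p$area_mm2 - pi * (20 * 0.025)^2) / (pi * 0.5^2), 0.02)
    expect_gte(p$circularity, 0.95)
    expect_lte(p$circularity, 1)
    # single pixel: area is one pixel area
    one <- matrix(0L, 5, 5); one[3, 3] <- 1L
    expect_equal(measureParticles(one, 25)$area_mm2, 0.000625)
    # a 40 x 2 bar is far from circular
    bar <- matrix(0L, 10, 50); bar[5:6, 6:45] <- 1L
    expect_lt(measureParticles(bar, 25)$circularity, 0.5)
    # empty labelling
    expect_identical(nrow(measureParticles(matrix(0L, 8, 8), 25)), 0L)
})

test_that("centroids are reported in centred physical coordinates", {
    lab <- matrix(0L, 41, 41); lab[21, 21] <- 1L
    p <- measureParticles(lab, 25)
    expect_equal(c(p$x_mm, p$y_mm), c(0, 0))
    lab2 <- matrix(0L, 41, 41); lab2[21, 31] <- 1L
    p2 <- measureParticles(lab2, 25)
    expect_equal(p2$x_mm, 10 * 0.025)
    expect_equal(p2$y_mm, 0)
})

test_that("label areas conserve the masked area up to watershed lines", {
    sp <- smallSpec(seed = 59, bundleRadius = 1.4, imageShape = c(160, 160),
                    blurSigma = 12.5)
    ph <- generatePhantom(sp)
    mask <- thresholdDark(ph$slice)
    w <- watershedSplit(mask, 25)
    expect_lte(sum(w > 0), sum(mask))
    expect_lt((sum(mask) - sum(w > 0)) / sum(mask), 0.03)
})

test_that("counting is invariant to translation and 90-degree rotation", {
    sp <- smallSpec(seed = 4, bundleRadius = 1.3, imageShape = c(160, 160),
                    blockedFraction = 0.2)
    ph <- generatePhantom(sp)
    m <- intensities(ph$slice)
    n0 <- countOpenFibers(ph$slice)$n_open
    shifted <- matrix(sp@intensityBackground, 160, 160)
    shifted[6:160, 4:160] <- m[1:155, 1:157]
    expect_identical(countOpenFibers(grayscaleSlice(shifted, 25))$n_open, n0)
    rotated <- t(m)[160:1, ]
    expect_identical(countOpenFibers(grayscaleSlice(rotated, 25))$n_open, n0)
})
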