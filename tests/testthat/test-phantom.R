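test_that("hexagonal lattice matches brute-force site enumeration", {
    lumenDiam <- 2 * sqrt(NOMINAL_LUMEN / pi) * 1000      # um
    pitch <- 2 * lumenDiam
    radius <- 1.5 * pitch / 1000                          # mm
    sp <- phantomSpec(bundleRadius = radius, latticePitch = pitch,
                      imageShape = c(120, 120), jitterFraction = 0)
    lat <- buildLattice(sp)
    # independent oracle: enumerate all hex sites on a generous grid and
    # keep those within the disk
    p <- pitch / 1000
    sites <- 0L
    for (i in -10:10) {
        y <- i * p * sqrt(3) / 2
        xoff <- if (i %% 2 == 0) 0 else p / 2
        for (j in -10:10) {
            x <- j * p + xoff
            if (x^2 + y^2 <= radius^2 + 1e-12) sites <- sites + 1L
        }
    }
    expect_identical(nrow(lat), sites)
    # centres respect the pitch (no jitter)
    dmat <- as.matrix(dist(lat[, c("x_mm", "y_mm")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), p - 1e-9)
})

test_that("zero-radius bundle holds exactly the origin fiber", {
    sp <- phantomSpec(bundleRadius = 0, imageShape = c(40, 40),
                      jitterFraction = 0)
    lat <- buildLattice(sp)
    expect_identical(nrow(lat), 1L)
    expect_equal(c(lat$x_mm, lat$y_mm), c(0, 0))
})

test_that("FX600-scale lattice approaches the blanco fiber total", {
    sp <- phantomSpec(bundleRadius = 16.5, latticePitch = 310,
                      jitterFraction = 0)
    n <- nrow(buildLattice(sp))
    # hex-packing density oracle: pi R^2 * (2/sqrt(3)) / pitch^2
    oracle <- pi * 16.5^2 * (2 / sqrt(3)) / 0.310^2
    expect_lt(abs(n - oracle) / oracle, 0.02)
    expect_lt(abs(n - 10748) / 10748, 0.05)
    # package default pitch is calibrated to the blanco total itself
    expect_lt(abs(nrow(buildLattice(phantomSpec())) - 10748) / 10748, 0.005)
})

test_that("a pitch below the lumen diameter is rejected", {
    expect_error(phantomSpec(latticePitch = 150, imageShape = c(100, 100),
                             bundleRadius = 1),
                 "overlap")
})

test_that("rendered dark area matches ground-truth open area", {
    sp <- smallSpec(bundleRadius = 0.6, imageShape = c(80, 80))
    tr <- truthAt(cbind(0.05, -0.04))
    sl <- renderSlice(sp, tr)
    m <- intensities(sl)
    # pixels darker than midway between lumen and potting, weighted is not
    # needed: compare thresholded area to truth within one pixel area
    darkArea <- sum(m < 0.4) * (0.025)^2
    expect_lt(abs(darkArea - NOMINAL_LUMEN), 0.025^2)
    # supersampled coverage is much tighter than the hard-threshold count:
    # total missing intensity equals area to < 2% at the default 8x factor
    cov <- sum((sp@intensityPotting - pmin(m, sp@intensityPotting)) /
               (sp@intensityPotting - sp@intensityLumen)) * 0.025^2
    expect_lt(abs(cov - NOMINAL_LUMEN) / NOMINAL_LUMEN, 0.02)
})

test_that("fully blocked phantom renders no dark pixel inside the bundle", {
    sp <- smallSpec(seed = 9, blockedFraction = 1)
    ph <- generatePhantom(sp)
    m <- intensities(ph$slice)
    expect_true(all(m >= sp@intensityPotting - 1e-9))
    expect_true(all(fiberTable(ph$truth)$open_area_mm2 == 0))
})

test_that("fibers at a pitch just above the lumen diameter touch after blur", {
    # centres 200 um apart, lumen diameter ~193 um: distinct disks whose
    # rendered dots fuse once blurred; the truth still lists both fibers
    tr <- truthAt(rbind(c(-0.1, 0), c(0.1, 0)))
    sp <- phantomSpec(bundleRadius = 0.8, imageShape = c(90, 90),
                      blurSigma = 12.5, noiseSigma = 0, seed = 2)
    sl <- renderSlice(sp, tr)
    mask <- thresholdDark(sl)
    comps <- max(EBImage::bwlabel(EBImage::Image(mask + 0)))
    expect_identical(as.integer(comps), 1L)
    expect_identical(nrow(fiberTable(tr)), 2L)
})

test_that("generatePhantom is deterministic given the seed", {
    sp <- smallSpec(seed = 11, blockedFraction = 0.4, partialFraction = 0.2,
                    noiseSigma = 0.02, blurSigma = 12.5)
    a <- generatePhantom(sp)
    b <- generatePhantom(sp)
    expect_identical(intensities(a$slice), intensities(b$slice))
    expect_identical(fiberTable(a$truth), fiberTable(b$truth))
    # and byte-identical on disk
    d1 <- withr::local_tempdir()
    writePhantom(a, sp, d1, "p1")
    writePhantom(b, sp, d1, "p2")
    expect_identical(unname(tools::md5sum(file.path(d1, "p1.tif"))),
                     unname(tools::md5sum(file.path(d1, "p2.tif"))))
})

test_that("patency assignment follows the requested fractions", {
    sp <- phantomSpec(bundleRadius = 3, nFibers = 200,
                      imageShape = c(300, 300), blockedFraction = 0.3,
                      seed = 21, noiseSigma = 0, blurSigma = 0)
    ph <- generatePhantom(sp)
    fb <- fiberTable(ph$truth)
    expect_identical(nrow(fb), 200L)
    nOpen <- sum(fb$label == "open")
    # binomial(200, 0.7): stay within 5 sd of the mean
    expect_lt(abs(nOpen - 140), 5 * sqrt(200 * 0.3 * 0.7))
    expect_identical(truthCount(ph$truth, 0.999), nOpen)
})

test_that("partial occlusion below the threshold is never patent", {
    sp <- smallSpec(seed = 31, partialFraction = 0.5,
                    partialOcclusionRange = c(0.2, 0.6))
    ph <- generatePhantom(sp)
    fb <- fiberTable(ph$truth)
    partial <- fb[fb$label == "partial", ]
    expect_gt(nrow(partial), 0)
    expect_true(all(partial$open_area_mm2 <= 0.6 * NOMINAL_LUMEN + 1e-12))
    expect_true(all(partial$open_area_mm2 < 0.7 * NOMINAL_LUMEN))
})

test_that("truthCount applies a strict area inequality", {
    allOpen <- truthAt(cbind(runif(10, -1, 1), runif(10, -1, 1)))
    expect_identical(truthCount(allOpen, 0.1), 10L)
    expect_identical(truthCount(allOpen, 1), 0L)  # open_area == nominal
    # a fiber exactly at fraction * nominal is NOT counted
    exact <- truthAt(cbind(0, 0), openArea = 0.7 * NOMINAL_LUMEN)
    expect_identical(truthCount(exact, 0.7), 0L)
    expect_identical(truthCount(exact, 0.699), 1L)
    # brute-force scan oracle on a mixed list
    areas <- c(0, 0.004, 0.01, 0.018, 0.0204, 0.0205, 0.022, 0.025,
               0.029, 0.0291)
    mixed <- truthAt(cbind(seq(-1, 1, length.out = 10), 0),
                     openArea = areas)
    for (f in c(0.3, 0.6, 0.7, 0.8, 1)) {
        expect_identical(truthCount(mixed, f),
                         sum(areas > f * NOMINAL_LUMEN))
    }
})

test_that("truthCount is non-increasing in the threshold fraction", {
    for (seed in 1:5) {
        sp <- smallSpec(seed = seed, blockedFraction = 0.3,
                        partialFraction = 0.3)
        ph <- generatePhantom(sp)
        fr <- seq(0.05, 1, by = 0.05)
        counts <- vapply(fr, function(f) truthCount(ph$truth, f),
                         integer(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("phantom truth respects lattice spacing bounds", {
    sp <- smallSpec(seed = 13, jitterFraction = 0.1)
    ph <- generatePhantom(sp)
    fb <- fiberTable(ph$truth)
    dmat <- as.matrix(dist(fb[, c("x_mm", "y_mm")]))
    diag(dmat) <- Inf
    pitch <- sp@latticePitch / 1000
    expect_gte(min(dmat), pitch - 2 * 0.1 * pitch - 1e-9)
})

test_that("phantom files round-trip through TIFF and CSV", {
    sp <- smallSpec(seed = 17, bundleRadius = 0.8, imageShape = c(100, 100),
                    noiseSigma = 0.02, blurSigma = 12.5)
    ph <- generatePhantom(sp)
    d <- withr::local_tempdir()
    paths <- writePhantom(ph, sp, d)
    expect_true(all(file.exists(paths)))
    back <- readSliceTiff(paths[["image"]], pixelSize = 25)
    expect_identical(dim(intensities(back)), dim(intensities(ph$slice)))
    # 16-bit quantization error only
    expect_lt(max(abs(intensities(back) - intensities(ph$slice))),
              1 / 65535 + 1e-9)
    tr <- read.csv(paths[["truth"]])
    expect_identical(nrow(tr), nrow(fiberTable(ph$truth)))
})
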