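# Shared fixture builders. All phantoms are generated in code at test time;
# sizes are kept small so the whole suite stays fast.

NOMINAL_LUMEN <- 0.0204 / 0.70

# a small clean phantom spec (no blur/noise unless asked)
smallSpec <- function(seed = 1, bundleRadius = 1.5, imageShape = c(180, 180),
                      blockedFraction = 0, partialFraction = 0,
                      noiseSigma = 0, blurSigma = 0, ...) {
    phantomSpec(bundleRadius = bundleRadius, imageShape = imageShape,
                blockedFraction = blockedFraction,
                partialFraction = partialFraction,
                noiseSigma = noiseSigma, blurSigma = blurSigma,
                seed = seed, ...)
}

# ground truth with explicit fiber centres, all fully open
truthAt <- function(centers, openArea = NOMINAL_LUMEN) {
    n <- nrow(centers)
    area <- rep_len(openArea, n)
    new("PhantomGroundTruth",
        fibers = data.frame(id = seq_len(n), x_mm = centers[, 1],
                            y_mm = centers[, 2], open_area_mm2 = area,
                            label = ifelse(area >= NOMINAL_LUMEN - 1e-12,
                                           "open",
                                           ifelse(area > 0, "partial",
                                                  "blocked"))),
        nominalLumenArea = NOMINAL_LUMEN)
}

# random particle table resembling measureParticles() output
randomParticles <- function(n, seed) {
    set.seed(seed)
    data.frame(
        label = seq_len(n),
        area_mm2 = runif(n, 0, 3 * NOMINAL_LUMEN),
        perimeter_mm = runif(n, 0.1, 1),
        circularity = runif(n),
        x_mm = runif(n, -5, 5), y_mm = runif(n, -5, 5))
}

# rasterized digital disk as a label matrix
diskLabel <- function(radiusPx, pad = 3L) {
    n <- 2L * ceiling(radiusPx) + 2L * pad + 1L
    ctr <- (n + 1L) / 2
    matrix(as.integer(outer(seq_len(n), seq_len(n), function(r, cc)
        (r - ctr)^2 + (cc - ctr)^2 <= radiusPx^2)), n, n)
}
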