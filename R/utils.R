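# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's random stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Physical x (mm) of pixel column c and y (mm) of pixel row r, 1-based,
# origin at the image centre; pixel centres sit at half-integer offsets.
pixelToX <- function(col, ncol, pxmm) (col - (ncol + 1) / 2) * pxmm
pixelToY <- function(row, nrow, pxmm) (row - (nrow + 1) / 2) * pxmm
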