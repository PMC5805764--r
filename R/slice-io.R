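#' Read a grayscale slice from TIFF or PNG
#'
#' Multi-page TIFFs are treated as slice stacks, \code{page} selecting one
#' slice (1-based). The pixel size must be supplied by the caller: TIFF
#' resolution tags are unreliable in reconstructed CT exports and are
#' deliberately ignored. RGB(A) inputs are averaged to grayscale.
#' Intensities arrive on the [0, 1] scale used throughout.
#'
#' @param path TIFF or PNG file.
#' @param pixelSize physical pixel size in micrometres.
#' @param page page index for multi-page TIFF stacks.
#' @param sliceId slice tag; defaults to the file stem (plus page for
#'   stacks).
#' @return a [GrayscaleSlice-class].
#' @export
readSliceTiff <- function(path, pixelSize, page = 1L, sliceId = NULL) {
    if (!file.exists(path)) stop("no such image file: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        img <- png::readPNG(path)
        if (page != 1L) stop("PNG files hold a single slice; page must be 1")
    } else {
        pages <- tiff::readTIFF(path, all = TRUE)
        if (page < 1L || page > length(pages))
            stop(sprintf("page %d out of range: stack has %d page(s)",
                         page, length(pages)))
        img <- pages[[page]]
        if (length(pages) > 1L && is.null(sliceId))
            sliceId <- sprintf("%s_p%d",
                               tools::file_path_sans_ext(basename(path)),
                               page)
    }
    if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
    if (is.null(sliceId))
        sliceId <- tools::file_path_sans_ext(basename(path))
    grayscaleSlice(img, pixelSize = pixelSize, sliceId = sliceId)
}

#' Write a slice (or stack) as 16-bit grayscale TIFF
#'
#' @param slice a [GrayscaleSlice-class] or a list of them (written as a
#'   multi-page stack). Intensities above 1 are scaled down by the maximum
#'   before quantization.
#' @param path output .tif path.
#' @return invisibly, \code{path}.
#' @export
writeSliceTiff <- function(slice, path) {
    slices <- if (is(slice, "GrayscaleSlice")) list(slice) else slice
    mats <- lapply(slices, function(s) {
        m <- intensities(s)
        if (max(m) > 1) m <- m / max(m)
        m
    })
    tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none",
                    reduce = TRUE)
    invisible(path)
}

#' Read a binary ROI mask from TIFF/PNG
#'
#' Any pixel above half the intensity range counts as inside the region.
#'
#' @param path image file.
#' @return logical matrix.
#' @export
readRoiMask <- function(path) {
    s <- readSliceTiff(path, pixelSize = 1)
    intensities(s) > 0.5
}
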