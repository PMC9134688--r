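#' Percent positively-stained area of a hemisphere section
#'
#' After absolute-value background subtraction, a pixel inside the hemisphere
#' mask is positive when `|intensity - backgroundValue| > threshold`. The
#' score is the percentage of mask pixels that are positive. When `threshold`
#' is `NULL` it is set to the midpoint between the background and foreground
#' intensity modes of the masked image (two-cluster k-means seeded at the
#' intensity extremes), expressed as a deviation from `backgroundValue`.
#'
#' @param image numeric matrix of grayscale intensities.
#' @param mask logical matrix of the same shape; `TRUE` inside the
#'   hemisphere.
#' @param backgroundValue intensity of unstained tissue.
#' @param threshold deviation cut-off (same units as `image`), or `NULL` for
#'   the automatic midpoint rule.
#' @return list of class `"areaFraction"`: `positivePixels`, `maskPixels`,
#'   `percentPositive`, `threshold`.
#' @examples
#' im <- matrix(50, 10, 10); im[1:5, 1:5] <- 200
#' percentPositiveArea(im, matrix(TRUE, 10, 10), 50, 75)$percentPositive
#' @export
percentPositiveArea <- function(image, mask, backgroundValue,
                                threshold = NULL) {
    if (!identical(dim(image), dim(mask)))
        stop("image and mask dimensions differ")
    if (!any(mask)) stop("empty hemisphere mask")
    px <- image[mask]
    if (is.null(threshold)) {
        if (diff(range(px)) == 0) {
            threshold <- 0
        } else {
            km <- suppressWarnings(kmeans(px, centers = range(px)))
            dev <- sort(abs(km$centers[, 1] - backgroundValue))
            threshold <- mean(dev)
        }
    }
    if (threshold < 0) stop("'threshold' must be non-negative")
    pos <- sum(abs(px - backgroundValue) > threshold)
    structure(list(positivePixels = pos, maskPixels = length(px),
        percentPositive = 100 * pos / length(px), threshold = threshold),
        class = "areaFraction")
}

#' @export
print.areaFraction <- function(x, ...) {
    cat(sprintf("%.2f%% positive area (%d / %d pixels, threshold %.3g)\n",
        x$percentPositive, x$positivePixels, x$maskPixels, x$threshold))
    invisible(x)
}

#' Read and write grayscale section images as TIFF
#'
#' Intensities are stored scaled to `[0, 1]` (divided by `scale`); masks are
#' stored as 0/1 images.
#'
#' @param image numeric matrix; `mask` logical matrix.
#' @param path file path.
#' @param scale intensity corresponding to white (default 255).
#' @return `readIHCImage()` returns a numeric matrix on the original
#'   intensity scale; `readIHCMask()` a logical matrix.
#' @export
writeIHCImage <- function(image, path, scale = 255) {
    tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
        bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeIHCImage
#' @export
readIHCImage <- function(path, scale = 255) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * scale
}

#' @rdname writeIHCImage
#' @export
writeIHCMask <- function(mask, path) {
    tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeIHCImage
#' @export
readIHCMask <- function(path) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
}
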