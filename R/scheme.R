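#' Construct a diffusion acquisition scheme
#'
#' Builds a single-shell scheme with `nB0` non-diffusion-weighted volumes
#' followed by `nDirections` diffusion-weighted volumes at `bValue`.
#' Directions are placed deterministically on the unit sphere by the
#' Fibonacci-spiral construction, which is approximately uniform and
#' reproducible without iterative electrostatic repulsion.
#'
#' @param nDirections number of diffusion-weighted directions (>= 6 for
#'   tensor identifiability).
#' @param bValue diffusion weighting in s/mm^2 for the weighted volumes.
#' @param nB0 number of b = 0 volumes (default 1).
#' @param seed unused by the deterministic construction; accepted so that the
#'   generator API is uniformly seedable.
#' @return a [DiffusionScheme-class] with `nB0 + nDirections` rows.
#' @examples
#' sch <- makeScheme(30, 970)
#' table(bValues(sch))
#' @export
makeScheme <- function(nDirections, bValue, nB0 = 1L, seed = 0L) {
    if (nDirections < 6L)
        stop("at least 6 directions are required for tensor identifiability")
    if (nB0 < 1L)
        stop("'nB0' must be at least 1")
    if (bValue <= 0)
        stop("'bValue' must be positive")
    i <- seq_len(nDirections) - 1L
    # slight asymmetry in the polar spacing removes the exact quadratic-form
    # degeneracy of the symmetric spiral at small even n (rank must be 7)
    z <- 1 - 2 * (i + 0.5) / (nDirections + 0.5)
    phi <- i * pi * (3 - sqrt(5))          # golden angle
    r <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r * cos(phi), r * sin(phi), z)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    d <- rbind(matrix(0, nB0, 3L), dirs)
    colnames(d) <- c("x", "y", "z")
    new("DiffusionScheme", directions = d,
        bValues = c(rep(0, nB0), rep(bValue, nDirections)))
}

#' @rdname DiffusionScheme-class
#' @export
setMethod("directions", "DiffusionScheme", function(x) x@directions)

#' @rdname DiffusionScheme-class
#' @export
setMethod("bValues", "DiffusionScheme", function(x) x@bValues)

#' @rdname DiffusionScheme-class
#' @export
setMethod("nB0", "DiffusionScheme", function(x) sum(x@bValues == 0))

setMethod("show", "DiffusionScheme", function(object) {
    b <- object@bValues
    shells <- sort(unique(b[b > 0]))
    cat("DiffusionScheme with", length(b), "volumes\n")
    cat("  b = 0 volumes:", sum(b == 0), "\n")
    for (s in shells)
        cat(sprintf("  b = %g s/mm^2: %d directions\n", s, sum(b == s)))
})

#' @describeIn designMatrix rows per the quadratic-form expansion of
#'   `log S = log S0 - b g' D g`.
#' @export
setMethod("designMatrix", "DiffusionScheme", function(scheme) {
    g <- scheme@directions
    b <- scheme@bValues
    X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
               -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
               -2 * b * g[, 2] * g[, 3], 1)
    colnames(X) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz", "lnS0")
    if (qr(X)$rank < 7L)
        stop("scheme is not identifiable: design matrix rank < 7 ",
             "(need >= 6 non-collinear b > 0 directions)")
    X
})

#' Read and write FSL-dialect scheme files
#'
#' `readScheme()` reads `bvals` (one row of b-values) and `bvecs` (three rows
#' of direction components) plain-text files; `writeScheme()` writes them.
#' Directions of b > 0 rows are renormalized to unit length on read to absorb
#' formatting round-off.
#'
#' @param bvalsFile,bvecsFile paths to the two text files.
#' @param scheme a [DiffusionScheme-class].
#' @return `readScheme()` returns a [DiffusionScheme-class];
#'   `writeScheme()` returns the file paths invisibly.
#' @export
readScheme <- function(bvalsFile, bvecsFile) {
    b <- scan(bvalsFile, quiet = TRUE)
    v <- as.matrix(read.table(bvecsFile))
    if (nrow(v) != 3L)
        stop("'bvecs' must have exactly 3 rows")
    if (ncol(v) != length(b))
        stop("'bvals' and 'bvecs' disagree on the number of volumes")
    d <- t(v)
    dw <- b > 0
    nrm <- sqrt(rowSums(d[dw, , drop = FALSE]^2))
    if (any(nrm == 0))
        stop("b > 0 volume with zero direction vector")
    d[dw, ] <- d[dw, , drop = FALSE] / nrm
    dimnames(d) <- list(NULL, c("x", "y", "z"))
    new("DiffusionScheme", directions = d, bValues = b)
}

#' @rdname readScheme
#' @export
writeScheme <- function(scheme, bvalsFile, bvecsFile) {
    stopifnot(is(scheme, "DiffusionScheme"))
    writeLines(paste(format(scheme@bValues, trim = TRUE), collapse = " "),
        bvalsFile)
    v <- t(scheme@directions)
    writeLines(apply(v, 1L, function(r)
        paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvecsFile)
    invisible(c(bvalsFile, bvecsFile))
}
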