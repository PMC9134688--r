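## Vectorized eigenvalues of many symmetric 3x3 matrices (trigonometric
## closed form). `comp` is an n x 6 matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz);
## returns an n x 3 matrix of eigenvalues sorted descending per row.
symEigenvalues3 <- function(comp) {
    a11 <- comp[, 1]; a22 <- comp[, 2]; a33 <- comp[, 3]
    a12 <- comp[, 4]; a13 <- comp[, 5]; a23 <- comp[, 6]
    p1 <- a12^2 + a13^2 + a23^2
    q <- (a11 + a22 + a33) / 3
    p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
    p <- sqrt(p2 / 6)
    # B = (A - qI) / p; det(B)/2 drives the eigenvalue phase
    b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
    detB <- b11 * (b22 * b33 - a23^2) -
            a12 * (a12 * b33 - a23 * a13) +
            a13 * (a12 * a23 - b22 * a13)
    r <- ifelse(p > 0, detB / (2 * p^3), 0)
    r <- pmin(1, pmax(-1, r))
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    iso <- p1 == 0 & p2 == 0
    if (any(iso)) { e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso] }
    cbind(e1, e2, e3, deparse.level = 0)
}

## Floor non-positive signals at (smallest positive signal in the voxel) * 1e-3
## so that the log-linear model is defined; rows = voxels, cols = volumes.
clampSignals <- function(S) {
    bad <- S <= 0
    if (!any(bad)) return(S)
    for (i in which(rowSums(bad) > 0)) {
        pos <- S[i, S[i, ] > 0]
        if (!length(pos))
            stop("voxel with no positive signal cannot be fitted")
        S[i, S[i, ] <= 0] <- min(pos) * 1e-3
    }
    S
}

#' @describeIn fitTensor single-voxel fit returning the full eigensystem.
#' @export
setMethod("fitTensor", signature(signals = "numeric", scheme = "DiffusionScheme"),
    function(signals, scheme, ...) {
        X <- designMatrix(scheme)
        if (length(signals) != nrow(X))
            stop("signal length does not match the scheme")
        if (any(!is.finite(signals)))
            stop("non-finite signals in voxel")
        S <- clampSignals(matrix(signals, nrow = 1L))
        beta <- qr.coef(qr(X), log(as.vector(S)))
        D <- matrix(c(beta[1], beta[4], beta[5],
                      beta[4], beta[2], beta[6],
                      beta[5], beta[6], beta[3]), 3L, 3L)
        es <- eigen(D, symmetric = TRUE)
        pred <- exp(as.vector(X %*% beta))
        list(D = D, lnS0 = unname(beta[7]),
             eigenvalues = es$values, eigenvectors = es$vectors,
             residualRMS = sqrt(mean((as.vector(S) - pred)^2)))
    })

#' @describeIn fitTensor whole-volume fit; voxels with non-finite signals (or
#'   outside `mask`) are excluded and flagged `FALSE` in the returned mask.
#' @export
setMethod("fitTensor", signature(signals = "array", scheme = "DiffusionScheme"),
    function(signals, scheme, mask = NULL, ...) {
        dm <- dim(signals)
        if (length(dm) != 4L)
            stop("'signals' must be a 4-D array (x, y, z, volume)")
        X <- designMatrix(scheme)
        if (dm[4] != nrow(X))
            stop("4th dimension does not match the scheme")
        nvox <- prod(dm[1:3])
        S <- matrix(signals, nrow = nvox)          # voxels x volumes
        ok <- rowSums(!is.finite(S)) == 0
        if (!is.null(mask)) ok <- ok & as.vector(mask)
        beta <- matrix(NA_real_, nvox, 7L)
        resid <- rep(NA_real_, nvox)
        if (any(ok)) {
            Sok <- clampSignals(S[ok, , drop = FALSE])
            qrX <- qr(X)
            bet <- t(qr.coef(qrX, t(log(Sok))))    # voxels x 7
            beta[ok, ] <- bet
            pred <- exp(bet %*% t(X))
            resid[ok] <- sqrt(rowMeans((Sok - pred)^2))
        }
        ev <- matrix(NA_real_, nvox, 3L)
        if (any(ok)) ev[ok, ] <- symEigenvalues3(beta[ok, 1:6, drop = FALSE])
        list(tensor = array(beta[, 1:6], c(dm[1:3], 6L)),
             lnS0 = array(beta[, 7], dm[1:3]),
             eigenvalues = array(ev, c(dm[1:3], 3L)),
             residualRMS = array(resid, dm[1:3]),
             mask = array(ok, dm[1:3]))
    })

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((l_i - lbar)^2)) / sqrt(sum(l_i^2))` after
#' clamping negative eigenvalues to zero (noise can push small eigenvalues
#' below zero; clamping keeps FA in `[0, 1]` without touching the raw
#' diffusivities used for AD/RD/MD). All-zero eigenvalues give 0 by
#' convention; the result is clipped to `[0, 1]`.
#'
#' @param eigenvalues numeric vector of 3 eigenvalues, or an n x 3 matrix
#'   (one tensor per row).
#' @return FA value(s) in `[0, 1]`.
#' @examples
#' computeFA(c(1.7e-3, 0.3e-3, 0.3e-3))  # prolate tract-like tensor
#' computeFA(c(1, 1, 1))                 # isotropic: 0
#' @export
computeFA <- function(eigenvalues) {
    ev <- if (is.matrix(eigenvalues)) eigenvalues else
        matrix(eigenvalues, nrow = 1L)
    if (ncol(ev) != 3L) stop("expected 3 eigenvalues per tensor")
    if (any(!is.finite(ev))) stop("eigenvalues must be finite")
    ev <- pmax(ev, 0)
    mn <- rowMeans(ev)
    num <- (ev[, 1] - mn)^2 + (ev[, 2] - mn)^2 + (ev[, 3] - mn)^2
    den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
    fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
    fa <- pmin(1, pmax(0, fa))
    if (is.matrix(eigenvalues)) fa else fa[1]
}

#' Derive scalar maps from a fitted tensor volume
#'
#' AD is the largest eigenvalue, RD the mean of the two smaller eigenvalues,
#' MD their combination `(AD + 2 RD) / 3`, and FA per [computeFA()].
#'
#' @param tensorFit the list returned by the array method of [fitTensor()].
#' @param mask optional logical 3-D array further restricting the fit mask.
#' @return a [ScalarMapSet-class]; voxels outside the mask hold `NA`.
#' @export
computeScalarMaps <- function(tensorFit, mask = NULL) {
    ev <- tensorFit$eigenvalues
    dm <- dim(ev)[1:3]
    m <- tensorFit$mask
    if (!is.null(mask)) m <- m & mask
    if (!any(m)) stop("empty mask: no voxels to summarize")
    evm <- matrix(ev, ncol = 3L)
    idx <- as.vector(m)
    ad <- md <- rd <- fa <- rep(NA_real_, length(idx))
    ad[idx] <- evm[idx, 1]
    rd[idx] <- (evm[idx, 2] + evm[idx, 3]) / 2
    md[idx] <- (ad[idx] + 2 * rd[idx]) / 3
    fa[idx] <- computeFA(evm[idx, , drop = FALSE])
    new("ScalarMapSet", fa = array(fa, dm), md = array(md, dm),
        ad = array(ad, dm), rd = array(rd, dm), mask = array(m, dm))
}

#' @rdname ScalarMapSet-class
#' @export
setMethod("faMap", "ScalarMapSet", function(x) x@fa)
#' @rdname ScalarMapSet-class
#' @export
setMethod("mdMap", "ScalarMapSet", function(x) x@md)
#' @rdname ScalarMapSet-class
#' @export
setMethod("adMap", "ScalarMapSet", function(x) x@ad)
#' @rdname ScalarMapSet-class
#' @export
setMethod("rdMap", "ScalarMapSet", function(x) x@rd)
#' @rdname ScalarMapSet-class
#' @export
setMethod("mapMask", "ScalarMapSet", function(x) x@mask)

setMethod("show", "ScalarMapSet", function(object) {
    cat("ScalarMapSet", paste(dim(object@fa), collapse = " x "),
        "voxels,", sum(object@mask), "in mask\n")
    if (any(object@mask)) {
        fa <- object@fa[object@mask]
        cat(sprintf("  FA: median %.3f [%.3f, %.3f]\n",
            median(fa), min(fa), max(fa)))
        cat(sprintf("  MD: median %.3g mm^2/s\n",
            median(object@md[object@mask])))
    }
})

#' Write and read scalar maps as NIfTI-1 volumes
#'
#' One 3-D volume per metric, named `<prefix>_FA.nii.gz`, `_MD`, `_AD`, `_RD`
#' and `_mask`. A template image (e.g. the input DWI) may supply the affine
#' and header, which are carried through untouched.
#'
#' @param maps a [ScalarMapSet-class].
#' @param prefix output path prefix.
#' @param template optional NIfTI image or path providing header/affine.
#' @return `writeScalarMaps()` returns the written paths invisibly;
#'   `readScalarMaps()` returns a [ScalarMapSet-class].
#' @export
writeScalarMaps <- function(maps, prefix, template = NULL) {
    stopifnot(is(maps, "ScalarMapSet"))
    vols <- list(FA = maps@fa, MD = maps@md, AD = maps@ad, RD = maps@rd,
                 mask = maps@mask * 1)
    paths <- character(0)
    for (nm in names(vols)) {
        p <- paste0(prefix, "_", nm, ".nii.gz")
        img <- if (is.null(template)) RNifti::asNifti(vols[[nm]])
               else RNifti::asNifti(vols[[nm]], reference = template)
        RNifti::writeNifti(img, p)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' @rdname writeScalarMaps
#' @export
readScalarMaps <- function(prefix) {
    rd <- function(nm) {
        a <- as.array(RNifti::readNifti(paste0(prefix, "_", nm, ".nii.gz")))
        array(a, dim(a))
    }
    fa <- rd("FA")
    new("ScalarMapSet", fa = fa, md = rd("MD"), ad = rd("AD"), rd = rd("RD"),
        mask = array(rd("mask") > 0.5, dim(fa)))
}
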