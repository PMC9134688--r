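#' @rdname DiffusionScheme-class
#' @param object,x an object of the documented class
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname DiffusionScheme-class
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname DiffusionScheme-class
#' @export
setGeneric("nB0", function(x) standardGeneric("nB0"))

#' Design matrix of the log-linear tensor model
#'
#' Maps the parameter vector `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln S0)` to the
#' log-signal of each acquired volume. For direction `g = (gx, gy, gz)` at
#' b-value `b`, the row is
#' `(-b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz, 1)`.
#'
#' @param scheme a [DiffusionScheme-class] object.
#' @return numeric matrix with one row per volume and 7 columns.
#' @examples
#' X <- designMatrix(makeScheme(30, 970))
#' qr(X)$rank  # 7: all tensor components identifiable
#' @export
setGeneric("designMatrix", function(scheme) standardGeneric("designMatrix"))

#' Fit the diffusion tensor by log-linear least squares
#'
#' Ordinary least squares of log-signals on the tensor [designMatrix()], the
#' default linear regression model of standard DTI fitting tools. Signals at
#' or below zero are clamped to a small positive floor (the smallest positive
#' signal of the voxel times 1e-3) before taking logarithms. The method for a
#' numeric vector fits a single voxel; the method for a 4-D array fits every
#' voxel of a volume.
#'
#' @param signals numeric vector of per-volume signals for one voxel, or a
#'   4-D array `(x, y, z, volume)`.
#' @param scheme a [DiffusionScheme-class] matching the last dimension.
#' @param ... further arguments passed to methods (`mask` for the array
#'   method: logical 3-D array of voxels to fit).
#' @return For a vector: a list with `D` (symmetric 3x3 tensor, mm^2/s),
#'   `lnS0`, `eigenvalues` (descending), `eigenvectors` (columns matching the
#'   eigenvalues), and `residualRMS` (signal units). For an array: a list with
#'   `tensor` (`(x, y, z, 6)`, components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#'   `lnS0`, `eigenvalues` (`(x, y, z, 3)`, descending), `residualRMS` and
#'   `mask` (voxels with all-finite signals that were fitted).
#' @export
setGeneric("fitTensor", function(signals, scheme, ...) standardGeneric("fitTensor"))

#' @rdname ScalarMapSet-class
#' @export
setGeneric("faMap", function(x) standardGeneric("faMap"))

#' @rdname ScalarMapSet-class
#' @export
setGeneric("mdMap", function(x) standardGeneric("mdMap"))

#' @rdname ScalarMapSet-class
#' @export
setGeneric("adMap", function(x) standardGeneric("adMap"))

#' @rdname ScalarMapSet-class
#' @export
setGeneric("rdMap", function(x) standardGeneric("rdMap"))

#' @rdname ScalarMapSet-class
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))

#' @rdname FAHistogram-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname FAHistogram-class
#' @export
setGeneric("binHeights", function(x) standardGeneric("binHeights"))

#' @rdname BurrFit-class
#' @export
setGeneric("burrParams", function(x) standardGeneric("burrParams"))

#' @rdname BurrFit-class
#' @export
setGeneric("burrDescriptors", function(x) standardGeneric("burrDescriptors"))

#' @rdname PlateModel-class
#' @export
setGeneric("plateParams", function(x) standardGeneric("plateParams"))

#' @rdname PlateModel-class
#' @export
setGeneric("lloq", function(x) standardGeneric("lloq"))
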