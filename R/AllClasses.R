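#' @import methods
NULL

#' Diffusion acquisition scheme
#'
#' Gradient directions and b-values defining the forward signal model of a
#' diffusion-weighted acquisition. Rows with `b = 0` are non-diffusion-weighted
#' reference volumes; their direction entries are ignored.
#'
#' @slot directions numeric matrix, one row per acquired volume, three columns
#'   (x, y, z components). Rows with positive b-value must be unit vectors.
#' @slot bValues numeric vector of diffusion weightings in s/mm^2, one per row
#'   of `directions`.
#'
#' @seealso [makeScheme()], [designMatrix()], [readScheme()]
#' @export
setClass("DiffusionScheme",
    representation(directions = "matrix", bValues = "numeric"))

setValidity("DiffusionScheme", function(object) {
    d <- object@directions
    b <- object@bValues
    msg <- character()
    if (!is.numeric(d) || ncol(d) != 3L)
        msg <- c(msg, "'directions' must be a numeric matrix with 3 columns")
    else {
        if (nrow(d) != length(b))
            msg <- c(msg, "nrow(directions) must equal length(bValues)")
        if (any(!is.finite(d)) || any(!is.finite(b)) || any(b < 0))
            msg <- c(msg, "directions and b-values must be finite, b >= 0")
        dw <- which(b > 0)
        if (length(dw) < 6L)
            msg <- c(msg, "at least 6 diffusion-weighted (b > 0) volumes are required")
        if (sum(b == 0) < 1L)
            msg <- c(msg, "at least one b = 0 volume is required")
        if (length(dw) && nrow(d) == length(b)) {
            nrm <- sqrt(rowSums(d[dw, , drop = FALSE]^2))
            if (any(abs(nrm - 1) > 1e-8))
                msg <- c(msg, "b > 0 directions must have unit norm (tol 1e-8)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Two-group diffusion phantom specification
#'
#' Describes a rectangular voxel grid containing axis-aligned prolate "tract"
#' regions embedded in an isotropic background. Tract tensors are cylindrically
#' symmetric with a common axial diffusivity and a per-group radial
#' diffusivity, so a treatment effect on myelination is emulated as a radial
#' diffusivity contrast between groups.
#'
#' @slot gridShape integer vector of length 3, grid size in voxels.
#' @slot tracts list of tract regions; each element is a list with entries
#'   `label` (character), `voxels` (n x 3 integer matrix of 1-based voxel
#'   indices) and `direction` (unit 3-vector, principal diffusion direction).
#' @slot backgroundDiffusivity isotropic background diffusivity, mm^2/s.
#' @slot tractAxialDiffusivity axial (principal) tract diffusivity, mm^2/s.
#' @slot tractRadialDiffusivity named numeric, radial tract diffusivity per
#'   group, mm^2/s; each entry must not exceed the axial diffusivity.
#' @slot groups named integer, number of subjects per group.
#' @slot s0 non-diffusion-weighted signal amplitude (arbitrary units).
#' @slot snr b0 signal-to-noise ratio (s0 / Rician sigma); `Inf` for noiseless.
#' @slot seed integer seed controlling the noise realization.
#'
#' @seealso [phantomSpec()], [defaultPhantomSpec()], [simulateDWI()]
#' @export
setClass("PhantomSpec",
    representation(gridShape = "integer", tracts = "list",
        backgroundDiffusivity = "numeric", tractAxialDiffusivity = "numeric",
        tractRadialDiffusivity = "numeric", groups = "integer",
        s0 = "numeric", snr = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    g <- object@gridShape
    if (length(g) != 3L || any(g < 1L))
        msg <- c(msg, "'gridShape' must be 3 positive integers")
    if (length(object@backgroundDiffusivity) != 1L ||
        object@backgroundDiffusivity <= 0)
        msg <- c(msg, "'backgroundDiffusivity' must be a single positive value")
    if (length(object@tractAxialDiffusivity) != 1L ||
        object@tractAxialDiffusivity <= 0)
        msg <- c(msg, "'tractAxialDiffusivity' must be a single positive value")
    rd <- object@tractRadialDiffusivity
    if (is.null(names(rd)) || any(rd <= 0))
        msg <- c(msg, "'tractRadialDiffusivity' must be a named positive vector")
    if (any(rd > object@tractAxialDiffusivity))
        msg <- c(msg, "radial diffusivity must not exceed axial diffusivity")
    if (is.null(names(object@groups)) || any(object@groups < 1L))
        msg <- c(msg, "'groups' must be a named vector of positive counts")
    if (!setequal(names(rd), names(object@groups)))
        msg <- c(msg, "groups of 'tractRadialDiffusivity' must match 'groups'")
    if (length(object@snr) != 1L || object@snr <= 0)
        msg <- c(msg, "'snr' must be a single positive value (Inf allowed)")
    if (length(object@s0) != 1L || object@s0 <= 0)
        msg <- c(msg, "'s0' must be a single positive value")
    for (tr in object@tracts) {
        if (!all(c("label", "voxels", "direction") %in% names(tr))) {
            msg <- c(msg, "each tract needs 'label', 'voxels' and 'direction'")
            next
        }
        v <- tr$voxels
        if (!is.matrix(v) || ncol(v) != 3L ||
            any(v < 1L) || any(t(v) > g))
            msg <- c(msg, sprintf(
                "tract '%s' voxels must be an n x 3 index matrix inside the grid",
                tr$label))
        if (abs(sqrt(sum(tr$direction^2)) - 1) > 1e-8)
            msg <- c(msg, sprintf("tract '%s' direction must be unit norm",
                tr$label))
        # optional per-tract diffusivity overrides (axial scalar, radial
        # named per group), e.g. for weakly anisotropic parenchyma
        ax <- if (is.null(tr$axial)) object@tractAxialDiffusivity else tr$axial
        if (ax <= 0)
            msg <- c(msg, sprintf("tract '%s': axial override must be > 0",
                tr$label))
        if (!is.null(tr$radial)) {
            if (!setequal(names(tr$radial), names(object@groups)) ||
                any(tr$radial <= 0) || any(tr$radial > ax))
                msg <- c(msg, sprintf(
                    "tract '%s': radial override must name all groups, 0 < radial <= axial",
                    tr$label))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Per-group noiseless tensor and FA fields of a simulated phantom, plus the
#' subject-to-group assignment, for round-trip validation of the estimation
#' pipeline.
#'
#' @slot tensorFields named list (one per group) of 4-D arrays
#'   `(x, y, z, 6)` holding tensor components in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s).
#' @slot faFields named list (one per group) of 3-D FA arrays in `[0, 1]`.
#' @slot groupAssignment named character vector mapping subject id to group.
#'
#' @export
setClass("GroundTruth",
    representation(tensorFields = "list", faFields = "list",
        groupAssignment = "character"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!setequal(names(object@tensorFields), names(object@faFields)))
        msg <- c(msg, "tensorFields and faFields must cover the same groups")
    for (g in names(object@faFields)) {
        fa <- object@faFields[[g]]
        if (any(fa < -1e-12 | fa > 1 + 1e-12, na.rm = TRUE))
            msg <- c(msg, sprintf("FA field of group '%s' outside [0, 1]", g))
    }
    if (!all(object@groupAssignment %in% names(object@tensorFields)))
        msg <- c(msg, "groupAssignment refers to unknown groups")
    if (length(msg)) msg else TRUE
})

#' Diffusion scalar maps
#'
#' Voxelwise diffusion-tensor scalar maps: fractional anisotropy (FA), mean
#' diffusivity (MD), axial diffusivity (AD, the largest eigenvalue) and radial
#' diffusivity (RD, mean of the two smaller eigenvalues), with the validity
#' mask of the tensor fit.
#'
#' @slot fa 3-D array, unitless FA in `[0, 1]` where `mask` is `TRUE`.
#' @slot md,ad,rd 3-D arrays in mm^2/s; `md == (ad + 2 rd) / 3`.
#' @slot mask logical 3-D array flagging voxels with a valid tensor fit.
#'
#' @seealso [computeScalarMaps()], [faMap()], [writeScalarMaps()]
#' @export
setClass("ScalarMapSet",
    representation(fa = "array", md = "array", ad = "array", rd = "array",
        mask = "array"))

setValidity("ScalarMapSet", function(object) {
    msg <- character()
    dm <- dim(object@fa)
    for (s in c("md", "ad", "rd", "mask"))
        if (!identical(dim(slot(object, s)), dm))
            msg <- c(msg, sprintf("'%s' dimensions differ from 'fa'", s))
    if (!is.logical(object@mask))
        msg <- c(msg, "'mask' must be logical")
    else if (identical(dim(object@mask), dm)) {
        m <- object@mask
        fa <- object@fa[m]
        if (length(fa) && (any(fa < 0) || any(fa > 1)))
            msg <- c(msg, "FA must lie in [0, 1] inside the mask")
        resid <- object@md[m] - (object@ad[m] + 2 * object@rd[m]) / 3
        if (length(resid) && max(abs(resid)) > 1e-12 * max(1, max(abs(object@md[m]))))
            msg <- c(msg, "MD must equal (AD + 2 RD) / 3")
    }
    if (length(msg)) msg else TRUE
})

#' Normalized FA histogram
#'
#' Per-subject forebrain FA histogram with fixed 0.01-wide bins on `[0, 1]`
#' (100 bins, half-open on the left except the last bin which is closed at 1),
#' normalized so the heights sum to one.
#'
#' @slot binEdges numeric vector of 101 edges, 0 to 1 in steps of 0.01.
#' @slot heights numeric vector of 100 bin probabilities summing to one.
#' @slot nVoxels number of FA values contributing to the histogram.
#' @slot subjectId,group identifiers carried through to downstream tables.
#'
#' @seealso [buildHistogram()], [fitBurr()]
#' @export
setClass("FAHistogram",
    representation(binEdges = "numeric", heights = "numeric",
        nVoxels = "integer", subjectId = "character", group = "character"))

setValidity("FAHistogram", function(object) {
    msg <- character()
    e <- object@binEdges
    h <- object@heights
    if (length(e) != 101L || any(diff(e) <= 0))
        msg <- c(msg, "'binEdges' must be 101 strictly increasing values")
    if (length(h) != 100L || any(h < 0))
        msg <- c(msg, "'heights' must be 100 non-negative values")
    if (abs(sum(h) - 1) > 1e-10)
        msg <- c(msg, "heights must sum to 1 (tol 1e-10)")
    if (object@nVoxels < 1L)
        msg <- c(msg, "'nVoxels' must be positive")
    if (length(msg)) msg else TRUE
})

#' Burr type XII histogram fit
#'
#' Least-squares fit of the three-parameter Burr XII distribution,
#' `F(x) = 1 - (1 + (x/alpha)^c)^(-k)`, to a normalized FA histogram, together
#' with the mode, mean and median derived in closed form from the fitted
#' parameters. The mean exists only when `c * k > 1` and is `NA` otherwise.
#'
#' @slot c,k shape parameters, positive.
#' @slot alpha scale parameter, positive (FA units).
#' @slot mode,mean,median distribution descriptors in FA units (`mean` may be
#'   `NA` when undefined).
#' @slot sse value of the least-squares objective at the optimum.
#' @slot converged logical convergence flag of the optimizer.
#' @slot subjectId,group identifiers inherited from the fitted histogram.
#'
#' @seealso [fitBurr()], [burrMedian()], [compareGroups()]
#' @export
setClass("BurrFit",
    representation(c = "numeric", k = "numeric", alpha = "numeric",
        mode = "numeric", mean = "numeric", median = "numeric",
        sse = "numeric", converged = "logical",
        subjectId = "character", group = "character"))

setValidity("BurrFit", function(object) {
    msg <- character()
    if (object@converged) {
        if (object@c <= 0 || object@k <= 0 || object@alpha <= 0)
            msg <- c(msg, "converged fit requires c, k, alpha > 0")
        med <- object@alpha * (2^(1 / object@k) - 1)^(1 / object@c)
        if (abs(med - object@median) > 1e-8 * max(1, abs(med)))
            msg <- c(msg, "median inconsistent with (c, k, alpha) closed form")
        if (object@c * object@k <= 1 && is.finite(object@mean))
            msg <- c(msg, "mean must be NA when c * k <= 1")
    }
    if (length(msg)) msg else TRUE
})

#' ELISA standard-curve model
#'
#' Four-parameter logistic (4PL) standard curve fitted to blank-subtracted
#' signals of a purified-protein dilution series, with the lower limit of
#' quantification (LLOQ) determined by back-calculated standard recovery.
#'
#' @slot params named numeric of length 4: `lower` and `upper` asymptotes
#'   (signal units), `mid` (midpoint concentration, ng/mL) and `slope`
#'   (unitless Hill slope).
#' @slot standards data.frame with columns `nominal` (ng/mL), `signal`
#'   (blank-subtracted), `backcalc` (back-calculated ng/mL) and `recovery`
#'   (percent of nominal).
#' @slot blank blank-well signal subtracted from all signals.
#' @slot lloq lower limit of quantification, ng/mL (`NA` if indeterminate).
#' @slot residuals fit residuals in signal units.
#' @slot converged logical convergence flag.
#'
#' @seealso [fitStandardCurve()], [quantifySamples()]
#' @export
setClass("PlateModel",
    representation(params = "numeric", standards = "data.frame",
        blank = "numeric", lloq = "numeric", residuals = "numeric",
        converged = "logical"))

setValidity("PlateModel", function(object) {
    msg <- character()
    p <- object@params
    if (!all(c("lower", "upper", "mid", "slope") %in% names(p)))
        msg <- c(msg, "'params' must name lower, upper, mid, slope")
    else {
        if (p[["mid"]] <= 0)
            msg <- c(msg, "midpoint concentration must be positive")
        if (p[["slope"]] == 0)
            msg <- c(msg, "slope must be nonzero (monotone curve)")
        if (p[["upper"]] <= p[["lower"]])
            msg <- c(msg, "upper asymptote must exceed lower asymptote")
    }
    if (length(msg)) msg else TRUE
})
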