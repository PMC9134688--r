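#' Construct a phantom specification
#'
#' Thin validated constructor for [PhantomSpec-class]. `tractRegion()` builds
#' one axis-aligned rectangular tract from index ranges.
#'
#' @param gridShape integer vector of length 3.
#' @param tracts list of tract regions (see [tractRegion()]).
#' @param backgroundDiffusivity,tractAxialDiffusivity diffusivities, mm^2/s.
#' @param tractRadialDiffusivity named numeric, one radial diffusivity per
#'   group, mm^2/s.
#' @param groups named integer vector of subjects per group.
#' @param s0 b0 signal amplitude.
#' @param snr b0 signal-to-noise ratio (`Inf` = noiseless).
#' @param seed integer seed for the noise realization.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape, tracts, backgroundDiffusivity,
                        tractAxialDiffusivity, tractRadialDiffusivity,
                        groups, s0 = 1000, snr = Inf, seed = 1L) {
    new("PhantomSpec", gridShape = as.integer(gridShape), tracts = tracts,
        backgroundDiffusivity = backgroundDiffusivity,
        tractAxialDiffusivity = tractAxialDiffusivity,
        tractRadialDiffusivity = tractRadialDiffusivity,
        groups = structure(as.integer(groups), names = names(groups)),
        s0 = s0, snr = snr, seed = as.integer(seed))
}

#' @rdname phantomSpec
#' @param label region label (character).
#' @param xRange,yRange,zRange integer index ranges of the box.
#' @param direction principal diffusion direction (normalized internally).
#' @export
tractRegion <- function(label, xRange, yRange, zRange, direction) {
    v <- as.matrix(expand.grid(x = xRange, y = yRange, z = zRange))
    list(label = label, voxels = v,
         direction = direction / sqrt(sum(direction^2)))
}

## White-matter structures scored in the regional analysis: forceps minor,
## genu, body and splenium of corpus callosum, forceps major, external
## capsule, anterior commissure (anterior part), internal capsule, optic
## tract, cerebellar peduncle.
wmRegionNames <- function()
    c("fmi", "gcc", "bcc", "scc", "fmj", "ec", "aca", "ic", "opt", "cp")

#' Default two-group study phantom
#'
#' A 16 x 16 x 6 voxel grid emulating a neonatal forebrain slab: ten
#' 3 x 3 x 2 deep white-matter tract boxes labelled with the structures of
#' the regional analysis, embedded in weakly anisotropic parenchyma (the
#' immature cortex and subcortical grey of the developing brain carry
#' low but nonzero FA), surrounded by an isotropic fluid-like rim. Tracts
#' are prolate (axial 1.4e-3, vehicle radial 0.6e-3 mm^2/s, FA ~ 0.49);
#' parenchyma has axial 1.0e-3 and vehicle radial 0.8e-3 (FA ~ 0.13). The
#' treated group's radial diffusivity is reduced by `rdReduction` in the
#' tracts and by half that fraction in the parenchyma, emulating brain-wide
#' accelerated myelination that is strongest in deep white matter; this
#' shifts the whole forebrain FA distribution upward, as well as every
#' regional tract FA. The forebrain ROI of the histogram analysis is the
#' union of tracts and parenchyma (region label > 0).
#'
#' @param groups named integer, subjects per group; the second group is the
#'   treated one.
#' @param rdReduction fractional radial-diffusivity reduction in the treated
#'   group (0 gives a null study).
#' @param snr b0 signal-to-noise ratio.
#' @param seed integer noise seed.
#' @return a [PhantomSpec-class]; region labels 1..10 are the white-matter
#'   structures, 11 the parenchyma.
#' @export
defaultPhantomSpec <- function(groups = c(vehicle = 6L, T4 = 6L),
                               rdReduction = 0.25, snr = 25, seed = 1L) {
    rdVeh <- 0.6e-3
    rd <- c(rdVeh, rdVeh * (1 - rdReduction))
    names(rd) <- names(groups)
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    nms <- wmRegionNames()
    xs <- c(1, 4, 7, 10, 13)
    tracts <- vector("list", 11L)
    inTract <- array(FALSE, c(16L, 16L, 6L))
    for (i in seq_len(10L)) {
        row <- (i - 1L) %/% 5L      # 0 = anterior row, 1 = posterior row
        col <- (i - 1L) %% 5L
        tracts[[i]] <- tractRegion(nms[i],
            xRange = xs[col + 1L] + 0:2,
            yRange = (if (row == 0L) 3L else 10L) + 0:2,
            zRange = 3:4,
            direction = dirs[[(i - 1L) %% 3L + 1L]])
        inTract[tracts[[i]]$voxels] <- TRUE
    }
    slab <- array(FALSE, c(16L, 16L, 6L)); slab[, , 2:5] <- TRUE
    par <- which(slab & !inTract, arr.ind = TRUE)
    dimnames(par) <- NULL
    rdPar <- 0.8e-3 * c(1, 1 - rdReduction / 2)
    names(rdPar) <- names(groups)
    tracts[[11L]] <- list(label = "parenchyma", voxels = par,
        direction = c(0, 0, 1), axial = 1.0e-3, radial = rdPar)
    phantomSpec(gridShape = c(16L, 16L, 6L), tracts = tracts,
        backgroundDiffusivity = 2.0e-3,
        tractAxialDiffusivity = 1.4e-3,
        tractRadialDiffusivity = rd,
        groups = groups, s0 = 1000, snr = snr, seed = seed)
}

## Tensor components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) of a cylindrically
## symmetric tensor with the given axis and axial/radial diffusivities.
prolateTensor <- function(direction, axial, radial) {
    g <- direction
    D <- radial * diag(3) + (axial - radial) * tcrossprod(g)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

phantomFields <- function(spec) {
    nvox <- prod(spec@gridShape)
    lab <- integer(nvox)
    dim(lab) <- spec@gridShape
    regionNames <- vapply(spec@tracts, `[[`, "", "label")
    tensors <- list()
    for (g in names(spec@groups)) {
        comp <- matrix(0, nvox, 6L)
        comp[, 1:3] <- spec@backgroundDiffusivity
        for (i in seq_along(spec@tracts)) {
            tr <- spec@tracts[[i]]
            idx <- tr$voxels[, 1] +
                (tr$voxels[, 2] - 1L) * spec@gridShape[1] +
                (tr$voxels[, 3] - 1L) * prod(spec@gridShape[1:2])
            ax <- if (is.null(tr$axial)) spec@tractAxialDiffusivity
                  else tr$axial
            rad <- if (is.null(tr$radial)) spec@tractRadialDiffusivity[[g]]
                   else tr$radial[[g]]
            comp[idx, ] <- matrix(prolateTensor(tr$direction, ax, rad),
                length(idx), 6L, byrow = TRUE)
            lab[idx] <- i
        }
        tensors[[g]] <- comp
    }
    list(tensors = tensors, labels = lab, regionNames = regionNames)
}

#' Simulate a two-group diffusion-weighted study
#'
#' Generates per-subject DWI volumes from the noiseless single-tensor forward
#' model `S_i = S0 exp(-b_i g_i' D g_i)` with Rician noise on the magnitude
#' signal: `S_noisy = sqrt((S + n1)^2 + n2^2)`, `n1, n2 ~ N(0, sigma)`,
#' `sigma = S0 / snr` (infinite SNR returns the exact forward model). The
#' noise realization is reproducible from the spec's seed.
#'
#' @param spec a [PhantomSpec-class].
#' @param scheme a [DiffusionScheme-class].
#' @return list with `subjects` (named list of 4-D signal arrays), `truth`
#'   (a [GroundTruth-class]), `labels` (integer 3-D region-label array) and
#'   `regionNames` (labels 1..10 in order).
#' @export
simulateDWI <- function(spec, scheme) {
    stopifnot(is(spec, "PhantomSpec"), is(scheme, "DiffusionScheme"))
    fl <- phantomFields(spec)
    X <- designMatrix(scheme)
    dm <- spec@gridShape
    nvol <- length(scheme@bValues)
    sigma <- spec@s0 / spec@snr
    set.seed(spec@seed)
    subjects <- list()
    assignment <- character(0)
    tensorFields <- faFields <- list()
    for (g in names(spec@groups)) {
        comp <- fl$tensors[[g]]
        S <- exp(comp %*% t(X[, 1:6]) + log(spec@s0))   # nvox x nvol
        ev <- symEigenvalues3(comp)
        tensorFields[[g]] <- array(comp, c(dm, 6L))
        faFields[[g]] <- array(computeFA(ev), dm)
        for (i in seq_len(spec@groups[[g]])) {
            id <- sprintf("%s_%02d", g, i)
            vol <- if (is.finite(sigma) && sigma > 0)
                sqrt((S + rnorm(length(S), 0, sigma))^2 +
                     rnorm(length(S), 0, sigma)^2)
            else S
            subjects[[id]] <- array(vol, c(dm, nvol))
            assignment[id] <- g
        }
    }
    list(subjects = subjects,
         truth = new("GroundTruth", tensorFields = tensorFields,
             faFields = faFields, groupAssignment = assignment),
         labels = fl$labels, regionNames = fl$regionNames)
}

#' Simulate the developmental MBP curve
#'
#' Mean brain MBP concentration follows a logistic rise with postnatal age;
#' treatment shifts the logistic midpoint `effect` days earlier, emulating
#' accelerated myelination. Observations get multiplicative Gaussian noise
#' with coefficient of variation `noiseCv` and are floored at zero.
#'
#' @param ages integer postnatal days, within 3..11.
#' @param groups character vector of two group names; `treatedGroup` (default
#'   the second) receives the midpoint shift.
#' @param effect leftward midpoint shift in days (>= 0).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param nPerCell subjects per group x age cell.
#' @param seed integer seed.
#' @param treatedGroup which group is treated.
#' @param plateau,baseline asymptotic and initial MBP levels, ng/mL.
#' @param midpointAge vehicle-group logistic midpoint, postnatal day.
#' @param scaleDays logistic time scale, days.
#' @return data.frame with columns `subject`, `group`, `PND`, `MBP` (ng/mL).
#' @export
simulateMBPDevelopment <- function(ages = 3:11,
                                   groups = c("vehicle", "T4"),
                                   effect = 2, noiseCv = 0.15,
                                   nPerCell = 6L, seed = 1L,
                                   treatedGroup = groups[2],
                                   plateau = 50, baseline = 0.5,
                                   midpointAge = 10, scaleDays = 1.5) {
    if (any(ages < 3 | ages > 11))
        stop("'ages' must lie within postnatal days 3..11")
    if (effect < 0) stop("'effect' must be non-negative")
    if (noiseCv < 0) stop("'noiseCv' must be non-negative")
    set.seed(seed)
    grid <- expand.grid(i = seq_len(nPerCell), PND = ages, group = groups,
        stringsAsFactors = FALSE)
    shift <- ifelse(grid$group == treatedGroup, effect, 0)
    mu <- baseline + plateau /
        (1 + exp(-(grid$PND - (midpointAge - shift)) / scaleDays))
    mbp <- pmax(0, mu * (1 + rnorm(nrow(grid), 0, noiseCv)))
    data.frame(subject = sprintf("%s_P%02d_%d", grid$group, grid$PND, grid$i),
        group = grid$group, PND = grid$PND, MBP = mbp,
        stringsAsFactors = FALSE)
}

#' @rdname simulateMBPDevelopment
#' @details `mbpMeanCurve()` returns the noiseless mean curve used by the
#'   generator, for one group.
#' @param age ages at which to evaluate the mean curve.
#' @param treated logical; apply the midpoint shift.
#' @export
mbpMeanCurve <- function(age, effect = 2, treated = FALSE, plateau = 50,
                         baseline = 0.5, midpointAge = 10, scaleDays = 1.5) {
    shift <- ifelse(treated, effect, 0)
    baseline + plateau / (1 + exp(-(age - (midpointAge - shift)) / scaleDays))
}

#' Simulate an ELISA plate
#'
#' Standards form a `dilutionFactor`-fold serial dilution from `standardTop`
#' (`nSerial` levels) plus a blank; signals come from the four-parameter
#' logistic `curveParams` with multiplicative Gaussian noise. Sample
#' concentrations are in-well (already diluted) values; quantification
#' multiplies by the recorded dilution factor to recover neat concentrations.
#'
#' @param standardTop top standard concentration, ng/mL.
#' @param nSerial number of serial-dilution levels (>= 5).
#' @param dilutionFactor fold-dilution between consecutive standards (> 1).
#' @param curveParams named numeric (`lower`, `upper`, `mid`, `slope`).
#' @param noiseCv coefficient of variation of the signal noise.
#' @param samples optional data.frame with columns `id`, `conc` (in-well
#'   ng/mL) and `dilution` (fold).
#' @param seed integer seed.
#' @return data.frame of plate records: `well`, `type`
#'   (standard/blank/sample), `id`, `nominal` (ng/mL), `dilution`, `signal`.
#' @export
simulatePlate <- function(standardTop = 100, nSerial = 7L,
                          dilutionFactor = 2,
                          curveParams = c(lower = 0.05, upper = 2,
                                          mid = 15, slope = 1.2),
                          noiseCv = 0, samples = NULL, seed = 1L) {
    if (dilutionFactor <= 1) stop("'dilutionFactor' must exceed 1")
    if (curveParams[["slope"]] == 0) stop("curve slope must be nonzero")
    if (noiseCv < 0) stop("'noiseCv' must be non-negative")
    set.seed(seed)
    nominal <- standardTop / dilutionFactor^(seq_len(nSerial) - 1L)
    rec <- data.frame(
        well = c(sprintf("STD%d", seq_len(nSerial)), "BLK",
                 if (!is.null(samples)) sprintf("S%d", seq_len(nrow(samples)))),
        type = c(rep("standard", nSerial), "blank",
                 rep("sample", if (is.null(samples)) 0L else nrow(samples))),
        id = c(sprintf("std_%g", nominal), "blank",
               if (!is.null(samples)) as.character(samples$id)),
        nominal = c(nominal, 0,
                    if (!is.null(samples)) samples$conc),
        dilution = c(rep(1, nSerial + 1L),
                     if (!is.null(samples)) samples$dilution),
        stringsAsFactors = FALSE)
    mu <- fourPL(rec$nominal, curveParams)
    rec$signal <- mu * (1 + rnorm(nrow(rec), 0, noiseCv))
    rec
}

#' Simulate a stained hemisphere section
#'
#' Builds an elliptical hemisphere mask inside the image frame and draws
#' exactly `round(positiveFraction * mask area)` randomly placed mask pixels
#' at the foreground intensity, the rest at background, plus additive
#' Gaussian noise.
#'
#' @param shape image size (rows, cols).
#' @param positiveFraction target positive area fraction in `[0, 1]`.
#' @param fgIntensity,bgIntensity stained and unstained intensities
#'   (foreground must exceed background).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `image` (numeric matrix), `mask` (logical matrix) and
#'   `trueFraction` (the realized exact positive fraction).
#' @export
simulateIHCImage <- function(shape = c(80L, 100L), positiveFraction = 0.25,
                             fgIntensity = 200, bgIntensity = 50,
                             noiseSd = 0, seed = 1L) {
    if (positiveFraction < 0 || positiveFraction > 1)
        stop("'positiveFraction' must lie in [0, 1]")
    if (fgIntensity <= bgIntensity)
        stop("'fgIntensity' must exceed 'bgIntensity'")
    if (noiseSd < 0) stop("'noiseSd' must be non-negative")
    set.seed(seed)
    r <- row(matrix(0, shape[1], shape[2]))
    cc <- col(matrix(0, shape[1], shape[2]))
    mask <- ((r - (shape[1] + 1) / 2) / (0.45 * shape[1]))^2 +
            ((cc - (shape[2] + 1) / 2) / (0.45 * shape[2]))^2 <= 1
    area <- sum(mask)
    nPos <- round(positiveFraction * area)
    img <- matrix(bgIntensity, shape[1], shape[2])
    if (nPos > 0)
        img[sample(which(mask), nPos)] <- fgIntensity
    if (noiseSd > 0)
        img <- img + matrix(rnorm(length(img), 0, noiseSd),
                            shape[1], shape[2])
    list(image = img, mask = mask, trueFraction = nPos / area)
}

#' Simulate tooth-eruption counts
#'
#' Bernoulli eruption outcomes per pup at the scoring day, summarized as the
#' 2 x 2 table (group x erupted/not) handed to Fisher's exact test.
#'
#' @param nPerGroup named integer, pups per group.
#' @param pEruption named numeric in `[0, 1]`, eruption probability per
#'   group (same names).
#' @param seed integer seed.
#' @return 2 x 2 integer matrix; rows = groups, columns `erupted`,
#'   `notErupted`.
#' @export
simulateTeeth <- function(nPerGroup = c(T4 = 11L, vehicle = 11L),
                          pEruption = c(T4 = 9 / 11, vehicle = 1 / 11),
                          seed = 1L) {
    if (any(pEruption < 0 | pEruption > 1))
        stop("eruption probabilities must lie in [0, 1]")
    if (!setequal(names(nPerGroup), names(pEruption)))
        stop("'nPerGroup' and 'pEruption' must name the same groups")
    set.seed(seed)
    groups <- names(nPerGroup)
    counts <- vapply(groups, function(g)
        sum(runif(nPerGroup[[g]]) < pEruption[[g]]), 0L)
    tab <- cbind(erupted = counts, notErupted = unname(nPerGroup) - counts)
    rownames(tab) <- groups
    tab
}
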