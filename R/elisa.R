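#' Four-parameter logistic curve
#'
#' `fourPL()` evaluates the immunoassay-standard 4PL response
#' `f(x) = upper + (lower - upper) / (1 + (x / mid)^slope)` (increasing in
#' concentration for `slope > 0`; `f(0) = lower`, `f(mid)` is halfway between
#' the asymptotes). `fourPLInverse()` back-calculates concentration from
#' signal; signals outside the open asymptote interval return `NA`.
#'
#' @param x concentrations (>= 0), ng/mL.
#' @param y signals.
#' @param params named numeric: `lower`, `upper`, `mid`, `slope`.
#' @return signal values, or back-calculated concentrations.
#' @export
fourPL <- function(x, params) {
    p <- params
    p[["upper"]] + (p[["lower"]] - p[["upper"]]) /
        (1 + (x / p[["mid"]])^p[["slope"]])
}

#' @rdname fourPL
#' @export
fourPLInverse <- function(y, params) {
    p <- params
    out <- rep(NA_real_, length(y))
    inRange <- y > p[["lower"]] & y < p[["upper"]]
    ratio <- (p[["upper"]] - y[inRange]) / (y[inRange] - p[["lower"]])
    out[inRange] <- p[["mid"]] * ratio^(-1 / p[["slope"]])
    # exact boundary: signal at zero concentration
    out[y == p[["lower"]]] <- 0
    out
}

#' Fit an ELISA standard curve
#'
#' Fits the four-parameter logistic to blank-subtracted standard signals by
#' least squares (Levenberg-Marquardt) and derives the lower limit of
#' quantification (LLOQ) as the lowest nonzero standard whose back-calculated
#' concentration recovers its nominal value within the assay acceptance range
#' of 70-120%.
#'
#' @param standards data.frame with columns `nominal` (ng/mL, >= 5 distinct
#'   nonzero levels) and `signal`.
#' @param blank blank-well signal subtracted from all standard signals
#'   (default 0 for already-subtracted data).
#' @param monotoneTol maximum tolerated Spearman departure from monotonicity
#'   (the fit is rejected when the rank correlation between concentration and
#'   signal falls below this value).
#' @return a [PlateModel-class].
#' @export
fitStandardCurve <- function(standards, blank = 0, monotoneTol = 0.8) {
    stopifnot(all(c("nominal", "signal") %in% names(standards)))
    st <- standards[standards$nominal > 0, , drop = FALSE]
    if (length(unique(st$nominal)) < 5L)
        stop("at least 5 distinct nonzero standards are required")
    sig <- st$signal - blank
    rho <- suppressWarnings(cor(st$nominal, sig, method = "spearman"))
    if (!is.finite(rho) || rho < monotoneTol)
        stop("standard signals are not monotone in concentration; fit rejected")
    start <- c(lower = max(min(sig) * 0.5, 0), upper = max(sig) * 1.05,
               mid = exp(mean(log(st$nominal))), slope = 1)
    # analytic Jacobian: the numerical one floors convergence around 1e-8
    jac <- function(p) {
        names(p) <- names(start)
        z <- (st$nominal / p[["mid"]])^p[["slope"]]
        den <- 1 + z
        cbind(1 / den, 1 - 1 / den,
            (p[["lower"]] - p[["upper"]]) * z * p[["slope"]] /
                p[["mid"]] / den^2,
            -(p[["lower"]] - p[["upper"]]) * z *
                log(st$nominal / p[["mid"]]) / den^2)
    }
    fit <- minpack.lm::nls.lm(par = start,
        lower = c(-Inf, -Inf, 1e-12, 1e-3), upper = c(Inf, Inf, Inf, 100),
        fn = function(p) {
            names(p) <- names(start)
            fourPL(st$nominal, p) - sig
        },
        jac = jac,
        control = minpack.lm::nls.lm.control(
            ftol = 1e-15, ptol = 1e-15, maxiter = 500L))
    p <- fit$par
    names(p) <- names(start)
    back <- fourPLInverse(sig, p)
    recov <- back / st$nominal * 100
    passes <- is.finite(recov) & recov >= 70 & recov <= 120
    lloqVal <- if (any(passes)) min(st$nominal[passes]) else NA_real_
    new("PlateModel", params = p,
        standards = data.frame(nominal = st$nominal, signal = sig,
            backcalc = back, recovery = recov),
        blank = blank, lloq = lloqVal,
        residuals = fourPL(st$nominal, p) - sig,
        converged = fit$info %in% 1:4)
}

#' @rdname PlateModel-class
#' @export
setMethod("plateParams", "PlateModel", function(x) x@params)

#' @rdname PlateModel-class
#' @export
setMethod("lloq", "PlateModel", function(x) x@lloq)

setMethod("show", "PlateModel", function(object) {
    p <- object@params
    cat("PlateModel (4PL standard curve)\n")
    cat(sprintf("  asymptotes %.4g .. %.4g, midpoint %.4g ng/mL, slope %.3g\n",
        p[["lower"]], p[["upper"]], p[["mid"]], p[["slope"]]))
    cat(sprintf("  %d standards, LLOQ %s ng/mL, %s\n",
        nrow(object@standards),
        ifelse(is.na(object@lloq), "indeterminate",
               format(object@lloq, digits = 5)),
        ifelse(object@converged, "converged", "NOT converged")))
})

#' Back-quantify samples against a standard curve
#'
#' Inverts the fitted 4PL for each sample signal (after blank subtraction
#' with the model's blank) and scales by the dilution factor to a neat
#' concentration. Signals outside the invertible asymptote range, or
#' back-calculating below the LLOQ, are flagged rather than extrapolated.
#'
#' @param samples data.frame with columns `id`, `signal` and `dilution`
#'   (fold-dilution applied to the neat sample, >= 1).
#' @param model a fitted, converged [PlateModel-class].
#' @return data.frame with columns `id`, `signal`, `diluted` (back-calculated
#'   ng/mL at the measured dilution), `dilution`, `neat` (ng/mL),
#'   `belowLLOQ`, `saturated` and `inRange`.
#' @export
quantifySamples <- function(samples, model) {
    stopifnot(is(model, "PlateModel"))
    if (!model@converged) stop("standard-curve fit did not converge")
    stopifnot(all(c("id", "signal", "dilution") %in% names(samples)))
    if (any(samples$dilution < 1)) stop("dilution factors must be >= 1")
    sig <- samples$signal - model@blank
    p <- model@params
    diluted <- fourPLInverse(sig, p)
    saturated <- sig >= p[["upper"]]
    belowLLOQ <- !saturated &
        (!is.finite(diluted) | is.na(model@lloq) | diluted < model@lloq)
    neat <- diluted * samples$dilution
    data.frame(id = samples$id, signal = samples$signal, diluted = diluted,
        dilution = samples$dilution, neat = neat,
        belowLLOQ = belowLLOQ, saturated = saturated,
        inRange = !belowLLOQ & !saturated & is.finite(diluted))
}

#' Spike-and-recovery
#'
#' Percent of a known spiked amount recovered by the assay:
#' `(spiked - base) / nominal * 100`, with a pass flag against the 70-120%
#' acceptance range. Negative recoveries are reported as-is and fail.
#'
#' @param baseMeasured measured concentration of the unspiked sample.
#' @param spikedMeasured measured concentration after spiking.
#' @param spikeNominal known spiked amount (> 0), same units.
#' @return list with `recovery` (percent) and `pass`.
#' @export
spikeRecovery <- function(baseMeasured, spikedMeasured, spikeNominal) {
    if (any(spikeNominal <= 0)) stop("'spikeNominal' must be positive")
    rec <- (spikedMeasured - baseMeasured) / spikeNominal * 100
    list(recovery = rec, pass = rec >= 70 & rec <= 120)
}

#' Dilution linearity
#'
#' For serial dilutions of one sample, each step's neat-concentration
#' estimate as a percent of the least-diluted (reference) estimate, with
#' pass flags against the 70-120% acceptance range.
#'
#' @param series data.frame with columns `dilution` (fold) and `neat`
#'   (back-calculated neat concentration).
#' @return data.frame with `dilution`, `neat`, `percent`, `pass`; the
#'   reference row has `percent = 100`.
#' @export
dilutionLinearity <- function(series) {
    stopifnot(all(c("dilution", "neat") %in% names(series)))
    if (nrow(series) < 2L)
        stop("at least 2 dilutions of one sample are required")
    ref <- series$neat[which.min(series$dilution)]
    pct <- series$neat / ref * 100
    data.frame(dilution = series$dilution, neat = series$neat,
        percent = pct, pass = pct >= 70 & pct <= 120)
}
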