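#' The Burr type XII distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter Burr XII distribution with shape parameters `c`
#' and `k` and scale `alpha`:
#' `F(x) = 1 - (1 + (x / alpha)^c)^(-k)` for `x >= 0`.
#'
#' Closed-form descriptors: the median is
#' `alpha * (2^(1/k) - 1)^(1/c)`; the mode is
#' `alpha * ((c - 1) / (k c + 1))^(1/c)` for `c > 1` and 0 otherwise; the
#' mean `alpha * k * B(k - 1/c, 1 + 1/c)` exists only when `c k > 1` and is
#' returned as `NA` otherwise.
#'
#' @param x,q quantiles (`>= 0`).
#' @param p probabilities in `(0, 1)`.
#' @param n number of random draws.
#' @param c,k positive shape parameters.
#' @param alpha positive scale parameter.
#' @return numeric vector of densities, probabilities, quantiles, draws or
#'   descriptor values.
#' @examples
#' pburr(0.3, c = 4, k = 1, alpha = 0.3)   # 0.5: x = alpha, k = 1
#' burrMedian(4, 2, 0.3)
#' @name burr
NULL

checkBurrParams <- function(c, k, alpha) {
    if (any(!is.finite(c)) || any(!is.finite(k)) || any(!is.finite(alpha)) ||
        any(c <= 0) || any(k <= 0) || any(alpha <= 0))
        stop("Burr parameters must be finite and positive")
}

#' @rdname burr
#' @export
dburr <- function(x, c, k, alpha) {
    checkBurrParams(c, k, alpha)
    if (any(x < 0)) stop("'x' must be non-negative")
    z <- (x / alpha)^c
    (c * k / alpha) * (x / alpha)^(c - 1) * (1 + z)^(-k - 1)
}

#' @rdname burr
#' @export
pburr <- function(q, c, k, alpha) {
    checkBurrParams(c, k, alpha)
    if (any(q < 0)) stop("'q' must be non-negative")
    1 - (1 + (q / alpha)^c)^(-k)
}

#' @rdname burr
#' @export
qburr <- function(p, c, k, alpha) {
    checkBurrParams(c, k, alpha)
    if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)")
    alpha * ((1 - p)^(-1 / k) - 1)^(1 / c)
}

#' @rdname burr
#' @export
rburr <- function(n, c, k, alpha) {
    checkBurrParams(c, k, alpha)
    qburr(runif(n), c, k, alpha)
}

#' @rdname burr
#' @export
burrMedian <- function(c, k, alpha) {
    checkBurrParams(c, k, alpha)
    alpha * (2^(1 / k) - 1)^(1 / c)
}

#' @rdname burr
#' @export
burrMode <- function(c, k, alpha) {
    checkBurrParams(c, k, alpha)
    ifelse(c > 1, alpha * ((c - 1) / (k * c + 1))^(1 / c), 0)
}

#' @rdname burr
#' @export
burrMean <- function(c, k, alpha) {
    checkBurrParams(c, k, alpha)
    ifelse(c * k > 1, alpha * k * beta(k - 1 / c, 1 + 1 / c), NA_real_)
}
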