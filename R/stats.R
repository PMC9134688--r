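#' Regional means of diffusion metrics
#'
#' Averages each scalar map over every labelled region of a label mask.
#' Bilateral structures carry the same label in both hemispheres, so left and
#' right voxels are pooled before averaging.
#'
#' @param maps a [ScalarMapSet-class].
#' @param labelArray integer 3-D array; 0 = unlabelled, positive integers =
#'   regions.
#' @param regionNames optional character vector naming labels 1, 2, ...; also
#'   defines the labels that must be present (a named label with zero voxels
#'   under the fit mask is an error).
#' @return data.frame with columns `region`, `metric` (FA/MD/AD/RD) and
#'   `value`.
#' @export
regionalMeans <- function(maps, labelArray, regionNames = NULL) {
    stopifnot(is(maps, "ScalarMapSet"))
    if (!identical(dim(labelArray), dim(maps@fa)))
        stop("label mask dimensions differ from the maps")
    lab <- as.vector(labelArray)
    m <- as.vector(maps@mask)
    labels <- sort(unique(lab[lab > 0]))
    if (!is.null(regionNames)) {
        expect <- seq_along(regionNames)
        missing <- setdiff(expect, unique(lab[lab > 0 & m]))
        if (length(missing))
            stop("no voxels for region(s): ",
                 paste(regionNames[missing], collapse = ", "))
        labels <- expect
    }
    metrics <- list(FA = maps@fa, MD = maps@md, AD = maps@ad, RD = maps@rd)
    out <- do.call(rbind, lapply(labels, function(l) {
        sel <- lab == l & m
        if (!any(sel))
            stop("no voxels for label ", l)
        nm <- if (is.null(regionNames)) as.character(l) else regionNames[l]
        data.frame(region = nm,
            metric = names(metrics),
            value = vapply(metrics, function(a) mean(as.vector(a)[sel]), 0),
            stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

twoSampleT <- function(a, b, pooled) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (var(a) == 0 && var(b) == 0) {
        # degenerate: no within-group variability; equal means give the
        # trivially null comparison, unequal means an infinite statistic
        eq <- mean(a) == mean(b)
        return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
            df = length(a) + length(b) - 2,
            p.value = if (eq) 1 else 0, degenerate = TRUE))
    }
    tt <- t.test(a, b, var.equal = pooled)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, degenerate = FALSE)
}

#' Two-sample t-tests
#'
#' `studentT()` is the classical pooled-variance test; `welchT()` the
#' unequal-variance test with Welch-Satterthwaite degrees of freedom. Both
#' are two-sided. When both groups have zero variance the comparison is
#' degenerate: equal means return `t = 0, p = 1`, flagged `degenerate`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p.value`, `degenerate`.
#' @export
studentT <- function(a, b) twoSampleT(a, b, pooled = TRUE)

#' @rdname studentT
#' @export
welchT <- function(a, b) twoSampleT(a, b, pooled = FALSE)

bkyRejectAt <- function(p, q) {
    m <- length(p)
    qp <- q / (1 + q)
    bh <- function(pv, level) {
        o <- order(pv)
        thr <- level * seq_len(m) / m
        k <- which(pv[o] <= thr)
        rej <- logical(m)
        if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
        rej
    }
    r1 <- sum(bh(p, qp))
    if (r1 == 0L) return(logical(m))
    if (r1 == m) return(rep(TRUE, m))
    bh(p, qp * m / (m - r1))
}

#' Two-stage adaptive FDR control (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage 1 applies
#' Benjamini-Hochberg at level `q' = q / (1 + q)` to estimate the number of
#' true nulls; with `r1` stage-1 rejections out of `m` tests, stage 2 applies
#' Benjamini-Hochberg at `q' * m / (m - r1)` (rejecting none if `r1 = 0`, all
#' if `r1 = m`). The reported q-value of each test is the smallest nominal
#' `q` at which that test would be rejected, found by bisection; adaptive
#' procedures can yield q-values below the raw p-value.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate in `(0, 1)` (study default 0.1).
#' @param withQValues set `FALSE` to skip the bisection for q-values when
#'   only the discovery flags are needed (e.g. in simulations).
#' @return list with `qValues` (`NULL` if skipped) and logical `discovery`
#'   flags at level `q`.
#' @examples
#' bkyFdr(c(0.001, 0.012, 0.2, 0.5, 0.8), q = 0.1)
#' @export
bkyFdr <- function(pValues, q = 0.1, withQValues = TRUE) {
    if (!length(pValues)) stop("empty p-value vector")
    if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
        stop("p-values must lie in [0, 1]")
    if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
    m <- length(pValues)
    if (!withQValues)
        return(list(qValues = NULL, discovery = bkyRejectAt(pValues, q)))
    qv <- vapply(seq_len(m), function(i) {
        if (!bkyRejectAt(pValues, 1 - 1e-12)[i]) return(1)
        lo <- 1e-12; hi <- 1 - 1e-12
        for (it in 1:60) {
            mid <- (lo + hi) / 2
            if (bkyRejectAt(pValues, mid)[i]) hi <- mid else lo <- mid
        }
        hi
    }, 0)
    list(qValues = qv, discovery = bkyRejectAt(pValues, q))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table (the convention
#' of `stats::fisher.test` and mainstream statistics packages).
#'
#' @param table 2 x 2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return two-sided p-value.
#' @examples
#' # tooth eruption at PND9: 9/11 treated vs 1/11 vehicle pups
#' fisherExact2x2(matrix(c(9, 2, 1, 10), 2, 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
    tab <- as.matrix(table)
    if (!identical(dim(tab), c(2L, 2L)))
        stop("a 2 x 2 table is required")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all table margins must be positive")
    stats::fisher.test(tab)$p.value
}

#' Two-way ANOVA with Tukey post hoc comparisons
#'
#' Fits `value ~ treatment * age` with type-II sums of squares and follows
#' with Tukey's honestly-significant-difference test on all
#' `treatment x age` cell pairs via the studentized range. Pairs comparing
#' the two treatments within the same age (the comparisons annotated in the
#' study design) are flagged `withinAge`.
#'
#' @param data data.frame with columns `value` (numeric), `treatment` and
#'   `age` (coerced to factors); at least 2 observations per cell.
#' @return list of class `"anovaResult"`: `anova` (data.frame with term, F,
#'   df1, df2, p) and `tukey` (data.frame with comparison, diff, p.adj,
#'   withinAge).
#' @export
twoWayAnovaTukey <- function(data) {
    stopifnot(all(c("value", "treatment", "age") %in% names(data)))
    d <- data.frame(value = data$value,
        treatment = factor(data$treatment), age = factor(data$age))
    cells <- table(d$treatment, d$age)
    if (any(cells < 2L))
        stop("each treatment x age cell needs at least 2 observations")
    fit <- aov(value ~ treatment * age, data = d)
    a2 <- car::Anova(fit, type = 2)
    terms <- c("treatment", "age", "treatment:age")
    dfres <- a2[["Df"]][rownames(a2) == "Residuals"]
    atab <- data.frame(term = terms,
        F = a2[terms, "F value"], df1 = a2[terms, "Df"], df2 = dfres,
        p = a2[terms, "Pr(>F)"], row.names = NULL)
    tk <- TukeyHSD(fit, "treatment:age")[["treatment:age"]]
    cmp <- rownames(tk)
    parts <- strsplit(cmp, "-")
    withinAge <- vapply(parts, function(pr) {
        c1 <- strsplit(pr[1], ":", fixed = TRUE)[[1]]
        c2 <- strsplit(pr[2], ":", fixed = TRUE)[[1]]
        c1[2] == c2[2] && c1[1] != c2[1]
    }, logical(1))
    structure(list(anova = atab,
        tukey = data.frame(comparison = cmp, diff = tk[, "diff"],
            p.adj = tk[, "p adj"], withinAge = withinAge, row.names = NULL)),
        class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
    cat("Two-way ANOVA (type II)\n")
    for (i in seq_len(nrow(x$anova)))
        cat(sprintf("  %-14s F(%d, %d) = %.4g, p = %.4g\n",
            x$anova$term[i], x$anova$df1[i], x$anova$df2[i],
            x$anova$F[i], x$anova$p[i]))
    w <- x$tukey[x$tukey$withinAge, , drop = FALSE]
    if (nrow(w)) {
        cat("Tukey, treatment within age:\n")
        for (i in seq_len(nrow(w)))
            cat(sprintf("  %-24s diff %+.4g, p.adj = %.4g\n",
                w$comparison[i], w$diff[i], w$p.adj[i]))
    }
    invisible(x)
}

#' Pearson correlation
#'
#' Two-sided test of zero correlation via the t transform with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return list with `r`, `r.squared`, `p.value`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
    if (length(x) < 3L) stop("need at least 3 paired observations")
    if (var(x) == 0 || var(y) == 0)
        stop("constant input: correlation undefined")
    ct <- cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    list(r = r, r.squared = r^2, p.value = ct$p.value, n = length(x))
}
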