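# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# random symmetric positive-definite tensors on the diffusivity scale
randomSPD <- function(n, scale = 1e-3) {
    lapply(seq_len(n), function(i) {
        A <- matrix(rnorm(9), 3, 3)
        D <- crossprod(A) + diag(3) * 0.05
        D / max(eigen(D, symmetric = TRUE, only.values = TRUE)$values) *
            scale * runif(1, 0.5, 2)
    })
}

# noiseless forward signals for one tensor under a scheme
forwardSignals <- function(D, scheme, s0 = 1000) {
    g <- directions(scheme)
    b <- bValues(scheme)
    q <- rowSums((g %*% D) * g)
    s0 * exp(-b * q)
}

# literal transcription of the two-stage adaptive step-up definition,
# independent of the package implementation
bkyReference <- function(p, q) {
    m <- length(p)
    qp <- q / (1 + q)
    bhReject <- function(pv, level) {
        s <- sort(pv)
        below <- which(s <= level * seq_len(m) / m)
        if (!length(below)) return(logical(m))
        pv <= s[max(below)]
    }
    stage1 <- bhReject(p, qp)
    r1 <- sum(stage1)
    if (r1 == 0) return(logical(m))
    if (r1 == m) return(rep(TRUE, m))
    bhReject(p, qp * m / (m - r1))
}

# exact two-sided Fisher p by full enumeration of the hypergeometric support
fisherEnumeration <- function(tab) {
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    pObs <- dhyper(a, r1, r2, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# pooled- and unequal-variance t-tests from first principles
manualStudent <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
manualWelch <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    v1 <- var(a) / n1; v2 <- var(b) / n2
    t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# balanced two-way ANOVA sums of squares from cell means
manualTwoWayF <- function(d) {
    n <- nrow(d)
    mu <- mean(d$value)
    cm <- tapply(d$value, list(d$treatment, d$age), mean)
    tm <- tapply(d$value, d$treatment, mean)
    am <- tapply(d$value, d$age, mean)
    reps <- n / length(cm)
    ssT <- reps * ncol(cm) * sum((tm - mu)^2)
    ssA <- reps * nrow(cm) * sum((am - mu)^2)
    ssC <- reps * sum((cm - mu)^2)
    ssI <- ssC - ssT - ssA
    ssE <- sum((d$value - cm[cbind(as.character(d$treatment),
        as.character(d$age))])^2)
    dfT <- nrow(cm) - 1; dfA <- ncol(cm) - 1; dfI <- dfT * dfA
    dfE <- n - length(cm)
    list(F = c(treatment = (ssT / dfT) / (ssE / dfE),
               age = (ssA / dfA) / (ssE / dfE),
               interaction = (ssI / dfI) / (ssE / dfE)),
         df = c(dfT, dfA, dfI, dfE))
}

# exact Burr-probability histogram (normalized over [0, 1])
burrProbHistogram <- function(c, k, alpha, subject = "exact", group = "g") {
    edges <- seq(0, 1, length.out = 101)
    pr <- diff(1 - (1 + (edges / alpha)^c)^(-k))
    new("FAHistogram", binEdges = edges, heights = pr / sum(pr),
        nVoxels = 100000L, subjectId = subject, group = group)
}
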