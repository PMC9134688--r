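test_that("Burr cdf/quantile/pdf are mutually consistent", {
    expect_equal(pburr(0.3, c = 4, k = 1, alpha = 0.3), 0.5)   # x = alpha, k = 1
    ps <- c(0.01, 0.1, 0.5, 0.9, 0.99)
    expect_lt(max(abs(pburr(qburr(ps, 2, 3, 0.5), 2, 3, 0.5) - ps)), 1e-10)
    # median of Burr(2, 3, 0.5) from an independent root of the cdf
    medRoot <- uniroot(function(x) 1 - (1 + (x / 0.5)^2)^(-3) - 0.5,
        c(1e-6, 5), tol = 1e-12)$root
    expect_equal(qburr(0.5, 2, 3, 0.5), medRoot, tolerance = 1e-9)
    expect_equal(qburr(0.5, 2, 3, 0.5), 0.2549, tolerance = 1e-3)
    # quadrature of the density against the cdf
    q99 <- qburr(0.99, 4, 2, 0.3)
    expect_equal(integrate(dburr, 0, q99, c = 4, k = 2, alpha = 0.3,
        rel.tol = 1e-10)$value, 0.99, tolerance = 1e-6)
    expect_error(pburr(0.5, -1, 2, 0.3), "positive")
    expect_error(qburr(1.2, 2, 2, 0.3), "\\(0, 1\\)")
})

test_that("closed-form descriptors match numerical optimization and quadrature", {
    for (par in list(c(4, 2, 0.3), c(3, 1.5, 0.4), c(2.2, 0.8, 0.25))) {
        c0 <- par[1]; k0 <- par[2]; a0 <- par[3]
        modeNum <- optimize(dburr, c(0, 3), c = c0, k = k0, alpha = a0,
            maximum = TRUE, tol = 1e-10)$maximum
        expect_equal(burrMode(c0, k0, a0), modeNum, tolerance = 1e-5)
        meanNum <- integrate(function(x) x * dburr(x, c0, k0, a0), 0, Inf,
            rel.tol = 1e-10)$value
        expect_equal(burrMean(c0, k0, a0), meanNum, tolerance = 1e-6)
        expect_equal(burrMedian(c0, k0, a0), qburr(0.5, c0, k0, a0),
            tolerance = 1e-12)
    }
    # heavy tail: mean undefined when c * k <= 1, mode 0 when c <= 1
    expect_true(is.na(burrMean(1, 0.9, 0.3)))
    expect_equal(burrMode(0.8, 3, 0.3), 0)
})

test_that("histogram binning is normalized with half-open bins", {
    centers <- seq(0.005, 0.995, by = 0.01)
    h <- buildHistogram(centers, "s", "g")
    expect_equal(binHeights(h), rep(0.01, 100))
    expect_equal(sum(binHeights(h)), 1, tolerance = 1e-12)
    # exact boundary values: left edge belongs to the bin, 1.0 to the last
    hb <- buildHistogram(c(0, 0.29, 1.0), "s", "g")
    expect_equal(which(binHeights(hb) > 0), c(1L, 30L, 100L))
    expect_error(buildHistogram(numeric(0), "s", "g"), "no FA values")
    expect_error(buildHistogram(c(0.2, NaN), "s", "g"), "NA/NaN")
    # out-of-range values are dropped, not binned
    hd <- buildHistogram(c(rep(0.5, 9), 1.5), "s", "g")
    expect_equal(hd@nVoxels, 9L)
})

test_that("sampled Burr data reproduce the closed-form median", {
    set.seed(42)
    x <- rburr(1e5, 4, 2, 0.3)
    h <- buildHistogram(x, "s", "g")
    expect_equal(sum(binHeights(h)), 1, tolerance = 1e-12)
    expect_lt(abs(median(x) - burrMedian(4, 2, 0.3)), 0.005)
})

test_that("fit recovers exact bin probabilities to machine precision", {
    fit <- fitBurr(burrProbHistogram(4, 2, 0.3))
    expect_true(fit@converged)
    expect_lt(max(abs(burrParams(fit) - c(4, 2, 0.3)) / c(4, 2, 0.3)), 1e-6)
    expect_lt(fit@sse, 1e-20)
})

test_that("fit on sampled histograms recovers the median within 2%", {
    set.seed(7)
    x <- rburr(5e4, 3, 1.5, 0.4)
    fit <- fitBurr(buildHistogram(x, "s", "g"))
    expect_true(fit@converged)
    target <- burrMedian(3, 1.5, 0.4)
    expect_lt(abs(fit@median - target) / target, 0.02)
    # internal identity: reported median is the fitted-parameter quantile
    expect_equal(fit@median, qburr(0.5, fit@c, fit@k, fit@alpha),
        tolerance = 1e-8)
})

test_that("degenerate single-bin histograms are rejected", {
    h <- new("FAHistogram", binEdges = seq(0, 1, length.out = 101),
        heights = c(rep(0, 49), 1, rep(0, 50)), nVoxels = 10L,
        subjectId = "s", group = "g")
    expect_error(fitBurr(h), "degenerate")
})

test_that("an upward shift of FA values never decreases the fitted median", {
    for (seed in 1:4) {
        set.seed(seed)
        x <- pmin(rburr(2e4, 4, 2, 0.25), 1)
        m0 <- fitBurr(buildHistogram(x, "s", "g"))@median
        m1 <- fitBurr(buildHistogram(pmin(x + 0.05, 1), "s", "g"))@median
        expect_gte(m1, m0 - 1e-10)
    }
})

test_that("group comparison tests the chosen descriptor and averages histograms", {
    set.seed(3)
    mkfit <- function(id, group, a) {
        x <- rburr(5e3, 4, 2, a)
        fitBurr(buildHistogram(x, id, group))
    }
    fits <- c(lapply(1:3, function(i) mkfit(paste0("v", i), "vehicle", 0.25)),
              lapply(1:3, function(i) mkfit(paste0("t", i), "treated", 0.32)))
    hists <- lapply(seq_along(fits), function(i) {
        set.seed(100 + i)
        buildHistogram(rburr(5e3, 4, 2, 0.25), fits[[i]]@subjectId,
            fits[[i]]@group)
    })
    res <- compareGroups(fits, hists, descriptor = "median")
    expect_lt(res$p.value, 0.05)
    expect_equal(unname(rowSums(res$groupAverageHistograms)), c(1, 1),
        tolerance = 1e-12)
    # identical descriptor values in both groups: t = 0, p = 1
    same <- c(lapply(1:3, function(i) mkfit(paste0("a", i), "g1", 0.3)),
              lapply(1:3, function(i) mkfit(paste0("b", i), "g2", 0.3)))
    # force identical per-group descriptor lists
    vals <- vapply(same[1:3], function(f) f@median, 0)
    for (i in 1:3) {
        same[[i + 3]]@median <- vals[i]
        same[[i + 3]]@alpha <- same[[i]]@alpha
        same[[i + 3]]@c <- same[[i]]@c
        same[[i + 3]]@k <- same[[i]]@k
    }
    nul <- compareGroups(same, descriptor = "median")
    expect_equal(nul$t, 0)
    expect_equal(nul$p.value, 1)
    expect_error(compareGroups(fits[c(1, 4, 5)]), "at least 2")
})
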