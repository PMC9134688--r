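mapsFromFA <- function(fa) {
    d <- 1e-3 * array(1, dim(fa))
    new("ScalarMapSet", fa = fa, md = d, ad = d, rd = d,
        mask = array(TRUE, dim(fa)))
}

test_that("regional means pool bilateral voxels and flag empty labels", {
    fa <- array(0, c(4, 4, 1))
    lab <- array(0L, c(4, 4, 1))
    fa[1:2, 1, 1] <- 0.5; lab[1:2, 1, 1] <- 1L
    fa[1, 2, 1] <- 0.4; fa[2, 2, 1] <- 0.6; lab[1:2, 2, 1] <- 2L
    maps <- mapsFromFA(fa)
    tab <- regionalMeans(maps, lab, c("gcc", "ic"))
    expect_equal(tab$value[tab$region == "gcc" & tab$metric == "FA"], 0.5)
    expect_equal(tab$value[tab$region == "ic" & tab$metric == "FA"], 0.5)
    expect_equal(nrow(tab), 8L)   # 2 regions x 4 metrics
    expect_error(regionalMeans(maps, lab, c("gcc", "ic", "opt")), "opt")
})

test_that("phantom regional FA matches the closed-form tract FA", {
    sch <- makeScheme(30, 970)
    spec <- defaultPhantomSpec(groups = c(vehicle = 1L, T4 = 1L), snr = Inf)
    sim <- simulateDWI(spec, sch)
    maps <- computeScalarMaps(fitTensor(sim$subjects[["vehicle_01"]], sch))
    lab <- array(ifelse(sim$labels <= 10, sim$labels, 0L), dim(sim$labels))
    tab <- regionalMeans(maps, lab, sim$regionNames[1:10])
    faTruth <- computeFA(c(1.4e-3, 0.6e-3, 0.6e-3))
    faTab <- tab$value[tab$metric == "FA"]
    expect_equal(faTab, rep(faTruth, 10), tolerance = 1e-8)
    expect_equal(tab$value[tab$metric == "RD"], rep(0.6e-3, 10),
        tolerance = 1e-8)
})

test_that("t-tests match first-principles formulas", {
    set.seed(8)
    for (i in 1:20) {
        a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), sd = 1.7)
        s <- studentT(a, b); ms <- manualStudent(a, b)
        w <- welchT(a, b); mw <- manualWelch(a, b)
        expect_equal(s$t, ms$t, tolerance = 1e-12)
        expect_equal(s$p.value, ms$p, tolerance = 1e-12)
        expect_equal(w$t, mw$t, tolerance = 1e-12)
        expect_equal(w$df, mw$df, tolerance = 1e-12)
        expect_equal(w$p.value, mw$p, tolerance = 1e-12)
    }
    x <- c(1, 2, 3)
    idn <- welchT(x, x)
    expect_equal(idn$t, 0); expect_equal(idn$p.value, 1)
    # equal n and equal variances: the two statistics coincide
    a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
    expect_equal(studentT(a, b)$t, welchT(a, b)$t, tolerance = 1e-12)
    # degenerate zero-variance comparisons are flagged, not errors
    dg <- studentT(c(1, 1), c(1, 1))
    expect_true(dg$degenerate); expect_equal(dg$p.value, 1)
    expect_equal(studentT(c(2, 2), c(1, 1))$p.value, 0)
})

test_that("t-test type-I error is at the nominal level", {
    set.seed(99)
    rej <- mean(replicate(4000, welchT(rnorm(6), rnorm(6))$p.value < 0.05))
    expect_lt(abs(rej - 0.05), 0.012)
})

test_that("two-stage FDR matches an independent transcription of the rule", {
    expect_equal(sum(bkyFdr(rep(1, 8))$discovery), 0L)
    p10 <- c(1e-6, seq(0.5, 0.9, length.out = 9))
    r <- bkyFdr(p10, q = 0.1)
    expect_equal(which(r$discovery), 1L)
    expect_identical(r$discovery, bkyReference(p10, 0.1))
    set.seed(13)
    for (i in 1:150) {
        m <- sample(5:15, 1)
        p <- round(runif(m)^sample(1:3, 1), 3)
        expect_identical(bkyFdr(p, q = 0.1)$discovery, bkyReference(p, 0.1))
    }
    expect_error(bkyFdr(numeric(0)), "empty")
    expect_error(bkyFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are the smallest rejection level and imply the flags", {
    set.seed(21)
    p <- c(0.0005, 0.004, 0.02, 0.2, 0.45, 0.8)
    r <- bkyFdr(p, q = 0.1)
    expect_identical(r$discovery, r$qValues <= 0.1)
    for (i in seq_along(p)) {
        qi <- r$qValues[i]
        if (qi < 1) {
            expect_true(bkyReference(p, qi + 1e-6)[i])
            if (qi > 1e-6) expect_false(bkyReference(p, qi - 1e-6)[i])
        }
    }
})

test_that("adaptive two-stage procedure is at least as powerful as plain BH", {
    set.seed(31)
    for (i in 1:40) {
        p <- runif(10)^sample(1:4, 1)
        bh <- p.adjust(p, "BH") <= 0.1 / 1.1
        expect_true(all(bh <= bkyFdr(p, q = 0.1)$discovery))
    }
})

test_that("Fisher's exact test reproduces enumeration and the eruption table", {
    tab <- matrix(c(9, 2, 1, 10), 2, 2, byrow = TRUE)
    expect_equal(round(fisherExact2x2(tab), 4), 0.0019)
    expect_equal(fisherExact2x2(matrix(5, 2, 2)), 1)
    set.seed(17)
    for (i in 1:60) {
        t2 <- matrix(rpois(4, 5) + 1, 2, 2)
        expect_equal(fisherExact2x2(t2), fisherEnumeration(t2),
            tolerance = 1e-10)
    }
    expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
    # label order cannot change the two-sided p
    expect_equal(fisherExact2x2(tab), fisherExact2x2(tab[2:1, ]),
        tolerance = 1e-12)
})

test_that("two-way ANOVA matches balanced sums of squares and Tukey nulls", {
    set.seed(23)
    d <- expand.grid(rep = 1:5, treatment = c("veh", "trt"),
        age = paste0("P", 7:10))
    d$value <- 2 + 0.8 * (d$treatment == "trt") + 0.5 * as.integer(d$age) +
        rnorm(nrow(d), 0, 0.4)
    res <- twoWayAnovaTukey(d)
    man <- manualTwoWayF(d)
    expect_equal(res$anova$F, unname(man$F), tolerance = 1e-8)
    expect_equal(res$anova$df2[1], man$df[4])
    # replicate structure identical across treatments: treatment F exactly 0
    d0 <- d
    d0$value <- as.integer(d0$age) + 0.1 * d0$rep
    res0 <- twoWayAnovaTukey(d0)
    expect_lt(res0$anova$F[res0$anova$term == "treatment"], 1e-10)
    # identical cell populations: Tukey adjusted p near 1
    dEq <- d
    dEq$value <- rep(c(1, 2, 3, 4, 5), times = 8)
    resEq <- twoWayAnovaTukey(dEq)
    expect_true(all(resEq$tukey$p.adj > 0.999))
    expect_true(any(res$tukey$withinAge))
    expect_error(twoWayAnovaTukey(d[-c(1:5), ]), "at least 2")
})

test_that("Pearson correlation handles exact and sampled relationships", {
    x <- 1:10
    lin <- pearsonCorrelation(x, 2 * x + 1)
    expect_equal(lin$r.squared, 1, tolerance = 1e-12)
    expect_equal(pearsonCorrelation(x, -x)$r, -1, tolerance = 1e-12)
    expect_error(pearsonCorrelation(x, rep(1, 10)), "constant")
    set.seed(12)
    rs <- replicate(2000, {
        z <- rnorm(12); e <- rnorm(12)
        pearsonCorrelation(z, 0.6 * z + sqrt(1 - 0.36) * e)$r
    })
    expect_lt(abs(mean(rs) - 0.6), 0.05)
})
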