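test_that("noiseless DWI equals the forward model and truth fields check out", {
    sch <- makeScheme(30, 970)
    spec <- defaultPhantomSpec(groups = c(vehicle = 1L, T4 = 1L), snr = Inf)
    sim <- simulateDWI(spec, sch)
    # isotropic rim voxel: S = S0 exp(-b d)
    s <- sim$subjects[["vehicle_01"]][1, 1, 1, ]
    expect_equal(s, 1000 * exp(-bValues(sch) * 2.0e-3), tolerance = 1e-12)
    # ground-truth FA of a prolate tract matches the closed form
    trVox <- which(sim$labels == 1, arr.ind = TRUE)[1, ]
    faTruth <- computeFA(c(1.4e-3, 0.6e-3, 0.6e-3))
    expect_equal(sim$truth@faFields[["vehicle"]][trVox[1], trVox[2],
        trVox[3]], faTruth, tolerance = 1e-12)
    # treated group has strictly higher tract FA
    expect_gt(sim$truth@faFields[["T4"]][trVox[1], trVox[2], trVox[3]],
        faTruth)
    # noiseless volumes feed back the exact tensors
    fit <- fitTensor(sim$subjects[["vehicle_01"]], sch)
    expect_lt(max(abs(fit$tensor - sim$truth@tensorFields[["vehicle"]])) /
        2e-3, 1e-10)
})

test_that("DWI simulation is seed-reproducible and seed-sensitive", {
    sch <- makeScheme(12, 970)
    specA <- defaultPhantomSpec(groups = c(vehicle = 1L, T4 = 1L),
        snr = 20, seed = 3)
    specB <- defaultPhantomSpec(groups = c(vehicle = 1L, T4 = 1L),
        snr = 20, seed = 4)
    s1 <- simulateDWI(specA, sch)$subjects[[1]]
    s2 <- simulateDWI(specA, sch)$subjects[[1]]
    s3 <- simulateDWI(specB, sch)$subjects[[1]]
    expect_identical(s1, s2)
    expect_false(identical(s1, s3))
})

test_that("invalid phantom parameters are rejected", {
    expect_error(defaultPhantomSpec(snr = -5), "snr")
    spec <- defaultPhantomSpec()
    expect_error({ spec@tractRadialDiffusivity[] <- 2e-3; validObject(spec) },
        "radial")
})

test_that("developmental MBP curves respect the null and effect contracts", {
    null <- simulateMBPDevelopment(effect = 0, noiseCv = 0, seed = 1)
    mv <- tapply(null$MBP, list(null$group, null$PND), mean)
    expect_equal(unname(mv["T4", ]), unname(mv["vehicle", ]),
        tolerance = 1e-12)
    eff <- simulateMBPDevelopment(effect = 2, noiseCv = 0, seed = 1)
    me <- tapply(eff$MBP, list(eff$group, eff$PND), mean)
    expect_true(all(me["T4", ] >= me["vehicle", ]))
    # strictly greater between the two midpoints (PND 8..10)
    between <- as.character(8:10)
    expect_true(all(me["T4", between] > me["vehicle", between]))
    noisy <- simulateMBPDevelopment(noiseCv = 0.3, seed = 2)
    expect_true(all(noisy$MBP >= 0))
    expect_error(simulateMBPDevelopment(ages = 1:5), "3..11")
    expect_error(simulateMBPDevelopment(effect = -1), "non-negative")
})

test_that("the generated treatment effect is detectable by the ANOVA", {
    hits <- 0L
    for (s in 1:20) {
        d <- simulateMBPDevelopment(effect = 2, noiseCv = 0.1,
            nPerCell = 6L, seed = s)
        res <- twoWayAnovaTukey(data.frame(value = d$MBP,
            treatment = d$group, age = d$PND))
        if (res$anova$p[res$anova$term == "treatment"] < 0.05)
            hits <- hits + 1L
    }
    expect_gte(hits, 18L)
})

test_that("plate simulation is deterministic and arithmetically exact", {
    p1 <- simulatePlate(noiseCv = 0.05, seed = 10)
    p2 <- simulatePlate(noiseCv = 0.05, seed = 10)
    expect_identical(p1, p2)
    pl <- simulatePlate(standardTop = 100, dilutionFactor = 2, nSerial = 7,
        noiseCv = 0)
    expect_equal(sort(pl$nominal[pl$type == "standard"])[1], 100 / 2^6)
    expect_error(simulatePlate(dilutionFactor = 1), "exceed 1")
})

test_that("tooth-eruption tables follow their Bernoulli model", {
    det <- simulateTeeth(nPerGroup = c(a = 8L, b = 8L),
        pEruption = c(a = 1, b = 0), seed = 1)
    expect_equal(unname(det), matrix(c(8L, 0L, 0L, 8L), 2, 2))
    # binomial expectation over repeated tables
    tot <- c(0, 0)
    for (s in 1:500)
        tot <- tot + simulateTeeth(nPerGroup = c(T4 = 11L, vehicle = 11L),
            pEruption = c(T4 = 0.8, vehicle = 0.1), seed = s)[, "erupted"]
    expect_lt(abs(tot[1] / 500 - 8.8), 0.3)
    expect_lt(abs(tot[2] / 500 - 1.1), 0.3)
})

test_that("equal eruption probabilities give nominal Fisher type-I error", {
    rej <- 0L
    for (s in 1:2000) {
        tab <- simulateTeeth(nPerGroup = c(a = 11L, b = 11L),
            pEruption = c(a = 0.5, b = 0.5), seed = s)
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
            fisherExact2x2(tab) <= 0.05)
            rej <- rej + 1L
    }
    expect_lt(rej / 2000, 0.05 + 0.02)
})
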