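test_that("noiseless signals recover the tensor to numerical precision", {
    sch <- makeScheme(30, 970)
    D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
    fit <- fitTensor(forwardSignals(D, sch), sch)
    expect_lt(max(abs(fit$D - D)) / max(abs(D)), 1e-10)
    expect_equal(fit$lnS0, log(1000), tolerance = 1e-10)
    expect_lt(fit$residualRMS, 1e-8)
    # isotropic tensor: all eigenvalues equal
    iso <- fitTensor(forwardSignals(0.7e-3 * diag(3), sch), sch)
    expect_equal(iso$eigenvalues, rep(0.7e-3, 3), tolerance = 1e-10)
    # eigenpairs reconstruct the tensor
    rec <- fit$eigenvectors %*% diag(fit$eigenvalues) %*% t(fit$eigenvectors)
    expect_lt(max(abs(rec - fit$D)), 1e-10 * max(abs(D)))
})

test_that("volume fit matches the single-voxel fit and flags bad voxels", {
    set.seed(11)
    sch <- makeScheme(30, 970)
    Ds <- randomSPD(20)
    S <- t(vapply(Ds, forwardSignals, numeric(31), scheme = sch))
    vol <- array(S, c(20, 1, 1, 31))
    vol[3, 1, 1, 5] <- NA            # an unusable voxel
    fit <- fitTensor(vol, sch)
    expect_false(fit$mask[3, 1, 1])
    expect_true(all(fit$mask[-3, 1, 1]))
    for (i in c(1, 7, 20)) {
        single <- fitTensor(S[i, ], sch)
        expect_equal(fit$tensor[i, 1, 1, 1:3], diag(single$D),
            tolerance = 1e-10)
        expect_equal(sort(fit$eigenvalues[i, 1, 1, ], decreasing = TRUE),
            fit$eigenvalues[i, 1, 1, ])
        expect_equal(fit$eigenvalues[i, 1, 1, ], single$eigenvalues,
            tolerance = 1e-8)
    }
})

test_that("closed-form symmetric eigenvalues agree with eigen()", {
    set.seed(2)
    Ds <- randomSPD(300)
    comp <- t(vapply(Ds, function(D)
        c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]), numeric(6)))
    ours <- myelindex:::symEigenvalues3(comp)
    ref <- t(vapply(Ds, function(D)
        eigen(D, symmetric = TRUE, only.values = TRUE)$values, numeric(3)))
    expect_lt(max(abs(ours - ref)) / max(ref), 1e-8)
})

test_that("signals at or below zero are floored before the log fit", {
    sch <- makeScheme(30, 970)
    S <- forwardSignals(diag(c(1.5e-3, 4e-4, 4e-4)), sch)
    S[10] <- 0
    fit <- fitTensor(S, sch)
    expect_true(all(is.finite(fit$D)))
    expect_error(fitTensor(rep(NA_real_, 31), sch), "non-finite")
})

test_that("FA has its closed-form values and invariances", {
    expect_equal(computeFA(c(5e-4, 5e-4, 5e-4)), 0)
    expect_equal(computeFA(c(1, 0, 0)), 1)
    # direct evaluation of the closed form for the prolate reference tensor
    ev <- c(1.7e-3, 0.3e-3, 0.3e-3)
    fa <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
    expect_equal(computeFA(ev), fa, tolerance = 1e-12)
    expect_equal(computeFA(ev), 0.799, tolerance = 1e-3)
    expect_equal(computeFA(c(0, 0, 0)), 0)   # all-zero convention
    # scale invariance and monotonicity in the leading eigenvalue
    expect_equal(computeFA(ev * 7.3), computeFA(ev), tolerance = 1e-12)
    l1 <- seq(0.4e-3, 2e-3, length.out = 15)
    fas <- computeFA(cbind(l1, 0.3e-3, 0.3e-3))
    expect_true(all(diff(fas) > 0))
    # negative eigenvalues are clamped for FA only
    expect_lte(computeFA(c(1.2e-3, 1e-5, -1e-5)), 1)
})

test_that("FA is bounded and rotation-invariant over random SPD tensors", {
    set.seed(5)
    for (D in randomSPD(400)) {
        ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
        fa <- computeFA(ev)
        expect_gte(fa, 0); expect_lte(fa, 1)
        A <- matrix(rnorm(9), 3, 3)
        R <- qr.Q(qr(A))
        evR <- eigen(R %*% D %*% t(R), symmetric = TRUE,
            only.values = TRUE)$values
        expect_lt(abs(computeFA(evR) - fa), 1e-10)
    }
})

test_that("scalar maps satisfy their defining identities", {
    sch <- makeScheme(30, 970)
    D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
    S <- forwardSignals(D, sch)
    vol <- array(rep(S, each = 8), c(2, 2, 2, 31))
    maps <- computeScalarMaps(fitTensor(vol, sch))
    expect_equal(unname(rdMap(maps)[1, 1, 1]), 0.3e-3, tolerance = 1e-9)
    expect_equal(unname(adMap(maps)[1, 1, 1]), 1.7e-3, tolerance = 1e-9)
    expect_equal(unname(mdMap(maps)[1, 1, 1]), (1.7e-3 + 0.6e-3) / 3,
        tolerance = 1e-7)
    resid <- mdMap(maps) - (adMap(maps) + 2 * rdMap(maps)) / 3
    expect_lt(max(abs(resid[mapMask(maps)])), 1e-18)
    expect_error(computeScalarMaps(fitTensor(vol, sch),
        mask = array(FALSE, c(2, 2, 2))), "empty mask")
})

test_that("scalar maps survive a NIfTI round trip", {
    sch <- makeScheme(30, 970)
    spec <- defaultPhantomSpec(groups = c(vehicle = 1L, T4 = 1L), snr = Inf)
    sim <- simulateDWI(spec, sch)
    maps <- computeScalarMaps(fitTensor(sim$subjects[[1]], sch))
    pre <- file.path(tempdir(), "maps_roundtrip")
    writeScalarMaps(maps, pre)
    back <- readScalarMaps(pre)
    expect_equal(faMap(back), faMap(maps), tolerance = 1e-6)
    expect_equal(mapMask(back), mapMask(maps))
})
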