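test_that("RIL genomes are Bernoulli(0.5) per locus with parents appended", {
    expect_error(simulateRilGenomes(0, 5, seed = 1), "positive")
    expect_error(simulateRilGenomes(5, 0, seed = 1), "positive")
    a1 <- simulateRilGenomes(64, 50, seed = 7)
    a2 <- simulateRilGenomes(64, 50, seed = 7)
    expect_identical(a1, a2)
    expect_equal(dim(a1), c(66, 51))
    expect_equal(unname(a1["P1", ]), rep(0, 51))
    expect_equal(unname(a1["P2", ]), rep(1, 51))
    # allele frequency at a locus converges to 0.5 (exact binomial CI at 1e4)
    big <- simulateRilGenomes(10000, 1, seed = 1)
    phat <- mean(big[seq_len(10000), "core"])
    expect_lt(abs(phat - 0.5), 0.02)
    ci <- stats::binom.test(sum(big[seq_len(10000), "core"]), 10000)$conf.int
    expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("trait simulation reduces to the brute-force allele-effect sum", {
    model <- defaultEffectModel(nPeripheral = 12, noiseSd = 0)
    al <- simulateRilGenomes(10, 12, seed = 3)
    tm <- simulateTraits(al, model, seed = 5)
    v <- traitValues(tm)
    for (p in model$parameters$parameter) {
        want <- vapply(seq_len(nrow(al)), function(g)
            bruteTraitValue(as.list(setNames(al[g, ], colnames(al))),
                            model, p), numeric(1))
        expect_equal(unname(v[, p]), want, tolerance = 1e-12)
    }
})

test_that("degenerate effect models collapse to the baseline", {
    model <- defaultEffectModel(nPeripheral = 6, noiseSd = 0)
    model$coreEffect <- 0
    model$peripheralEffects[] <- 0
    model$couplingTerms <- model$couplingTerms[0, ]
    al <- simulateRilGenomes(4, 6, seed = 2)
    v <- traitValues(simulateTraits(al, model, seed = 2))
    for (j in seq_len(ncol(v)))
        expect_equal(unname(v[, j]), rep(model$parameters$baseline[j], 6))
})

test_that("identical genomes give identical trait rows at zero noise", {
    model <- defaultEffectModel(nPeripheral = 8, noiseSd = 0)
    al <- rbind(gA = c(1, rep(c(0, 1), 4)), gB = c(1, rep(c(0, 1), 4)))
    colnames(al) <- c("core", sprintf("pl%03d", 1:8))
    v <- traitValues(simulateTraits(al, model, seed = 9))
    expect_equal(v["gA", ], v["gB", ])
})

test_that("effect-model preconditions are enforced", {
    model <- defaultEffectModel(nPeripheral = 8)
    al <- simulateRilGenomes(4, 9, seed = 1)
    expect_error(simulateTraits(al, model, seed = 1), "expects")
    bad <- model
    bad$peripheralEffects[1] <- bad$coreEffect * 2
    albad <- simulateRilGenomes(4, 8, seed = 1)
    expect_error(simulateTraits(albad, bad, seed = 1), "core effect")
})

test_that("the all-beneficial genome transgresses both parents everywhere", {
    model <- defaultEffectModel(nPeripheral = 30, noiseSd = 0)
    pop <- simulatePopulation(nRil = 10, nPeripheral = 30, model = model,
                              seed = 4)
    v <- traitValues(populationTraits(pop))
    dirs <- traitDirections(populationTraits(pop))
    st <- designatedOutliers(pop)["super_tolerant"]
    for (p in colnames(v)) {
        if (dirs[[p]] == "higher_better")
            expect_gt(v[st, p], max(v[c("P1", "P2"), p]))
        else
            expect_lt(v[st, p], min(v[c("P1", "P2"), p]))
    }
})

test_that("growth simulation plants an exact piecewise-linear fork", {
    cfg <- growthConfig(noiseSd = 0, noiseSdHeight = 0, forkDay = 7,
                        retentionMin = 0.5, slopeArea = 2)
    gs <- simulateGrowth(tolerance = 0, config = cfg, seed = 1)
    ctl <- armSeries(gs, "control", "area", "mean")
    str <- armSeries(gs, "stress", "area", "mean")
    # identical before the fork; deficit (1-retention)*slope*(d-fork) after
    expect_equal(str[1:7], ctl[1:7])
    expect_equal(ctl[10] - str[10], 3)
    # fully tolerant genotype: no fork at all
    gsT <- simulateGrowth(1, config = cfg, seed = 1)
    expect_equal(armSeries(gsT, "stress", "area", "mean"),
                 armSeries(gsT, "control", "area", "mean"))
    # reproducible under the seed
    gs2 <- simulateGrowth(0, config = cfg, seed = 1)
    expect_identical(armSeries(gs, "stress", "area", "mean"),
                     armSeries(gs2, "stress", "area", "mean"))
    expect_error(simulateGrowth(0, growthConfig(nDays = 5, forkDay = 9)),
                 "window")
    expect_error(simulateGrowth(1.5), "tolerance")
})

test_that("expression simulation plants cohorts and is reproducible", {
    coh <- list(B1 = paste0("c", 1:5))
    e0 <- simulateExpression("g", coh, nBackground = 3, sigma = 0,
                             nReps = 1, seed = 1)
    m <- exprValues(e0, collapse = "none")
    for (g in coh$B1) expect_equal(unname(m[g, ]), unname(m["B1", ]))
    e1 <- simulateExpression("g", coh, nBackground = 3, seed = 5)
    e2 <- simulateExpression("g", coh, nBackground = 3, seed = 5)
    expect_identical(exprValues(e1), exprValues(e2))
    expect_error(simulateExpression("g", list(B1 = c("x", "x"))),
                 "duplicate")
    expect_error(simulateExpression("g", list(B1 = character())),
                 "at least one")
    truth <- S4Vectors::metadata(e1)$groundTruth
    expect_equal(truth$cohorts, coh)
})

test_that("hyperspectral stacks have even band spacing and null behavior", {
    hs <- simulateHyperspectral(nBands = 243, nDays = 2, pixelsPerImage = 5,
                                seed = 1)
    expect_equal(unique(round(diff(hs$wavelengths), 10)),
                 round(1150 / 242, 10))
    # null stress effect: variances agree within sampling error at 1e4 px
    h0 <- simulateHyperspectral(nBands = 5, nDays = 2,
                                pixelsPerImage = 10000, stressEffect = 1,
                                seed = 2)
    hv <- hyperspectralVariance(h0)
    expect_equal(mean(hv$stress / hv$control), 1, tolerance = 0.05)
    expect_error(simulateHyperspectral(pixelsPerImage = 1), "at least 2")
    s1 <- simulateHyperspectral(nBands = 4, nDays = 2, pixelsPerImage = 10,
                                seed = 9)
    s2 <- simulateHyperspectral(nBands = 4, nDays = 2, pixelsPerImage = 10,
                                seed = 9)
    expect_identical(s1$control, s2$control)
})

test_that("populations carry parents once and designated outliers", {
    pop <- simulatePopulation(nRil = 12, nPeripheral = 10, seed = 3)
    al <- alleleMatrix(pop)
    expect_equal(sum(rownames(al) == "P1"), 1)
    expect_equal(sum(rownames(al) == "P2"), 1)
    expect_true(all(designatedOutliers(pop) %in% rownames(al)))
    pe <- pop@model$peripheralEffects
    expect_equal(unname(al["RIL_ST", -1]), as.numeric(pe > 0))
    expect_equal(unname(al["RIL_ST", "core"]), 1)
    expect_equal(unname(al["RIL_SS", -1]), as.numeric(pe < 0))
})
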