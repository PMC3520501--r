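test_that("null scenario stops at once with no discoveries", {
    scen <- ScenarioSpec(generatingHyper = nnHyp(pi = 0),
                         analysisHyper = nnHyp(pi = 0.05),
                         design = DesignSpec(T = 5,
                                             batchPerGroup = c(2, 2),
                                             t0 = 1),
                         util = UtilityParams(c = 10), nGenes = 200,
                         nrep = 6, m = 4, seed = 77)
    oc <- simulateSequentialStudy(scen, Boundary(10, 0))
    expect_lte(oc@meanTau, 1.5)
    expect_lt(oc@meanExpectedTP, 1)
    expect_equal(mean(oc@records$realizedTP), 0)
})

test_that("operating characteristics are reproducible given the seed", {
    scen <- scaledMicroarrayScenario(piScale = 1, nrep = 3, seed = 12,
                                    nGenes = 200, m = 3)
    oc1 <- simulateSequentialStudy(scen, Boundary(50, 0))
    oc2 <- simulateSequentialStudy(scen, Boundary(50, 0))
    expect_identical(oc1@records, oc2@records)
})

test_that("self-comparison of the fixed design yields zero differences", {
    scen <- ScenarioSpec(generatingHyper = nnHyp(pi = 0.2, tau0 = 1.5),
                         design = DesignSpec(T = 4,
                                             batchPerGroup = c(2, 2),
                                             t0 = 1),
                         util = UtilityParams(c = 5), nGenes = 150,
                         nrep = 4, m = 3, seed = 13)
    cmp <- compareDesigns(scen, Boundary(-Inf, 0), fixedN = 4)
    expect_true(all(cmp$perRep$utilityDiff == 0))
    expect_true(all(cmp$perRep$tauDiff == 0))
})

test_that("paired design comparison beats unpaired variance", {
    scen <- ScenarioSpec(generatingHyper = nnHyp(pi = 0.1, tau0 = 1.5),
                         design = DesignSpec(T = 5,
                                             batchPerGroup = c(2, 2),
                                             t0 = 1),
                         util = UtilityParams(c = 10), nGenes = 200,
                         nrep = 10, m = 4, seed = 14)
    cmp <- compareDesigns(scen, Boundary(10, 0), fixedN = 4)
    pairedVar <- var(cmp$perRep$utilityDiff)
    # unpaired: difference of independent replications (shifted pairing)
    unpaired <- cmp$perRep$utilitySeq -
        cmp$perRep$utilityFixed[c(2:10, 1)]
    expect_lt(pairedVar, var(unpaired))
})

test_that("a sequential design adapts when the prior overstates pi", {
    base <- nnHyp(pi = 0.3, tau0 = 1.25)
    gen <- base; priorDEProb(gen) <- 0.1
    scen <- ScenarioSpec(generatingHyper = gen, analysisHyper = base,
                         design = DesignSpec(T = 6,
                                             batchPerGroup = c(2, 2),
                                             t0 = 1),
                         util = UtilityParams(c = 50), nGenes = 500,
                         nrep = 8, m = 5, seed = 15)
    cmp <- compareDesigns(scen, Boundary(50, 0), fixedN = 4)
    expect_lt(cmp$summary$meanTauSeq, 4)
})

test_that("fixed-sample-size curve follows the cost structure", {
    hyp <- nnHyp(pi = 0.2, tau0 = 2)
    des <- DesignSpec(T = 4, batchPerGroup = c(2, 2), t0 = 0)
    # free sampling: more data never hurts
    res0 <- optimalFixedSampleSize(NULL, hyp, des, UtilityParams(c = 0),
                                   B = 120, seed = 16, nGenes = 300)
    expect_identical(res0$nStar, 4L)
    expect_true(all(diff(res0$curve$utility) >= 0))
    # prohibitive sampling cost: do not sample at all
    resC <- optimalFixedSampleSize(NULL, hyp, des,
                                   UtilityParams(c = 500), B = 30,
                                   seed = 16, nGenes = 300)
    expect_identical(resC$nStar, 0L)
    # argmax stable across seeds on a clear-cut toy
    res1 <- optimalFixedSampleSize(NULL, hyp, des, UtilityParams(c = 0),
                                   B = 120, seed = 17, nGenes = 300)
    expect_identical(res0$nStar, res1$nStar)
})

test_that("posterior predictive check accepts self-simulated data", {
    hyp <- nnHyp(pi = 0.1)
    sim <- sampleFromPrior(hyp, 400, c(6, 6), seed = 18)
    chk <- posteriorPredictiveCheck(sim@batch, hyp, nrep = 30, seed = 19)
    expect_false(any(chk$flag))
    chk2 <- posteriorPredictiveCheck(sim@batch, hyp, nrep = 30, seed = 19)
    expect_identical(chk, chk2)
})

test_that("posterior predictive check flags contaminated data", {
    hyp <- nnHyp(pi = 0.05)
    sim <- sampleFromPrior(hyp, 400, c(6, 6), seed = 20)
    vals <- exprValues(sim@batch)
    set.seed(21)
    # heavy-tailed contamination of 10% of the cells
    idx <- sample(length(vals), length(vals) %/% 10)
    vals[idx] <- vals[idx] * exp(pmax(pmin(rt(length(idx), df = 1), 8), -8))
    contaminated <- ExpressionBatch(vals, sampleGroups(sim@batch),
                                    sampleBatches(sim@batch))
    chk <- posteriorPredictiveCheck(contaminated, hyp, nrep = 30,
                                    seed = 22)
    expect_true(any(chk$flag))
})
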