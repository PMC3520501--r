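test_that("EE and DE marginals coincide when only one group is observed", {
    x <- c(350, 420, 610)
    for (hyp in list(nnHyp(), gagaHyp())) {
        expect_equal(logMarginal(hyp, x, numeric(0), "EE"),
                     logMarginal(hyp, x, numeric(0), "DE"))
        expect_equal(logMarginal(hyp, numeric(0), x, "EE"),
                     logMarginal(hyp, numeric(0), x, "DE"))
    }
})

test_that("NN marginals match brute-force grid quadrature", {
    set.seed(101)
    hyp <- nnHyp()
    for (i in 1:4) {
        x0 <- rlnorm(3, 7, 0.7); x1 <- rlnorm(3, 7.4, 0.7)
        for (p in c("EE", "DE"))
            expect_equal(logMarginal(hyp, x0, x1, p),
                         oracleLogMarginalNN(hyp, x0, x1, p),
                         tolerance = 1e-4)
    }
    # variance-independent mean-prior variant (1-D quadrature path)
    hv <- nnHyp(scaledMeans = FALSE)
    x0 <- rlnorm(3, 7, 0.6); x1 <- rlnorm(3, 7, 0.6)
    for (p in c("EE", "DE"))
        expect_equal(logMarginal(hv, x0, x1, p),
                     oracleLogMarginalNN(hv, x0, x1, p), tolerance = 1e-3)
})

test_that("GaGa marginals match brute-force grid quadrature", {
    set.seed(102)
    hyp <- gagaHyp()
    for (i in 1:4) {
        x0 <- rgamma(2, 8, rate = 8 / 500); x1 <- rgamma(2, 8, rate = 8 / 900)
        for (p in c("EE", "DE"))
            expect_equal(logMarginal(hyp, x0, x1, p),
                         oracleLogMarginalGaGa(hyp, x0, x1, p),
                         tolerance = 1e-3)
    }
})

test_that("GaGa quadrature is stable in the number of nodes", {
    hyp <- gagaHyp()
    x0 <- c(310, 520, 460); x1 <- c(900, 1100)
    expect_equal(logMarginal(hyp, x0, x1, "DE", quadNodes = 64L),
                 logMarginal(hyp, x0, x1, "DE", quadNodes = 256L),
                 tolerance = 1e-6)
})

test_that("marginal likelihood input validation", {
    expect_error(logMarginal(nnHyp(), numeric(0), numeric(0), "EE"),
                 "at least one")
    expect_error(logMarginal(gagaHyp(), c(-1, 2), c(3, 4), "EE"),
                 "strictly positive")
})

test_that("posteriorDEProb follows Bayes theorem and the prior limits", {
    sim <- sampleFromPrior(nnHyp(), 30, c(3, 3), seed = 7)
    h0 <- nnHyp(pi = 0); h1 <- nnHyp(pi = 1)
    expect_true(all(posteriorDEProb(sim@batch, h0) == 0))
    expect_true(all(posteriorDEProb(sim@batch, h1) == 1))
    # one gene: v equals the oracle Bayes combination
    hyp <- nnHyp(pi = 0.1)
    x0 <- exprValues(sim@batch)[1, sampleGroups(sim@batch) == 0L]
    x1 <- exprValues(sim@batch)[1, sampleGroups(sim@batch) == 1L]
    mEE <- oracleLogMarginalNN(hyp, x0, x1, "EE")
    mDE <- oracleLogMarginalNN(hyp, x0, x1, "DE")
    vOracle <- 0.1 * exp(mDE) / (0.1 * exp(mDE) + 0.9 * exp(mEE))
    expect_equal(unname(posteriorDEProb(sim@batch, hyp)[1]), vOracle,
                 tolerance = 1e-4)
})

test_that("v is monotonically increasing in pi for fixed data", {
    sim <- sampleFromPrior(nnHyp(), 25, c(4, 4), seed = 8)
    pis <- c(0.01, 0.05, 0.2, 0.5, 0.9)
    vs <- sapply(pis, function(p)
        posteriorDEProb(sim@batch, nnHyp(pi = p)))
    expect_true(all(diff(t(vs)) >= -1e-12))
    gs <- sampleFromPrior(gagaHyp(), 15, c(3, 3), seed = 9)
    vg <- sapply(pis, function(p)
        posteriorDEProb(gs@batch, gagaHyp(pi = p)))
    expect_true(all(diff(t(vg)) >= -1e-12))
})

test_that("prior simulation honors the generative law", {
    hyp <- nnHyp(pi = 0.3)
    sim <- sampleFromPrior(hyp, 10000, c(2, 2), seed = 11)
    # fraction of DE genes inside the binomial 99% interval
    ci <- qbinom(c(0.005, 0.995), 10000, 0.3) / 10000
    frac <- mean(sim@truth@delta)
    expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
    # EE genes have exactly tied means
    ee <- sim@truth@delta == 0L
    expect_identical(sim@truth@mean0[ee], sim@truth@mean1[ee])
    # grand mean of log-values near mu0 (law of large numbers)
    expect_equal(mean(log(exprValues(sim@batch))), 7, tolerance = 0.05)
    # identical seeds reproduce
    sim2 <- sampleFromPrior(hyp, 10000, c(2, 2), seed = 11)
    expect_identical(exprValues(sim@batch), exprValues(sim2@batch))
})

test_that("posterior predictive reduces to the prior with no data", {
    for (hyp in list(nnHyp(), gagaHyp())) {
        pp <- samplePosteriorPredictive(NULL, hyp, c(3, 2), seed = 21,
                                        nGenes = 40)
        sp <- sampleFromPrior(hyp, 40, c(3, 2), seed = 21)
        expect_identical(exprValues(pp$batch), exprValues(sp@batch))
        expect_identical(pp$theta@delta, sp@truth@delta)
    }
})

test_that("posterior predictive is reproducible", {
    sim <- sampleFromPrior(nnHyp(), 20, c(4, 4), nBatches = 2, seed = 31)
    a <- samplePosteriorPredictive(sim@batch, nnHyp(), c(2, 2), seed = 5)
    b <- samplePosteriorPredictive(sim@batch, nnHyp(), c(2, 2), seed = 5)
    expect_identical(exprValues(a$batch), exprValues(b$batch))
    expect_identical(unique(sampleBatches(a$batch)), 1L)
    expect_error(samplePosteriorPredictive(sim@batch, nnHyp(), c(2, 2),
                                           nGenes = 99), "mismatched")
})

test_that("NN predictive mean matches the conjugate posterior mean", {
    # one gene with much data: the predictive log-scale mean converges to
    # the closed-form posterior mean of mu
    hyp <- nnHyp(pi = 0.05)
    set.seed(41)
    y <- rnorm(400, 7.6, 0.5)
    batch <- ExpressionBatch(matrix(exp(y), nrow = 1),
                             group = rep(c(0, 1), each = 200),
                             batch = rep(1, 400))
    k0 <- 1 / hyp@tau0^2
    muN <- (k0 * hyp@mu0 + sum(y)) / (k0 + length(y))
    draws <- vapply(1:3000, function(s) {
        pp <- samplePosteriorPredictive(batch, hyp, c(1, 1), seed = s)
        mean(log(exprValues(pp$batch)))
    }, numeric(1))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - muN), 4 * se)
})

test_that("EM improves the likelihood monotonically and respects bounds", {
    sim <- sampleFromPrior(nnHyp(pi = 0.1), 400, c(6, 6), seed = 51)
    fit <- fitHyperParams(sim@batch, "nn", control = list(maxit = 25L))
    tr <- attr(fit, "trace")
    expect_gte(length(tr), 2)
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
    expect_true(priorDEProb(fit) >= 0 && priorDEProb(fit) <= 1)
    expect_true(all(c(fit@tau0, fit@nu0, fit@sigma0) > 0))
})

test_that("GaGa EM recovers generating hyperparameters approximately", {
    hyp <- gagaHyp(pi = 0.1)
    sim <- sampleFromPrior(hyp, 800, c(8, 8), seed = 52)
    fit <- fitHyperParams(sim@batch, "gaga", control = list(maxit = 15L))
    expect_lt(abs(priorDEProb(fit) - 0.1), 0.05)
    expect_lt(abs(fit@mu - hyp@mu) / hyp@mu, 0.3)
    tr <- attr(fit, "trace")
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
})

test_that("fitHyperParams rejects degenerate inputs", {
    sim <- sampleFromPrior(nnHyp(), 60, c(3, 3), seed = 53)
    vals <- exprValues(sim@batch)
    vals[2, ] <- 5
    bad <- ExpressionBatch(vals, sampleGroups(sim@batch),
                           sampleBatches(sim@batch))
    expect_error(fitHyperParams(bad, "nn"), "gene2")
    expect_error(fitHyperParams(sim@batch[, c(1, 4)], "nn"),
                 "2 samples per group")
    few <- sampleFromPrior(nnHyp(), 10, c(3, 3), seed = 54)
    expect_error(fitHyperParams(few@batch, "nn"), "50 genes")
})

test_that("profile-likelihood pi adjustment recovers deflated truth", {
    gen <- nnHyp(pi = 0.05)
    sim <- sampleFromPrior(gen, 3000, c(10, 10), seed = 61)
    inflated <- nnHyp(pi = 0.20)
    adj <- adjustPi(sim@batch, inflated)
    expect_lt(abs(priorDEProb(adj) - 0.05), 0.02)
    # fixed point: adjusting again moves (essentially) nowhere
    adj2 <- adjustPi(sim@batch, adj)
    expect_lt(abs(priorDEProb(adj2) - priorDEProb(adj)), 1e-3)
    # all-EE data: adjusted pi collapses toward zero
    simNull <- sampleFromPrior(nnHyp(pi = 0), 3000, c(10, 10), seed = 62)
    adjNull <- adjustPi(simNull@batch, nnHyp(pi = 0.1))
    expect_lte(priorDEProb(adjNull), 0.02)
})

test_that("marginal likelihoods are finite across random prior draws", {
    for (hyp in list(nnHyp(), gagaHyp())) {
        sim <- sampleFromPrior(hyp, 200, c(3, 3), seed = 71)
        ss <- seqhts:::.ssForBatch(sim@batch, hyp)
        lm_ <- seqhts:::.logMargMat(ss, hyp)
        expect_true(all(is.finite(lm_)))
    }
})
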