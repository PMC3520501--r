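test_that("stoppingTime follows the boundary and horizon rules", {
    util <- UtilityParams(c = 1)
    des <- DesignSpec(T = 3, t0 = 0)
    # thresholds at k = 0,1 are 0,1 -> no stop; at T-1, 2 - 1 > 0 -> tau = T
    st <- stoppingTime(c(10, 6, 2), Boundary(0, 1), util, des)
    expect_identical(st$tau, 3L)
    expect_identical(st$rule, "horizon_forced")
    # myopic special case: path (60, 40), c = 50 -> stop at second step
    stM <- stoppingTime(c(60, 40), Boundary(50, 0), UtilityParams(c = 50),
                        DesignSpec(T = 2, t0 = 0))
    expect_identical(stM$tau, 1L)
    # fixed-sample sentinel: tau = T iff the final increment beats c
    des5 <- DesignSpec(T = 5, t0 = 0)
    stF <- stoppingTime(c(9, 9, 9, 9, 9), Boundary(-Inf, 0),
                        UtilityParams(c = 5), des5)
    expect_identical(stF$tau, 5L)
    stF2 <- stoppingTime(c(9, 9, 9, 9, 3), Boundary(-Inf, 0),
                         UtilityParams(c = 5), des5)
    expect_identical(stF2$tau, 4L)
    expect_identical(stF2$rule, "horizon_myopic")
    # ties stop (strictly-above means continue)
    stT <- stoppingTime(c(5, 9, 9), Boundary(5, 0), UtilityParams(c = 1),
                        des)
    expect_identical(stT$tau, 0L)
    expect_error(stoppingTime(c(1, 2), Boundary(0, 0), util, des),
                 "incomplete")
})

test_that("boundary (c, 0) reproduces the myopic rule exactly", {
    set.seed(301)
    util <- UtilityParams(c = 3)
    des <- DesignSpec(T = 6, t0 = 1)
    for (i in 1:50) {
        path <- round(runif(5, 0, 8), 2)
        st <- stoppingTime(path, Boundary(util@c, 0), util, des)
        # independent myopic loop: continue while Delta_t U > 0
        tauM <- des@T
        for (j in seq_along(path)) {
            if (path[j] - util@c <= 0) { tauM <- des@t0 + j - 1L; break }
        }
        expect_identical(st$tau, as.integer(tauM))
    }
})

test_that("boundaryExpectedUtility averages hand-computable utilities", {
    # two hand-built trajectories over T = 3, t0 = 0
    ts <- new("TrajectorySet",
              deltaTP = rbind(c(4, 3, 1), c(1, 5, 6)),
              expectedTPAt = rbind(c(0, 4, 7, 8), c(0, 1, 6, 12)),
              t0 = 0L, seed = 0L)
    util <- UtilityParams(c = 2)
    bu <- boundaryExpectedUtility(ts, Boundary(2, 0), util)
    # traj 1: continues (4>2, 3>2), at T-1: 1-2<=0 stop at tau=2, u=7-4=3
    # traj 2: stops at k=0 (1<=2), u = 0
    expect_equal(bu$perTrajectory$tau, c(2L, 0L))
    expect_equal(bu$utility, mean(c(3, 0)))
    # all trajectories stopping immediately: zero variance
    bu0 <- boundaryExpectedUtility(ts, Boundary(100, 0), util)
    expect_equal(bu0$se, 0)
    expect_equal(bu0$utility, 0)
    # non-increasing in c
    us <- vapply(c(0, 1, 2, 5), function(cc)
        boundaryExpectedUtility(ts, Boundary(2, 0),
                                UtilityParams(c = cc))$utility, numeric(1))
    expect_true(all(diff(us) <= 1e-12))
    # invariant to trajectory order
    tsPerm <- new("TrajectorySet", deltaTP = ts@deltaTP[2:1, ],
                  expectedTPAt = ts@expectedTPAt[2:1, ], t0 = 0L,
                  seed = 0L)
    expect_equal(boundaryExpectedUtility(tsPerm, Boundary(2, 0),
                                         util)$utility, bu$utility)
})

test_that("optimizeBoundary agrees with a brute-force oracle", {
    set.seed(302)
    util <- UtilityParams(c = 2)
    ts <- new("TrajectorySet",
              deltaTP = matrix(runif(9, 0, 6), 3),
              expectedTPAt = t(apply(matrix(runif(12, 0, 4), 3), 1,
                                     cumsum)),
              t0 = 0L, seed = 0L)
    b0s <- seq(0, 6, length.out = 5)
    b1s <- seq(-2, 2, length.out = 5)
    opt <- optimizeBoundary(ts, util, b0s, b1s)
    or <- oracleBoundaryOpt(ts, b0s, b1s, util@c)
    expect_equal(max(opt$surface$utility), or$utility)
    expect_equal(opt$surface$utility,
                 or$surface$utility[order(or$surface$b1, or$surface$b0)],
                 tolerance = 1e-12)
    # single-point grid returns that boundary
    opt1 <- optimizeBoundary(ts, util, 1.5, 0.5)
    expect_equal(opt1$boundary@b0, 1.5)
    expect_equal(opt1$boundary@b1, 0.5)
    # a grid containing the myopic point can only do at least as well
    optM <- optimizeBoundary(ts, util, c(util@c, 0, 4), c(0, 1))
    um <- boundaryExpectedUtility(ts, Boundary(util@c, 0), util)$utility
    expect_gte(max(optM$surface$utility), um)
})

test_that("a degenerate analysis prior gives zero one-step gain", {
    hyp0 <- nnHyp(pi = 0)
    sim <- sampleFromPrior(nnHyp(pi = 0.1), 50, c(2, 2), seed = 33)
    est <- deltaTPOneStep(sim@batch, hyp0, UtilityParams(c = 10),
                          batchPerGroup = c(2, 2), m = 5, seed = 1)
    expect_identical(est$estimate, 0)
    ts <- forwardSimulate(sim@batch, hyp0,
                          DesignSpec(T = 3, batchPerGroup = c(2, 2),
                                     t0 = 1),
                          UtilityParams(c = 10), B = 4, seed = 2)
    expect_true(all(ts@deltaTP == 0))
})

test_that("deltaTPOneStep is reproducible and consistent with forward sim", {
    hyp <- nnHyp(pi = 0.2)
    sim <- sampleFromPrior(hyp, 80, c(2, 2), seed = 44)
    e1 <- deltaTPOneStep(sim@batch, hyp, m = 7, seed = 9)
    e2 <- deltaTPOneStep(sim@batch, hyp, m = 7, seed = 9)
    expect_identical(e1$draws, e2$draws)
    des <- DesignSpec(T = 2, batchPerGroup = c(2, 2), t0 = 1)
    ts <- forwardSimulate(sim@batch, hyp, des, UtilityParams(), B = 7,
                          seed = 9)
    expect_equal(unname(ts@deltaTP[, 1]), unname(e1$draws))
})

test_that("MC one-step gain matches exhaustive predictive integration", {
    hyp <- nnHyp(pi = 0.25)
    set.seed(55)
    values <- rbind(exp(rnorm(6, c(6.6, 6.6, 6.6, 7.6, 7.6, 7.6), 0.4)),
                    exp(rnorm(6, 7.1, 0.5)))
    batch <- ExpressionBatch(values, group = rep(c(0, 1), each = 3),
                             batch = rep(1, 6))
    oracle <- oracleDeltaTPTwoGene(hyp, batch, 0.05)
    est <- deltaTPOneStep(batch, hyp, UtilityParams(), c(1, 1), m = 4000,
                          seed = 56)
    expect_lt(abs(est$estimate - oracle), 3 * est$se + 0.002)
})

test_that("forwardSimulate validates design and guards memory", {
    sim <- sampleFromPrior(nnHyp(), 50, c(4, 4), nBatches = 2, seed = 66)
    expect_error(forwardSimulate(sim@batch, nnHyp(),
                                 DesignSpec(T = 4, t0 = 1),
                                 B = 2, seed = 1), "t0")
    expect_error(forwardSimulate(sim@batch, nnHyp(),
                                 DesignSpec(T = 4, t0 = 2), B = 5,
                                 seed = 1, maxCells = 10), "maxCells")
    ts <- forwardSimulate(sim@batch, nnHyp(),
                          DesignSpec(T = 4, t0 = 2), B = 3, seed = 1)
    expect_identical(dim(ts@deltaTP), c(3L, 2L))
    expect_identical(dim(ts@expectedTPAt), c(3L, 3L))
})

test_that("monitorStep compares the estimate with the right threshold", {
    hyp <- nnHyp(pi = 0.3, tau0 = 2)
    sim <- sampleFromPrior(hyp, 300, c(2, 2), seed = 77)
    des <- DesignSpec(T = 8, batchPerGroup = c(2, 2), t0 = 1)
    # generous boundary: early gain is far above a tiny threshold
    ms <- monitorStep(sim@batch, hyp, Boundary(0.01, 0),
                      UtilityParams(c = 0.01), des, m = 5, seed = 3)
    expect_identical(ms$decision, "continue")
    expect_identical(ms$rule, "boundary")
    expect_equal(ms$threshold, 0.01)
    # pi = 0 with positive cost always stops
    ms0 <- monitorStep(sim@batch, nnHyp(pi = 0), Boundary(50, 0),
                       UtilityParams(c = 50), des, m = 3, seed = 3)
    expect_identical(ms0$decision, "stop")
    # at the horizon stopping is forced
    full <- sampleFromPrior(hyp, 50, c(16, 16), nBatches = 8, seed = 78)
    msT <- monitorStep(full@batch, hyp, Boundary(0, 0), UtilityParams(),
                       des, m = 3, seed = 3)
    expect_identical(msT$decision, "stop")
    expect_identical(msT$rule, "horizon_forced")
    # at T-1 the myopic rule replaces the boundary
    at7 <- batchPrefix(full@batch, 7)
    ms7 <- monitorStep(at7, hyp, Boundary(-Inf, 0), UtilityParams(c = 1e6),
                       des, m = 3, seed = 3)
    expect_identical(ms7$rule, "horizon_myopic")
    expect_identical(ms7$decision, "stop")
})
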