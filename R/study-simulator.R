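# Study-level design evaluation: replicate simulated studies run through the
# sequential monitoring rule, fixed-design utility curves, paired design
# comparisons, and posterior-predictive goodness-of-fit summaries.

# Monitor one pre-generated data stream batch by batch until stopping.
# monitorSeed(t) supplies the substream for the predictive draws at step t,
# so that two designs evaluated on the same stream share all randomness.
.runOneStudy <- function(stream, analysisHyper, boundary, util, design, m,
                         monitorSeed) {
    full <- stream@batch
    truth <- stream@truth
    n <- nGenes(full)
    t <- design@t0
    repeat {
        cur <- if (t == 0L) NULL else batchPrefix(full, t)
        ms <- monitorStep(cur, analysisHyper, boundary, util, design,
                          m = m, seed = monitorSeed(t), nGenes = n)
        if (ms$decision == "stop" || t >= design@T) break
        t <- t + 1L
    }
    ps <- ms$posterior
    D <- ps@D
    realizedTP <- sum(ps@d * truth@delta)
    realizedFDR <- if (D > 0L) sum(ps@d * (1L - truth@delta)) / D else 0
    data.frame(tau = t, rule = ms$rule, D = D,
               expectedTP = ps@expectedTP, realizedTP = realizedTP,
               realizedFDR = realizedFDR,
               expectedUtility = ps@expectedTP - util@c * t,
               realizedUtility = realizedTP - util@c * t)
}

.streamForRep <- function(scenario, r) {
    des <- scenario@design
    sampleFromPrior(scenario@generatingHyper, scenario@nGenes,
                    samplesPerGroup = des@batchPerGroup * des@T,
                    nBatches = des@T,
                    seed = .substream(scenario@seed, r))
}

.monitorSeedFun <- function(scenario, r) {
    function(t) .substream(scenario@seed, 100003L + r * 1009L + t)
}

#' Operating characteristics of a sequential design
#'
#' Runs \code{nrep} replicate studies: each generates per-gene truth and a
#' full data stream from the generating hyperparameters, then monitors batch
#' by batch under the analysis hyperparameters and the given boundary until
#' stopping.  Stopping time, terminal decisions, and realized true positives
#' and FDR against the simulation truth are recorded and aggregated.  The
#' generating and analysis models may differ (prior misspecification).
#'
#' @param scenario a \code{\linkS4class{ScenarioSpec}}.
#' @param boundary a \code{\linkS4class{Boundary}} (typically from
#'   \code{\link{optimizeBoundary}}, or the myopic \code{Boundary(c, 0)}).
#' @return an \code{\linkS4class{OperatingCharacteristics}}.
#' @export
simulateSequentialStudy <- function(scenario, boundary) {
    recs <- lapply(seq_len(scenario@nrep), function(r) {
        stream <- .streamForRep(scenario, r)
        .runOneStudy(stream, scenario@analysisHyper, boundary,
                     scenario@util, scenario@design, scenario@m,
                     .monitorSeedFun(scenario, r))
    })
    recs <- do.call(rbind, recs)
    recs$rep <- seq_len(nrow(recs))
    new("OperatingCharacteristics",
        meanTau = mean(recs$tau),
        meanUtility = mean(recs$expectedUtility),
        meanExpectedTP = mean(recs$expectedTP),
        meanRealizedFDR = mean(recs$realizedFDR),
        records = recs)
}

#' Expected-utility curve over fixed sample sizes
#'
#' For every fixed design of \code{n} batches, \code{n = t0 .. T}, estimates
#' the predictive expected utility of stopping deterministically at \code{n}
#' (posterior expected true positives after \code{n} batches minus
#' \code{c * n}), averaged over \code{B} datasets simulated from the
#' posterior predictive given \code{batch} (the prior predictive when
#' \code{batch} is \code{NULL}).
#'
#' @inheritParams forwardSimulate
#' @return list with \code{nStar} (the utility-maximizing fixed number of
#'   batches), \code{curve} (data frame \code{n}, \code{utility},
#'   \code{se}), and \code{trajset} (the underlying
#'   \code{\linkS4class{TrajectorySet}}).
#' @export
optimalFixedSampleSize <- function(batch, hyper, design,
                                   util = UtilityParams(), B = 200L,
                                   seed = 1L, nGenes = NULL,
                                   quadNodes = 64L) {
    ts <- forwardSimulate(batch, hyper, design, util, B = B, seed = seed,
                          nGenes = nGenes, quadNodes = quadNodes)
    ns <- ts@t0:design@T
    u <- sweep(ts@expectedTPAt, 2L, util@c * ns, "-")
    curve <- data.frame(n = ns, utility = colMeans(u),
                        se = apply(u, 2L, sd) / sqrt(nrow(u)))
    list(nStar = ns[which.max(curve$utility)], curve = curve, trajset = ts)
}

#' Paired comparison of a sequential and a fixed design
#'
#' Evaluates both designs on identical simulated data streams (shared seeds,
#' including the monitoring substreams), and reports per-replication paired
#' differences in realized expected utility and sample size.  The fixed
#' design of \code{fixedN} batches is run through the same stopping
#' machinery with the fixed-sample sentinel boundary (\code{b0 = -Inf},
#' horizon \code{fixedN}).
#'
#' @param scenario a \code{\linkS4class{ScenarioSpec}} (its design governs
#'   the sequential arm).
#' @param boundary boundary for the sequential arm.
#' @param fixedN number of batches of the fixed design,
#'   \code{> scenario@design@t0}.
#' @return list with \code{perRep} (paired records) and \code{summary}
#'   (mean differences with Monte Carlo standard errors).
#' @export
compareDesigns <- function(scenario, boundary, fixedN) {
    des <- scenario@design
    fixedN <- as.integer(fixedN)
    if (fixedN <= des@t0 || fixedN > des@T)
        stop("fixedN must lie in (t0, T]")
    fixedDesign <- new("DesignSpec", T = fixedN,
                       batchPerGroup = des@batchPerGroup, t0 = des@t0)
    fixedBoundary <- Boundary(-Inf, 0)
    rows <- lapply(seq_len(scenario@nrep), function(r) {
        stream <- .streamForRep(scenario, r)
        sfun <- .monitorSeedFun(scenario, r)
        seq_ <- .runOneStudy(stream, scenario@analysisHyper, boundary,
                             scenario@util, des, scenario@m, sfun)
        fix_ <- .runOneStudy(stream, scenario@analysisHyper, fixedBoundary,
                             scenario@util, fixedDesign, scenario@m, sfun)
        data.frame(rep = r, tauSeq = seq_$tau, tauFixed = fix_$tau,
                   utilitySeq = seq_$expectedUtility,
                   utilityFixed = fix_$expectedUtility,
                   utilityDiff = seq_$expectedUtility - fix_$expectedUtility,
                   tauDiff = seq_$tau - fix_$tau)
    })
    perRep <- do.call(rbind, rows)
    nrep <- nrow(perRep)
    list(perRep = perRep,
         summary = data.frame(
             meanTauSeq = mean(perRep$tauSeq),
             meanTauFixed = mean(perRep$tauFixed),
             meanUtilityDiff = mean(perRep$utilityDiff),
             seUtilityDiff = if (nrep > 1L)
                 sd(perRep$utilityDiff) / sqrt(nrep) else 0,
             meanTauDiff = mean(perRep$tauDiff)))
}

.geneStats <- function(values, logScale) {
    x <- if (logScale) log(values) else values
    m <- rowMeans(x)
    s <- apply(x, 1L, sd)
    ctr <- x - m
    skew <- rowMeans(ctr^3) / pmax(rowMeans(ctr^2)^1.5, 1e-12)
    list(mean = m, sd = s, skew = skew)
}

#' Posterior-predictive goodness-of-fit summary
#'
#' Simulates replicate datasets of the same dimensions from the fitted
#' model and compares quantiles of the per-gene mean, standard deviation and
#' skewness (computed on the log scale for the NN model, the raw scale for
#' GaGa) between the observed data and the simulations.  Discrepancies are
#' reported as z-scores against the simulation distribution; |z| > 3 is
#' flagged.
#'
#' @param batch observed \code{\linkS4class{ExpressionBatch}}.
#' @param hyper fitted \code{\linkS4class{HyperParams}}.
#' @param nrep number of replicate simulated datasets.
#' @param seed integer seed.
#' @param probs quantiles compared.
#' @return data frame with one row per (statistic, quantile).
#' @export
posteriorPredictiveCheck <- function(batch, hyper, nrep = 50L, seed = 1L,
                                     probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    if (ncol(batch) == 0L) stop("batch must contain data")
    logScale <- modelId(hyper) == "nn"
    grp <- sampleGroups(batch)
    spg <- c(sum(grp == 0L), sum(grp == 1L))
    obs <- .geneStats(exprValues(batch), logScale)
    obsQ <- lapply(obs, quantile, probs = probs, names = FALSE)
    simQ <- lapply(seq_len(nrep), function(r) {
        sim <- sampleFromPrior(hyper, nGenes(batch), spg,
                               seed = .substream(seed, r))
        st <- .geneStats(exprValues(sim@batch), logScale)
        lapply(st, quantile, probs = probs, names = FALSE)
    })
    rows <- lapply(names(obsQ), function(nm) {
        mat <- do.call(rbind, lapply(simQ, `[[`, nm))
        mu <- colMeans(mat)
        sdv <- pmax(apply(mat, 2L, sd), 1e-12)
        z <- (obsQ[[nm]] - mu) / sdv
        data.frame(stat = nm, prob = probs, observed = obsQ[[nm]],
                   simMean = mu, simSD = sdv, z = z, flag = abs(z) > 3)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
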