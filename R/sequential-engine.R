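# Forward simulation of the monitoring statistic Delta_t(TP), linear
# stopping boundaries, stopping-time evaluation and grid-search boundary
# optimization.

.emptySS <- function(n, model) {
    z <- numeric(n)
    list(model = model, n = as.integer(n), m0 = 0L, m1 = 0L,
         s0 = z, s1 = z, q0 = z, q1 = z)
}

# Posterior (or prior, with no data) DE probabilities from sufficient stats.
.vFromSS <- function(ss, hyper, quadNodes) {
    if (ss$m0 + ss$m1 == 0L) return(rep(hyper@pi, ss$n))
    .postDEProbFromLM(.logMargMat(ss, hyper, quadNodes), hyper@pi)
}

#' Forward simulation of monitoring-statistic trajectories
#'
#' Simulates \code{B} complete futures of the experiment from the posterior
#' predictive distribution given the current data (the prior predictive when
#' no data are available).  Along each trajectory the posterior summary is
#' recomputed after every simulated batch, and the realized one-step
#' increment in the posterior expected number of true positives,
#' \eqn{\Delta_k(TP)}, is recorded for steps \code{k = t0 .. T-1}.
#' Trajectories use independent seed substreams, so results do not depend on
#' evaluation order.
#'
#' @param batch current data (\code{\linkS4class{ExpressionBatch}}) or
#'   \code{NULL} for design from no data.
#' @param hyper analysis \code{\linkS4class{HyperParams}}.
#' @param design a \code{\linkS4class{DesignSpec}}; \code{design@t0} must
#'   match the number of observed batches.
#' @param util a \code{\linkS4class{UtilityParams}} (supplies the terminal
#'   FDR level).
#' @param B number of simulated trajectories.
#' @param seed integer root seed.
#' @param nGenes gene count, required when \code{batch} is \code{NULL}.
#' @param quadNodes quadrature nodes for the marginal likelihoods.
#' @param maxCells guard on \code{nGenes * B * (T - t0)}; exceeding it is an
#'   error rather than an out-of-memory surprise.
#' @return a \code{\linkS4class{TrajectorySet}}.
#' @examples
#' hyp <- NNHyperParams(7, 1, 6, 0.6, pi = 0.1)
#' des <- DesignSpec(T = 3, batchPerGroup = c(2, 2), t0 = 0)
#' ts <- forwardSimulate(NULL, hyp, des, UtilityParams(c = 5), B = 10,
#'                       seed = 1, nGenes = 100)
#' @export
forwardSimulate <- function(batch, hyper, design, util = UtilityParams(),
                            B = 500L, seed = 1L, nGenes = NULL,
                            quadNodes = 64L, maxCells = 5e8) {
    t0 <- design@t0
    empty <- is.null(batch) || ncol(batch) == 0L
    if (!empty && nBatches(batch) != t0)
        stop("design@t0 (", t0, ") must equal the number of observed ",
             "batches (", nBatches(batch), ")")
    if (t0 >= design@T)
        stop("horizon already reached: t0 >= T")
    if (B < 1L) stop("B must be >= 1")
    n <- if (empty) {
        if (is.null(nGenes)) stop("nGenes is required when no data are given")
        as.integer(nGenes)
    } else nGenes(batch)
    K <- design@T - t0
    if (as.double(n) * B * K > maxCells)
        stop("requested simulation size n*B*(T-t0) = ",
             format(as.double(n) * B * K, big.mark = ","),
             " exceeds maxCells")
    ss0 <- if (empty) .emptySS(n, modelId(hyper)) else
        .ssForBatch(batch, hyper)
    v0 <- .vFromSS(ss0, hyper, quadNodes)
    etp0 <- bayesTerminalDecision(v0, util@fdrLevel)@expectedTP
    spg <- design@batchPerGroup
    etpMat <- matrix(NA_real_, B, K + 1L)
    etpMat[, 1L] <- etp0
    for (j in seq_len(B)) {
        set.seed(.substream(seed, j))
        delta <- rbinom(n, 1L, v0)
        theta <- if (ss0$m0 + ss0$m1 == 0L) {
            # no data: conditional posterior given delta is the prior with
            # the tie imposed by the drawn delta
            .drawThetaGivenDelta(hyper, delta)
        } else .drawThetaPosterior(hyper, ss0, delta, quadNodes)
        ss <- ss0
        for (k in seq_len(K)) {
            d <- .drawData(theta, hyper, spg, 1L, firstBatch = t0 + k)
            new0 <- d$values[, d$groups == 0L, drop = FALSE]
            new1 <- d$values[, d$groups == 1L, drop = FALSE]
            ss <- .ssAppend(ss, new0, new1)
            v <- .vFromSS(ss, hyper, quadNodes)
            etpMat[j, k + 1L] <-
                bayesTerminalDecision(v, util@fdrLevel)@expectedTP
        }
    }
    dTP <- etpMat[, -1L, drop = FALSE] - etpMat[, -(K + 1L), drop = FALSE]
    colnames(dTP) <- paste0("k", t0:(design@T - 1L))
    colnames(etpMat) <- paste0("t", t0:design@T)
    new("TrajectorySet", deltaTP = dTP, expectedTPAt = etpMat,
        t0 = as.integer(t0), seed = as.integer(seed))
}

# prior draw of theta with delta fixed (used for t0 = 0 trajectories so the
# delta used in the trajectory matches the recorded truth draw)
.drawThetaGivenDelta <- function(hyper, delta) {
    n <- length(delta)
    if (is(hyper, "NNHyperParams")) {
        sig2 <- hyper@nu0 * hyper@sigma0^2 / rchisq(n, hyper@nu0)
        sdm <- if (hyper@scaledMeans) hyper@tau0 * sqrt(sig2) else
            rep(hyper@tau0, n)
        m0 <- rnorm(n, hyper@mu0, sdm)
        m1a <- rnorm(n, hyper@mu0, sdm)
        new("GeneParams", delta = as.integer(delta), mean0 = m0,
            mean1 = ifelse(delta == 1L, m1a, m0), shapeOrVar = sig2)
    } else {
        alpha <- rgamma(n, hyper@beta, rate = hyper@beta / hyper@mu)
        l0 <- 1 / rgamma(n, hyper@alpha0, rate = hyper@alpha0 / hyper@nu)
        l1a <- 1 / rgamma(n, hyper@alpha0, rate = hyper@alpha0 / hyper@nu)
        new("GeneParams", delta = as.integer(delta), mean0 = l0,
            mean1 = ifelse(delta == 1L, l1a, l0), shapeOrVar = alpha)
    }
}

#' One-step-ahead expected gain in true positives
#'
#' Monte Carlo estimate of \eqn{\Delta_t(TP)}: draws \code{m} one-step-ahead
#' batches from the posterior predictive, recomputes the terminal decision on
#' each augmented dataset, and averages the increase in the posterior
#' expected number of true positives.  The monitoring statistic is
#' \eqn{\Delta_t U = \Delta_t(TP) - c}.
#'
#' @inheritParams forwardSimulate
#' @param batchPerGroup samples per group in the hypothetical next batch.
#' @param m number of posterior-predictive draws.
#' @return list with \code{estimate}, \code{se} (Monte Carlo standard
#'   error), and \code{draws} (the \code{m} simulated increments).
#' @export
deltaTPOneStep <- function(batch, hyper, util = UtilityParams(),
                           batchPerGroup = c(2L, 2L), m = 20L, seed = 1L,
                           nGenes = NULL, quadNodes = 64L) {
    if (m < 1L) stop("m must be >= 1")
    t0 <- if (is.null(batch) || ncol(batch) == 0L) 0L else nBatches(batch)
    des <- DesignSpec(T = t0 + 1L, batchPerGroup = batchPerGroup, t0 = t0)
    ts <- forwardSimulate(batch, hyper, des, util, B = m, seed = seed,
                          nGenes = nGenes, quadNodes = quadNodes)
    draws <- ts@deltaTP[, 1L]
    list(estimate = mean(draws),
         se = if (m > 1L) sd(draws) / sqrt(m) else NA_real_,
         draws = draws)
}

#' Stopping time of a monitoring-statistic path under a linear boundary
#'
#' Scans the path \eqn{\Delta_k(TP)}, \code{k = t0 .. T-1}: at
#' \code{k <= T-2} stopping occurs at the first step where the statistic
#' falls on or below \code{b0 + b1 * k} ("above the boundary" is strict, so
#' ties stop); at \code{k = T-1} the boundary is replaced by the myopic rule
#' (stop unless \eqn{\Delta_{T-1}(TP) - c > 0}); reaching the horizon forces
#' \eqn{\tau = T}.
#'
#' @param deltaPath numeric vector of length \code{T - t0}, the increments at
#'   steps \code{t0 .. T-1}.
#' @param boundary a \code{\linkS4class{Boundary}}.
#' @param util a \code{\linkS4class{UtilityParams}}.
#' @param design a \code{\linkS4class{DesignSpec}}.
#' @return list with \code{tau} (batches at stopping) and \code{rule}, one
#'   of \code{"boundary"}, \code{"horizon_myopic"}, \code{"horizon_forced"}.
#' @examples
#' des <- DesignSpec(T = 3, t0 = 0)
#' stoppingTime(c(10, 6, 2), Boundary(0, 1), UtilityParams(c = 1), des)
#' @export
stoppingTime <- function(deltaPath, boundary, util, design) {
    K <- design@T - design@t0
    if (length(deltaPath) != K || anyNA(deltaPath))
        stop("incomplete trajectory: expected ", K,
             " finite increments for steps ", design@t0, "..",
             design@T - 1L)
    st <- .stoppingTimes(matrix(deltaPath, 1L), design@t0, boundary, util,
                         design@T)
    list(tau = st$tau[1L], rule = st$rule[1L])
}

# vectorized stopping times for a B x K matrix of increments
.stoppingTimes <- function(dTP, t0, boundary, util, T) {
    B <- nrow(dTP)
    K <- ncol(dTP)
    ks <- t0:(T - 1L)
    stopAt <- matrix(FALSE, B, K + 1L)
    if (K > 1L) {
        thr <- boundary@b0 + boundary@b1 * ks[seq_len(K - 1L)]
        stopAt[, seq_len(K - 1L)] <-
            sweep(dTP[, seq_len(K - 1L), drop = FALSE], 2L, thr, "<=")
    }
    stopAt[, K] <- dTP[, K] - util@c <= 0
    stopAt[, K + 1L] <- TRUE
    first <- apply(stopAt, 1L, function(r) which(r)[1L])
    tau <- t0 + first - 1L
    rule <- ifelse(first <= K - 1L, "boundary",
                   ifelse(first == K, "horizon_myopic", "horizon_forced"))
    list(tau = as.integer(tau), rule = rule)
}

#' Expected utility of a boundary on a simulated trajectory set
#'
#' Applies \code{\link{stoppingTime}} to every trajectory and averages the
#' terminal utility \eqn{E(TP)\,\mathrm{at}\,\tau - c\,\tau}.
#'
#' @param trajset a \code{\linkS4class{TrajectorySet}}.
#' @param boundary a \code{\linkS4class{Boundary}}.
#' @param util a \code{\linkS4class{UtilityParams}}.
#' @return list with \code{utility}, \code{se}, \code{meanTau}, and the
#'   per-trajectory data frame \code{perTrajectory}.
#' @export
boundaryExpectedUtility <- function(trajset, boundary, util) {
    B <- nrow(trajset@deltaTP)
    if (B == 0L) stop("empty trajectory set")
    t0 <- trajset@t0
    T <- t0 + ncol(trajset@deltaTP)
    st <- .stoppingTimes(trajset@deltaTP, t0, boundary, util, T)
    etpAtTau <- trajset@expectedTPAt[cbind(seq_len(B), st$tau - t0 + 1L)]
    u <- etpAtTau - util@c * st$tau
    list(utility = mean(u),
         se = if (B > 1L) sd(u) / sqrt(B) else 0,
         meanTau = mean(st$tau),
         perTrajectory = data.frame(trajectory = seq_len(B), tau = st$tau,
                                    rule = st$rule, expectedTP = etpAtTau,
                                    utility = u))
}

#' Grid-search optimization of the stopping boundary
#'
#' Evaluates the expected utility of every boundary on the Cartesian grid
#' \code{b0Grid x b1Grid} against a shared trajectory set, and returns all
#' boundaries within one Monte Carlo standard error of the maximum (several
#' boundaries are often statistically indistinguishable).  The designated
#' representative is the optimum with the smallest expected stopping time,
#' i.e. the cheapest design among equals.
#'
#' @inheritParams boundaryExpectedUtility
#' @param b0Grid,b1Grid numeric grids for the intercept and slope; defaults
#'   span \code{[0, 3c]} and \code{[-c, c]} in 21 steps.
#' @return list with \code{boundary} (representative
#'   \code{\linkS4class{Boundary}}), \code{optima} (data frame of the
#'   argmax set), and \code{surface} (the full utility surface with
#'   Monte Carlo standard errors and mean stopping times).
#' @export
optimizeBoundary <- function(trajset, util,
                             b0Grid = seq(0, 3 * util@c, length.out = 21L),
                             b1Grid = seq(-util@c, util@c,
                                          length.out = 21L)) {
    if (nrow(trajset@deltaTP) == 0L) stop("empty trajectory set")
    if (length(b0Grid) == 0L || length(b1Grid) == 0L)
        stop("empty boundary grid")
    grid <- expand.grid(b0 = unique(b0Grid), b1 = unique(b1Grid))
    res <- lapply(seq_len(nrow(grid)), function(i) {
        bu <- boundaryExpectedUtility(trajset,
                                      Boundary(grid$b0[i], grid$b1[i]), util)
        c(utility = bu$utility, se = bu$se, meanTau = bu$meanTau)
    })
    res <- do.call(rbind, res)
    surface <- cbind(grid, as.data.frame(res))
    imax <- which.max(surface$utility)
    tol <- surface$se[imax]
    optima <- surface[surface$utility >= surface$utility[imax] - tol, ,
                      drop = FALSE]
    rep_ <- optima[order(optima$meanTau, -optima$utility), ][1L, ]
    list(boundary = Boundary(rep_$b0, rep_$b1), optima = optima,
         surface = surface)
}

#' One monitoring step of a running experiment
#'
#' Estimates \eqn{\Delta_t(TP)} from the current data, compares it with the
#' boundary threshold \code{b0 + b1 * t} (or, at \code{t = T-1}, with the
#' myopic rule threshold \code{c}), and returns the stop/continue decision
#' together with everything that entered it.  At \code{t >= T} stopping is
#' forced.
#'
#' @inheritParams deltaTPOneStep
#' @param boundary a \code{\linkS4class{Boundary}}.
#' @param design a \code{\linkS4class{DesignSpec}}.
#' @return list with \code{decision} (\code{"continue"} or \code{"stop"}),
#'   \code{deltaTP}, \code{se}, \code{threshold}, \code{t}, \code{rule}, and
#'   \code{posterior} (the current \code{\linkS4class{PosteriorSummary}}).
#' @export
monitorStep <- function(batch, hyper, boundary, util = UtilityParams(),
                        design, m = 20L, seed = 1L, nGenes = NULL,
                        quadNodes = 64L) {
    t <- if (is.null(batch) || ncol(batch) == 0L) 0L else nBatches(batch)
    n <- if (is.null(batch) || ncol(batch) == 0L) nGenes else nGenes(batch)
    ss <- if (is.null(batch) || ncol(batch) == 0L)
        .emptySS(n, modelId(hyper)) else .ssForBatch(batch, hyper)
    ps <- bayesTerminalDecision(.vFromSS(ss, hyper, quadNodes),
                                util@fdrLevel)
    if (t >= design@T)
        return(list(decision = "stop", deltaTP = NA_real_, se = NA_real_,
                    threshold = NA_real_, t = t, rule = "horizon_forced",
                    posterior = ps))
    est <- deltaTPOneStep(batch, hyper, util,
                          batchPerGroup = design@batchPerGroup, m = m,
                          seed = seed, nGenes = nGenes,
                          quadNodes = quadNodes)
    if (t == design@T - 1L) {
        thr <- util@c
        rule <- "horizon_myopic"
    } else {
        thr <- boundary@b0 + boundary@b1 * t
        rule <- "boundary"
    }
    list(decision = if (est$estimate > thr) "continue" else "stop",
         deltaTP = est$estimate, se = est$se, threshold = thr, t = t,
         rule = rule, posterior = ps)
}
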