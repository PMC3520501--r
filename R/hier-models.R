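# Hierarchical mixture models for differential expression: the gamma-gamma
# (GaGa) model and the log-normal-normal (NN) model with generalized
# variance.  Conditional on the hyperparameters all per-gene quantities are
# closed form (NN, and GaGa given the shape) or deterministic 1-D quadrature
# (GaGa shape; NN variance when the mean prior does not scale with it).

# ---- quadrature -----------------------------------------------------------

# Gauss-Legendre nodes/weights on log(theta) covering the prior's
# [qlo, 1 - qlo] quantile range; returns theta nodes and log-weights that
# already include the prior density and the log-transform Jacobian.
.quadGrid <- function(qfun, dfunLog, nodes, qlo = 1e-4) {
    lo <- log(qfun(qlo))
    hi <- log(qfun(1 - qlo))
    gl <- pracma::gaussLegendre(nodes, lo, hi)
    theta <- exp(gl$x)
    list(theta = theta, logw = log(gl$w) + dfunLog(theta) + gl$x)
}

.gagaAlphaGrid <- function(hyper, nodes = 64L) {
    .quadGrid(function(p) qgamma(p, hyper@beta, rate = hyper@beta / hyper@mu),
              function(a) dgamma(a, hyper@beta, rate = hyper@beta / hyper@mu,
                                 log = TRUE),
              nodes)
}

# scaled-inverse-chi-square quantiles/density for the NN variance prior
.qsichisq <- function(p, nu0, s0sq) nu0 * s0sq / qchisq(1 - p, nu0)
.dsichisqLog <- function(x, nu0, s0sq) {
    (nu0 / 2) * log(nu0 * s0sq / 2) - lgamma(nu0 / 2) -
        (nu0 / 2 + 1) * log(x) - nu0 * s0sq / (2 * x)
}
.nnSigmaGrid <- function(hyper, nodes = 64L) {
    .quadGrid(function(p) .qsichisq(p, hyper@nu0, hyper@sigma0^2),
              function(x) .dsichisqLog(x, hyper@nu0, hyper@sigma0^2),
              nodes)
}

# ---- NN marginals ---------------------------------------------------------

# Log marginal densities (on the log-data scale) for all genes under both
# expression patterns.  Returns an n x 2 matrix, columns EE, DE.
.nnLogMargMat <- function(ss, hyper, quadNodes = 64L) {
    stopifnot(ss$model == "nn")
    if (hyper@scaledMeans)
        .nnLogMargScaled(ss, hyper)
    else
        .nnLogMargQuad(ss, hyper, quadNodes)
}

# Fully conjugate normal / scaled-inverse-chi-square algebra: integrating the
# group means (precision kappa0/sigma^2 around mu0) and then sigma^2 yields a
# multivariate-t marginal evaluated through its sufficient statistics.
.nnLogMargScaled <- function(ss, hyper) {
    k0 <- 1 / hyper@tau0^2
    nu0 <- hyper@nu0
    s0sq <- hyper@sigma0^2
    grpSS <- function(m, s, q) {
        if (m == 0L) return(list(SS = 0, hl = 0))
        mean <- s / m
        S <- pmax(q - s^2 / m, 0)
        list(SS = S + k0 * m * (mean - hyper@mu0)^2 / (k0 + m),
             hl = 0.5 * log(k0 / (k0 + m)))
    }
    lm_ <- function(m, SS, hl) {
        -m / 2 * log(2 * pi) + hl + lgamma((nu0 + m) / 2) -
            lgamma(nu0 / 2) + (nu0 / 2) * log(nu0 * s0sq / 2) -
            ((nu0 + m) / 2) * log((nu0 * s0sq + SS) / 2)
    }
    mP <- ss$m0 + ss$m1
    pooled <- grpSS(mP, ss$s0 + ss$s1, ss$q0 + ss$q1)
    g0 <- grpSS(ss$m0, ss$s0, ss$q0)
    g1 <- grpSS(ss$m1, ss$s1, ss$q1)
    cbind(EE = lm_(mP, pooled$SS, pooled$hl),
          DE = lm_(mP, g0$SS + g1$SS, g0$hl + g1$hl))
}

# Variance-independent mean prior: integrate the means in closed form given
# sigma^2, then sigma^2 by Gauss-Legendre quadrature against its prior.
.nnLogMargQuad <- function(ss, hyper, quadNodes = 64L) {
    grid <- .nnSigmaGrid(hyper, quadNodes)
    t0sq <- hyper@tau0^2
    grpTerm <- function(m, s, q, sig2) {
        # n x K matrix of log integrated-likelihood contributions
        if (m == 0L) return(0)
        mean <- s / m
        S <- pmax(q - s^2 / m, 0)
        -m / 2 * log(2 * pi) -
            0.5 * outer(rep(1, length(s)), (m - 1) * log(sig2) +
                            log(sig2 + m * t0sq)) -
            0.5 * (outer(S, 1 / sig2) +
                       outer(m * (mean - hyper@mu0)^2, 1 / (sig2 + m * t0sq)))
    }
    sig2 <- grid$theta
    mP <- ss$m0 + ss$m1
    ee <- grpTerm(mP, ss$s0 + ss$s1, ss$q0 + ss$q1, sig2)
    de <- grpTerm(ss$m0, ss$s0, ss$q0, sig2) +
        grpTerm(ss$m1, ss$s1, ss$q1, sig2)
    cbind(EE = .rowLogSumExpW(ee, grid$logw),
          DE = .rowLogSumExpW(de, grid$logw))
}

# ---- GaGa marginals -------------------------------------------------------

# Conditional on the shape alpha, the conjugate inverse-gamma prior on each
# group mean integrates in closed form; m observations with sum s and
# sum-of-logs p contribute, per group,
#   m*alpha*log(alpha) + (alpha-1)*p - m*lgamma(alpha)
#   + alpha0*log(alpha0/nu) - lgamma(alpha0)
#   + lgamma(m*alpha + alpha0) - (m*alpha + alpha0)*log(alpha*s + alpha0/nu)
# (the term vanishes for an empty group).  alpha is then integrated by
# fixed-node quadrature against its gamma prior.
.gagaLogMargGivenAlpha <- function(m, s, p, alpha, hyper) {
    if (m == 0L) return(0)
    a0 <- hyper@alpha0
    r <- a0 / hyper@nu
    t1 <- outer(p, alpha - 1) +
        rep(1, length(s)) %o% (m * alpha * log(alpha) - m * lgamma(alpha))
    t2 <- lgamma(outer(rep(m, length(s)), alpha) + a0) -
        (outer(rep(m, length(s)), alpha) + a0) * log(outer(s, alpha) + r)
    t1 + t2 + a0 * log(r) - lgamma(a0)
}

.gagaLogMargMat <- function(ss, hyper, quadNodes = 64L) {
    stopifnot(ss$model == "gaga")
    grid <- .gagaAlphaGrid(hyper, quadNodes)
    a <- grid$theta
    mP <- ss$m0 + ss$m1
    ee <- .gagaLogMargGivenAlpha(mP, ss$s0 + ss$s1, ss$q0 + ss$q1, a, hyper)
    de <- .gagaLogMargGivenAlpha(ss$m0, ss$s0, ss$q0, a, hyper) +
        .gagaLogMargGivenAlpha(ss$m1, ss$s1, ss$q1, a, hyper)
    out <- cbind(EE = .rowLogSumExpW(ee, grid$logw),
                 DE = .rowLogSumExpW(de, grid$logw))
    if (any(!is.finite(out)))
        stop("GaGa quadrature produced non-finite log marginals for gene(s) ",
             paste(utils::head(which(rowSums(!is.finite(out)) > 0), 5L),
                   collapse = ", "),
             " (alpha grid range ", signif(min(a), 3), "..",
             signif(max(a), 3), ")")
    out
}

.logMargMat <- function(ss, hyper, quadNodes = 64L) {
    if (ss$model == "nn") .nnLogMargMat(ss, hyper, quadNodes)
    else .gagaLogMargMat(ss, hyper, quadNodes)
}

.ssForBatch <- function(batch, hyper) {
    .suffStats(exprValues(batch), sampleGroups(batch), modelId(hyper))
}

# ---- exported single-gene marginal ----------------------------------------

.logMarginalOne <- function(hyper, x0, x1, pattern, quadNodes) {
    pattern <- match.arg(pattern, c("EE", "DE"))
    x0 <- as.numeric(x0); x1 <- as.numeric(x1)
    if (length(x0) + length(x1) == 0L)
        stop("at least one observation is required")
    values <- matrix(c(x0, x1), nrow = 1L)
    ss <- .suffStats(values, c(rep(0L, length(x0)), rep(1L, length(x1))),
                     modelId(hyper))
    unname(.logMargMat(ss, hyper, quadNodes)[1L, pattern])
}

#' @rdname logMarginal
#' @param quadNodes number of Gauss-Legendre nodes for the 1-D prior
#'   integrations (GaGa shape; NN variance when \code{scaledMeans = FALSE}).
#' @export
setMethod("logMarginal", "GaGaHyperParams",
          function(hyper, x0, x1, pattern = c("EE", "DE"), quadNodes = 64L)
              .logMarginalOne(hyper, x0, x1, pattern, quadNodes))

#' @rdname logMarginal
#' @export
setMethod("logMarginal", "NNHyperParams",
          function(hyper, x0, x1, pattern = c("EE", "DE"), quadNodes = 64L)
              .logMarginalOne(hyper, x0, x1, pattern, quadNodes))

# ---- posterior probability of differential expression ---------------------

.postDEProbFromLM <- function(lm_, pi) {
    if (pi <= 0) return(rep(0, nrow(lm_)))
    if (pi >= 1) return(rep(1, nrow(lm_)))
    lo <- log1p(-pi) - log(pi) + lm_[, "EE"] - lm_[, "DE"]
    1 / (1 + exp(pmin(lo, 700)))
}

#' Posterior probabilities of differential expression
#'
#' For every gene computes \eqn{v_i = P(\delta_i = 1 | x)} by combining the
#' EE and DE marginal likelihoods with the prior weight \eqn{\pi} in stable
#' log arithmetic.
#'
#' @param batch an \code{\linkS4class{ExpressionBatch}}.
#' @param hyper a \code{\linkS4class{HyperParams}} (selects the model).
#' @param quadNodes quadrature nodes, see \code{\link{logMarginal}}.
#' @return numeric vector of length \code{nGenes(batch)}, named by gene.
#' @examples
#' hyp <- NNHyperParams(mu0 = 7, tau0 = 1, nu0 = 6, sigma0 = 0.6, pi = 0.05)
#' sim <- sampleFromPrior(hyp, n = 50, samplesPerGroup = c(4, 4), seed = 1)
#' v <- posteriorDEProb(sim@batch, hyp)
#' @export
posteriorDEProb <- function(batch, hyper, quadNodes = 64L) {
    ss <- .ssForBatch(batch, hyper)
    lm_ <- .logMargMat(ss, hyper, quadNodes)
    bad <- which(!is.finite(lm_[, 1L]) | !is.finite(lm_[, 2L]))
    if (length(bad))
        stop("non-finite marginal likelihood for gene(s): ",
             paste(utils::head(geneIds(batch)[bad], 5L), collapse = ", "))
    setNames(.postDEProbFromLM(lm_, hyper@pi), geneIds(batch))
}

# ---- empirical-Bayes fitting ----------------------------------------------

.hyperToPar <- function(hyper) {
    if (is(hyper, "NNHyperParams"))
        c(hyper@mu0, log(hyper@tau0), log(hyper@nu0), log(hyper@sigma0))
    else
        log(c(hyper@alpha0, hyper@nu, hyper@beta, hyper@mu))
}

.parToHyper <- function(par, hyper) {
    if (is(hyper, "NNHyperParams"))
        NNHyperParams(par[1], exp(par[2]), exp(par[3]), exp(par[4]),
                      hyper@pi, hyper@scaledMeans)
    else
        GaGaHyperParams(exp(par[1]), exp(par[2]), exp(par[3]), exp(par[4]),
                        hyper@pi)
}

.mixLogLik <- function(lm_, pi) {
    if (pi <= 0) return(sum(lm_[, "EE"]))
    if (pi >= 1) return(sum(lm_[, "DE"]))
    a <- log(pi) + lm_[, "DE"]
    b <- log1p(-pi) + lm_[, "EE"]
    m <- pmax(a, b)
    sum(m + log(exp(a - m) + exp(b - m)))
}

.momentInit <- function(ss, model, scaledMeans = TRUE) {
    if (model == "nn") {
        mP <- ss$m0 + ss$m1
        gm <- (ss$s0 + ss$s1) / mP
        # pooled within-group variance (falls back to total when a group
        # has < 2 samples)
        Sw <- pmax(ss$q0 - ss$s0^2 / max(ss$m0, 1), 0) +
            pmax(ss$q1 - ss$s1^2 / max(ss$m1, 1), 0)
        dfw <- max(ss$m0 - 1, 0) + max(ss$m1 - 1, 0)
        gv <- if (dfw > 0) Sw / dfw else
            pmax((ss$q0 + ss$q1) - mP * gm^2, 1e-6) / max(mP - 1, 1)
        gv <- pmax(gv, 1e-6)
        s2bar <- mean(gv)
        tau0 <- sqrt(max(var(gm) - s2bar / mP, 1e-4) /
                         if (scaledMeans) s2bar else 1)
        NNHyperParams(mu0 = mean(gm), tau0 = tau0, nu0 = 4,
                      sigma0 = sqrt(stats::median(gv)), pi = 0.1,
                      scaledMeans = scaledMeans)
    } else {
        mP <- ss$m0 + ss$m1
        gmean <- (ss$s0 + ss$s1) / mP
        # E(log x) - log E(x) = digamma(alpha) - log(alpha) per gene
        gap <- pmin((ss$q0 + ss$q1) / mP - log(gmean), -1e-4)
        ahat <- vapply(gap, function(g) {
            f <- function(a) digamma(a) - log(a) - g
            exp(stats::uniroot(function(u) f(exp(u)), c(-5, 12))$root)
        }, numeric(1))
        mu <- stats::median(ahat)
        beta <- max(mu^2 / max(var(ahat), 1e-8), 0.2)
        alpha0 <- 2.5
        nu <- alpha0 / ((alpha0 - 1) * mean(gmean))
        GaGaHyperParams(alpha0 = alpha0, nu = nu, beta = min(beta, 50),
                        mu = mu, pi = 0.1)
    }
}

#' Empirical-Bayes hyperparameter estimation by expectation-maximization
#'
#' Maximizes the marginal likelihood \eqn{\sum_i \log[\pi m_{DE}(x_i) +
#' (1-\pi) m_{EE}(x_i)]} treating the per-gene indicators \eqn{\delta_i} as
#' missing data.  The E-step computes the current posterior probabilities
#' \eqn{v_i}; the M-step updates \eqn{\pi} in closed form as their mean and
#' improves the remaining hyperparameters by bounded numerical optimization
#' on a log scale (a generalized EM step, so the marginal log-likelihood is
#' non-decreasing).  Deterministic given the data and control settings.
#'
#' @param batch an \code{\linkS4class{ExpressionBatch}} with at least two
#'   samples per group.
#' @param model \code{"nn"} or \code{"gaga"}.
#' @param init optional starting \code{\linkS4class{HyperParams}}; defaults
#'   to method-of-moments values.
#' @param control list: \code{maxit} (EM iterations, 200), \code{tol}
#'   (relative log-likelihood change, 1e-6), \code{mstepMaxit} (inner
#'   optimizer iterations, 60), \code{quadNodes} (64), \code{minGenes}
#'   (minimum number of genes, 50), \code{scaledMeans} (NN variant, TRUE).
#' @return the fitted \code{\linkS4class{HyperParams}}, with attributes
#'   \code{logLik} (final marginal log-likelihood), \code{iterations},
#'   \code{converged}, and \code{trace} (log-likelihood per iteration).
#' @examples
#' hyp <- NNHyperParams(7, 1, 6, 0.6, pi = 0.1)
#' sim <- sampleFromPrior(hyp, n = 200, samplesPerGroup = c(6, 6), seed = 2)
#' fit <- fitHyperParams(sim@batch, "nn", control = list(maxit = 20))
#' attr(fit, "logLik")
#' @export
fitHyperParams <- function(batch, model = c("nn", "gaga"), init = NULL,
                           control = list()) {
    model <- match.arg(model)
    ctl <- utils::modifyList(list(maxit = 200L, tol = 1e-6,
                                  mstepMaxit = 60L, quadNodes = 64L,
                                  minGenes = 50L, scaledMeans = TRUE),
                             control)
    vals <- exprValues(batch)
    if (any(!is.finite(vals)))
        stop("fit excludes non-finite values; found non-finite entries in ",
             "gene(s): ",
             paste(utils::head(rownames(vals)[rowSums(!is.finite(vals)) > 0],
                               5L), collapse = ", "))
    grp <- sampleGroups(batch)
    if (sum(grp == 0L) < 2L || sum(grp == 1L) < 2L)
        stop("at least 2 samples per group are required to fit ",
             "hyperparameters")
    if (nrow(vals) < ctl$minGenes)
        stop("at least ", ctl$minGenes, " genes are required for a stable ",
             "fit (got ", nrow(vals), ")")
    cst <- which(apply(vals, 1L, function(r) max(r) == min(r)))
    if (length(cst))
        stop("degenerate (constant) gene(s): ",
             paste(utils::head(rownames(vals)[cst], 5L), collapse = ", "))
    ss <- .suffStats(vals, grp, model)
    hyper <- if (is.null(init)) .momentInit(ss, model, ctl$scaledMeans)
             else init
    lm_ <- .logMargMat(ss, hyper, ctl$quadNodes)
    ll <- .mixLogLik(lm_, hyper@pi)
    trace <- ll
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(ctl$maxit)) {
        v <- .postDEProbFromLM(lm_, hyper@pi)
        # closed-form pi update, kept off the boundary for stability
        piNew <- min(max(mean(v), 1e-6), 1 - 1e-6)
        qfun <- function(par) {
            h <- .parToHyper(par, hyper)
            lmq <- tryCatch(.logMargMat(ss, h, ctl$quadNodes),
                            error = function(e) NULL)
            if (is.null(lmq)) return(1e10)
            -sum(v * lmq[, "DE"] + (1 - v) * lmq[, "EE"])
        }
        par0 <- .hyperToPar(hyper)
        opt <- stats::optim(par0, qfun, method = "Nelder-Mead",
                            control = list(maxit = ctl$mstepMaxit))
        # generalized EM: only accept an improving M-step
        hyperNew <- if (opt$value < qfun(par0)) .parToHyper(opt$par, hyper)
                    else hyper
        hyperNew@pi <- piNew
        lmNew <- .logMargMat(ss, hyperNew, ctl$quadNodes)
        llNew <- .mixLogLik(lmNew, piNew)
        if (llNew + 1e-9 * abs(ll) < ll) {
            # defensive: keep the previous iterate if numerics misbehave
            break
        }
        improved <- (llNew - ll) > ctl$tol * abs(ll)
        hyper <- hyperNew
        lm_ <- lmNew
        ll <- llNew
        trace <- c(trace, ll)
        if (!improved) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("EM did not meet the convergence tolerance within ",
                ctl$maxit, " iterations; returning the best iterate")
    attr(hyper, "logLik") <- ll
    attr(hyper, "iterations") <- iter
    attr(hyper, "converged") <- converged
    attr(hyper, "trace") <- trace
    hyper
}

#' Profile-likelihood adjustment of the prior DE probability
#'
#' Moment-based fits of the NN model can overestimate the proportion of
#' differentially expressed genes.  This replaces \eqn{\pi} by the maximizer
#' of the profile marginal likelihood in \eqn{\pi}, holding all other
#' hyperparameters fixed.
#'
#' @param batch an \code{\linkS4class{ExpressionBatch}}.
#' @param hyper a fitted \code{\linkS4class{HyperParams}}.
#' @param quadNodes quadrature nodes.
#' @return \code{hyper} with the adjusted \code{pi}.
#' @export
adjustPi <- function(batch, hyper, quadNodes = 64L) {
    ss <- .ssForBatch(batch, hyper)
    lm_ <- .logMargMat(ss, hyper, quadNodes)
    f <- function(p) .mixLogLik(lm_, p)
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-7)
    cand <- c(opt$maximum, 0, 1)
    best <- cand[which.max(vapply(cand, f, numeric(1)))]
    priorDEProb(hyper) <- best
    hyper
}

# ---- simulation from prior and posterior ----------------------------------

# Draw per-gene truth from the hierarchical prior, with deProb the
# per-gene probability of delta_i = 1 (the prior pi, or posterior v_i).
.drawTheta <- function(hyper, deProb) {
    n <- length(deProb)
    delta <- rbinom(n, 1L, deProb)
    if (is(hyper, "NNHyperParams")) {
        sig2 <- hyper@nu0 * hyper@sigma0^2 / rchisq(n, hyper@nu0)
        sdm <- if (hyper@scaledMeans) hyper@tau0 * sqrt(sig2) else
            rep(hyper@tau0, n)
        m0 <- rnorm(n, hyper@mu0, sdm)
        m1a <- rnorm(n, hyper@mu0, sdm)
        m1 <- ifelse(delta == 1L, m1a, m0)
        new("GeneParams", delta = as.integer(delta), mean0 = m0, mean1 = m1,
            shapeOrVar = sig2)
    } else {
        alpha <- rgamma(n, hyper@beta, rate = hyper@beta / hyper@mu)
        l0 <- 1 / rgamma(n, hyper@alpha0, rate = hyper@alpha0 / hyper@nu)
        l1a <- 1 / rgamma(n, hyper@alpha0, rate = hyper@alpha0 / hyper@nu)
        l1 <- ifelse(delta == 1L, l1a, l0)
        new("GeneParams", delta = as.integer(delta), mean0 = l0, mean1 = l1,
            shapeOrVar = alpha)
    }
}

# Generate expression columns given per-gene parameters.  Samples are laid
# out batch by batch, group 0 before group 1 within each batch.
.drawData <- function(theta, hyper, samplesPerGroup, nBatches = 1L,
                      firstBatch = 1L) {
    per <- samplesPerGroup / nBatches
    if (any(per != floor(per)))
        stop("samplesPerGroup must be divisible by nBatches")
    n <- length(theta@delta)
    nn <- is(hyper, "NNHyperParams")
    cols <- vector("list", nBatches)
    for (b in seq_len(nBatches)) {
        draw <- function(m, meanvec) {
            if (m == 0L) return(NULL)
            if (nn)
                matrix(exp(rnorm(n * m, mean = rep(meanvec, m),
                                 sd = rep(sqrt(theta@shapeOrVar), m))),
                       nrow = n)
            else
                matrix(rgamma(n * m, shape = rep(theta@shapeOrVar, m),
                              rate = rep(theta@shapeOrVar / meanvec, m)),
                       nrow = n)
        }
        x0 <- draw(per[1], theta@mean0)
        x1 <- draw(per[2], theta@mean1)
        cols[[b]] <- list(x0 = x0, x1 = x1)
    }
    values <- do.call(cbind, lapply(cols, function(cc) cbind(cc$x0, cc$x1)))
    groups <- rep(rep(c(0L, 1L), per), nBatches)
    batches <- rep(seq(firstBatch, length.out = nBatches), each = sum(per))
    list(values = values, groups = groups, batches = batches)
}

.sampleFromPriorImpl <- function(hyper, n, samplesPerGroup, nBatches, seed) {
    if (n < 1L) stop("n must be >= 1")
    samplesPerGroup <- rep(as.integer(samplesPerGroup), length.out = 2L)
    if (sum(samplesPerGroup) < 1L)
        stop("at least one sample is required")
    if (!is.null(seed)) set.seed(seed)
    theta <- .drawTheta(hyper, rep(hyper@pi, n))
    d <- .drawData(theta, hyper, samplesPerGroup, nBatches)
    batch <- ExpressionBatch(d$values, d$groups, d$batches,
                             geneIds = paste0("gene", seq_len(n)))
    new("SyntheticDataset", batch = batch, truth = theta,
        generatingHyper = hyper)
}

#' @rdname sampleFromPrior
#' @export
setMethod("sampleFromPrior", "HyperParams",
          function(hyper, n, samplesPerGroup, nBatches = 1L, seed = NULL, ...)
              .sampleFromPriorImpl(hyper, n, samplesPerGroup,
                                   as.integer(nBatches), seed))

# Posterior draw of per-gene parameters given data and drawn delta.
.drawThetaPosterior <- function(hyper, ss, delta, quadNodes = 64L) {
    n <- ss$n
    if (is(hyper, "NNHyperParams") && hyper@scaledMeans) {
        k0 <- 1 / hyper@tau0^2
        nu0 <- hyper@nu0; s0sq <- hyper@sigma0^2; mu0 <- hyper@mu0
        grp <- function(m, s, q) {
            if (m == 0L)
                return(list(SS = numeric(n), mun = rep(mu0, n),
                            kn = rep(k0, n), m = 0L))
            mean <- s / m
            S <- pmax(q - s^2 / m, 0)
            list(SS = S + k0 * m * (mean - mu0)^2 / (k0 + m),
                 mun = (k0 * mu0 + s) / (k0 + m), kn = rep(k0 + m, n), m = m)
        }
        g0 <- grp(ss$m0, ss$s0, ss$q0)
        g1 <- grp(ss$m1, ss$s1, ss$q1)
        gp <- grp(ss$m0 + ss$m1, ss$s0 + ss$s1, ss$q0 + ss$q1)
        de <- delta == 1L
        nun <- ifelse(de, nu0 + ss$m0 + ss$m1, nu0 + ss$m0 + ss$m1)
        scl <- ifelse(de, nu0 * s0sq + g0$SS + g1$SS, nu0 * s0sq + gp$SS)
        sig2 <- scl / rchisq(n, nun)
        m0d <- rnorm(n, g0$mun, sqrt(sig2 / g0$kn))
        m1d <- rnorm(n, g1$mun, sqrt(sig2 / g1$kn))
        mp <- rnorm(n, gp$mun, sqrt(sig2 / gp$kn))
        mean0 <- ifelse(de, m0d, mp)
        mean1 <- ifelse(de, m1d, mp)
        new("GeneParams", delta = as.integer(delta), mean0 = mean0,
            mean1 = mean1, shapeOrVar = sig2)
    } else if (is(hyper, "NNHyperParams")) {
        # variance-independent mean prior: sample sigma^2 on the quadrature
        # grid from its (pattern-conditional) posterior, then means given it
        grid <- .nnSigmaGrid(hyper, quadNodes)
        sig2g <- grid$theta
        t0sq <- hyper@tau0^2; mu0 <- hyper@mu0
        lik <- function(m, s, q) {
            if (m == 0L) return(matrix(0, n, length(sig2g)))
            mean <- s / m
            S <- pmax(q - s^2 / m, 0)
            -0.5 * outer(rep(1, n), (m - 1) * log(sig2g) +
                             log(sig2g + m * t0sq)) -
                0.5 * (outer(S, 1 / sig2g) +
                           outer(m * (mean - mu0)^2, 1 / (sig2g + m * t0sq)))
        }
        lwDE <- lik(ss$m0, ss$s0, ss$q0) + lik(ss$m1, ss$s1, ss$q1)
        lwEE <- lik(ss$m0 + ss$m1, ss$s0 + ss$s1, ss$q0 + ss$q1)
        lw <- sweep(ifelse(matrix(delta == 1L, n, length(sig2g)), lwDE, lwEE),
                    2L, grid$logw, "+")
        idx <- .sampleRowIndex(lw)
        sig2 <- sig2g[idx]
        postMean <- function(m, s, sig2) {
            prec <- m / sig2 + 1 / t0sq
            list(mean = (s / sig2 + mu0 / t0sq) / prec, sd = sqrt(1 / prec))
        }
        de <- delta == 1L
        p0 <- postMean(ss$m0, ss$s0, sig2)
        p1 <- postMean(ss$m1, ss$s1, sig2)
        pp <- postMean(ss$m0 + ss$m1, ss$s0 + ss$s1, sig2)
        m0d <- rnorm(n, p0$mean, p0$sd)
        m1d <- rnorm(n, p1$mean, p1$sd)
        mpd <- rnorm(n, pp$mean, pp$sd)
        new("GeneParams", delta = as.integer(delta),
            mean0 = ifelse(de, m0d, mpd), mean1 = ifelse(de, m1d, mpd),
            shapeOrVar = sig2)
    } else {
        # GaGa: discrete posterior for alpha on the quadrature grid, then
        # conjugate inverse-gamma draws for the group means
        grid <- .gagaAlphaGrid(hyper, quadNodes)
        a <- grid$theta
        lwDE <- .gagaLogMargGivenAlpha(ss$m0, ss$s0, ss$q0, a, hyper) +
            .gagaLogMargGivenAlpha(ss$m1, ss$s1, ss$q1, a, hyper)
        lwEE <- .gagaLogMargGivenAlpha(ss$m0 + ss$m1, ss$s0 + ss$s1,
                                       ss$q0 + ss$q1, a, hyper)
        if (is.null(dim(lwDE))) lwDE <- matrix(lwDE, ss$n, length(a))
        if (is.null(dim(lwEE))) lwEE <- matrix(lwEE, ss$n, length(a))
        lw <- sweep(ifelse(matrix(delta == 1L, ss$n, length(a)), lwDE, lwEE),
                    2L, grid$logw, "+")
        alpha <- a[.sampleRowIndex(lw)]
        a0 <- hyper@alpha0; r <- a0 / hyper@nu
        de <- delta == 1L
        l0d <- 1 / rgamma(ss$n, a0 + ss$m0 * alpha, rate = r + alpha * ss$s0)
        l1d <- 1 / rgamma(ss$n, a0 + ss$m1 * alpha, rate = r + alpha * ss$s1)
        lpd <- 1 / rgamma(ss$n, a0 + (ss$m0 + ss$m1) * alpha,
                          rate = r + alpha * (ss$s0 + ss$s1))
        new("GeneParams", delta = as.integer(delta),
            mean0 = ifelse(de, l0d, lpd), mean1 = ifelse(de, l1d, lpd),
            shapeOrVar = alpha)
    }
}

# sample one column index per row of a matrix of log-weights
.sampleRowIndex <- function(lw) {
    m <- apply(lw, 1L, max)
    w <- exp(lw - m)
    cw <- t(apply(w, 1L, cumsum))
    u <- runif(nrow(lw)) * cw[, ncol(cw)]
    max.col(cw >= u, ties.method = "first")
}

#' Simulate future samples from the posterior predictive distribution
#'
#' Composition sampling: per gene draw \eqn{\delta_i} from its posterior
#' probability \eqn{v_i}, then the gene-level parameters from their
#' conditional posterior given \eqn{\delta_i} and the data, then new
#' observations from the sampling model.  With an empty batch (no data, t =
#' 0) this reduces exactly to \code{\link{sampleFromPrior}}: the same seed
#' yields the same draws.
#'
#' @param batch current data as an \code{\linkS4class{ExpressionBatch}}, or
#'   \code{NULL} for no data (then \code{nGenes} must be given).
#' @param hyper analysis \code{\linkS4class{HyperParams}}.
#' @param newSamplesPerGroup samples per group to simulate (length 2).
#' @param nNewBatches how many batches they form.
#' @param seed integer seed.
#' @param nGenes gene count when \code{batch} is \code{NULL}.
#' @param quadNodes quadrature nodes.
#' @return list with elements \code{batch} (an \code{ExpressionBatch} of the
#'   new samples only, batch indices numbered from 1), \code{theta} (the
#'   drawn \code{\linkS4class{GeneParams}}), and \code{v} (the posterior DE
#'   probabilities used).
#' @export
samplePosteriorPredictive <- function(batch, hyper, newSamplesPerGroup,
                                      nNewBatches = 1L, seed = NULL,
                                      nGenes = NULL, quadNodes = 64L) {
    newSamplesPerGroup <- rep(as.integer(newSamplesPerGroup),
                              length.out = 2L)
    empty <- is.null(batch) || ncol(batch) == 0L
    if (empty && is.null(nGenes))
        stop("nGenes is required when no data are supplied")
    if (!empty && !is.null(nGenes) && nGenes != nGenes(batch))
        stop("mismatched gene dimension: nGenes = ", nGenes, " but batch has ",
             nGenes(batch), " genes")
    if (!is.null(seed)) set.seed(seed)
    if (empty) {
        n <- as.integer(nGenes)
        v <- rep(hyper@pi, n)
        theta <- .drawTheta(hyper, v)
        ids <- paste0("gene", seq_len(n))
    } else {
        ss <- .ssForBatch(batch, hyper)
        lm_ <- .logMargMat(ss, hyper, quadNodes)
        v <- .postDEProbFromLM(lm_, hyper@pi)
        delta <- rbinom(ss$n, 1L, v)
        theta <- .drawThetaPosterior(hyper, ss, delta, quadNodes)
        ids <- geneIds(batch)
    }
    d <- .drawData(theta, hyper, newSamplesPerGroup,
                   as.integer(nNewBatches), firstBatch = 1L)
    nb <- ExpressionBatch(d$values, d$groups, d$batches, geneIds = ids)
    list(batch = nb, theta = theta, v = v)
}
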