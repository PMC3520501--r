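# Independent brute-force oracles used to validate the closed-form /
# quadrature implementations.  These deliberately share no code with the
# package internals: plain grid quadrature on wide quantile ranges, and
# exhaustive enumeration for the decision rules.

# log marginal for one gene under the NN model by 2-D grid quadrature over
# (group means, variance); means integrated per group on a grid given each
# variance grid point.
oracleLogMarginalNN <- function(hyp, x0, x1, pattern,
                                nSig = 400L, nMu = 600L) {
    mu0 <- hyp@mu0; tau0 <- hyp@tau0; nu0 <- hyp@nu0
    s0sq <- hyp@sigma0^2
    scaled <- hyp@scaledMeans
    qs <- nu0 * s0sq / qchisq(1 - c(1e-7, 1 - 1e-7), nu0)
    sig2 <- exp(seq(log(qs[1]), log(qs[2]), length.out = nSig))
    dsig <- exp((nu0 / 2) * log(nu0 * s0sq / 2) - lgamma(nu0 / 2) -
                    (nu0 / 2 + 1) * log(sig2) - nu0 * s0sq / (2 * sig2))
    groupLik <- function(y) {
        # matrix over (mu grid, sig2 grid) of exp(loglik + log prior(mu))
        vapply(seq_along(sig2), function(j) {
            s2 <- sig2[j]
            sdm <- if (scaled) tau0 * sqrt(s2) else tau0
            mus <- seq(mu0 - 10 * sdm, mu0 + 10 * sdm, length.out = nMu)
            ll <- -length(y) / 2 * log(2 * pi * s2) -
                vapply(mus, function(m) sum((y - m)^2), numeric(1)) /
                (2 * s2) + dnorm(mus, mu0, sdm, log = TRUE)
            pracma::trapz(mus, exp(ll))
        }, numeric(1))
    }
    y0 <- log(x0); y1 <- log(x1)
    inner <- if (pattern == "EE") groupLik(c(y0, y1)) else {
        i0 <- if (length(y0)) groupLik(y0) else 1
        i1 <- if (length(y1)) groupLik(y1) else 1
        i0 * i1
    }
    log(pracma::trapz(sig2, inner * dsig))
}

# log marginal for one gene under the GaGa model by 2-D grid quadrature over
# (group means lambda, shape alpha).
oracleLogMarginalGaGa <- function(hyp, x0, x1, pattern,
                                  nA = 400L, nL = 600L) {
    a0 <- hyp@alpha0; nu <- hyp@nu; beta <- hyp@beta; mu <- hyp@mu
    aa <- exp(seq(log(qgamma(1e-7, beta, rate = beta / mu)),
                  log(qgamma(1 - 1e-7, beta, rate = beta / mu)),
                  length.out = nA))
    da <- dgamma(aa, beta, rate = beta / mu)
    lq <- 1 / qgamma(c(1 - 1e-8, 1e-8), a0, rate = a0 / nu)
    ll <- exp(seq(log(lq[1]), log(lq[2]), length.out = nL))
    dl <- exp(a0 * log(a0 / nu) - lgamma(a0) - (a0 + 1) * log(ll) -
                  (a0 / nu) / ll)
    groupLik <- function(x) {
        if (!length(x)) return(rep(1, length(aa)))
        m <- length(x); s <- sum(x); p <- sum(log(x))
        # (lambda grid) x (alpha grid) log-likelihood
        lmat <- outer(-m * log(ll), m * aa * log(aa) + (aa - 1) * p -
                          m * lgamma(aa), function(a, b) b) +
            outer(log(ll), aa, function(l, a) -m * a * l) -
            outer(1 / ll, aa * s)
        vapply(seq_along(aa), function(j)
            pracma::trapz(ll, exp(lmat[, j]) * dl), numeric(1))
    }
    inner <- if (pattern == "EE") groupLik(c(x0, x1))
             else groupLik(x0) * groupLik(x1)
    log(pracma::trapz(aa, inner * da))
}

# exhaustive search over all 2^n decision vectors: maximize the number of
# positives subject to posterior expected FDR <= level; among those, the
# best expected-TP value.
bruteForceDecision <- function(v, level) {
    n <- length(v)
    bestD <- 0L
    bestETP <- 0
    for (mask in 0:(2^n - 1)) {
        sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
        D <- sum(sel)
        if (D == 0L) next
        if (sum((1 - v)[sel]) / D <= level + 1e-12) {
            etp <- sum(v[sel])
            if (D > bestD || (D == bestD && etp > bestETP)) {
                bestD <- D
                bestETP <- etp
            }
        }
    }
    list(D = bestD, expectedTP = bestETP)
}

# straightforward loop implementation of the stopping rule
oracleStoppingTime <- function(deltaPath, b0, b1, cc, t0, T) {
    ks <- t0:(T - 1L)
    for (i in seq_along(ks)) {
        k <- ks[i]
        if (k < T - 1L) {
            if (deltaPath[i] <= b0 + b1 * k) return(k)
        } else {
            if (deltaPath[i] - cc <= 0) return(k)
        }
    }
    T
}

# independent grid-search boundary optimizer over a TrajectorySet
oracleBoundaryOpt <- function(trajset, b0s, b1s, cc) {
    t0 <- trajset@t0
    T <- t0 + ncol(trajset@deltaTP)
    B <- nrow(trajset@deltaTP)
    best <- -Inf; bestb <- NULL
    surface <- NULL
    for (b0 in b0s) for (b1 in b1s) {
        us <- vapply(seq_len(B), function(j) {
            tau <- oracleStoppingTime(trajset@deltaTP[j, ], b0, b1, cc,
                                      t0, T)
            trajset@expectedTPAt[j, tau - t0 + 1L] - cc * tau
        }, numeric(1))
        u <- mean(us)
        surface <- rbind(surface, data.frame(b0 = b0, b1 = b1, utility = u))
        if (u > best) { best <- u; bestb <- c(b0, b1) }
    }
    list(utility = best, boundary = bestb, surface = surface)
}

# expected TP of the FDR-controlling rule for exactly two genes
etpTwoGenes <- function(p, q, level) {
    hi <- pmax(p, q); lo <- pmin(p, q)
    both <- (1 - (hi + lo) / 2) <= level
    one <- (1 - hi) <= level
    ifelse(both, hi + lo, ifelse(one, hi, 0))
}

# Exhaustive fine-grid integration of the one-step-ahead expected gain in
# TP for a two-gene NN toy with one new sample per group.  This oracle
# replaces deltaTPOneStep's Monte Carlo over the posterior predictive by a
# deterministic 2-D grid integration per gene (the marginal likelihoods
# themselves are validated against grid quadrature separately); it shares no
# sampling code with the engine.
oracleDeltaTPTwoGene <- function(hyp, batch, level, nGrid = 61L) {
    stopifnot(nGenes(batch) == 2L)
    vals <- exprValues(batch)
    grp <- sampleGroups(batch)
    pi0 <- hyp@pi
    vOf <- function(mEE, mDE)
        1 / (1 + exp(log(1 - pi0) - log(pi0) + mEE - mDE))
    v <- numeric(2); etpGrid <- list(); wGrid <- list()
    for (i in 1:2) {
        x0 <- vals[i, grp == 0L]; x1 <- vals[i, grp == 1L]
        mEE <- logMarginal(hyp, x0, x1, "EE")
        mDE <- logMarginal(hyp, x0, x1, "DE")
        v[i] <- vOf(mEE, mDE)
        den <- log(pi0 * exp(mDE) + (1 - pi0) * exp(mEE))
        ctr <- mean(log(c(x0, x1)))
        span <- 6 * sqrt(hyp@nu0 * hyp@sigma0^2 / (hyp@nu0 - 2)) *
            sqrt(1 + hyp@tau0^2)
        gy <- seq(ctr - span, ctr + span, length.out = nGrid)
        newv <- logpred <- matrix(NA_real_, nGrid, nGrid)
        for (a in seq_len(nGrid)) for (b in seq_len(nGrid)) {
            nx0 <- c(x0, exp(gy[a])); nx1 <- c(x1, exp(gy[b]))
            aEE <- logMarginal(hyp, nx0, nx1, "EE")
            aDE <- logMarginal(hyp, nx0, nx1, "DE")
            logpred[a, b] <- log(pi0 * exp(aDE) +
                                     (1 - pi0) * exp(aEE)) - den
            newv[a, b] <- vOf(aEE, aDE)
        }
        dy <- gy[2] - gy[1]
        w <- exp(logpred) * dy * dy
        w <- w / sum(w)   # renormalize the truncated grid
        wGrid[[i]] <- as.vector(w)
        etpGrid[[i]] <- as.vector(newv)
    }
    etpNow <- etpTwoGenes(v[1], v[2], level)
    vv <- expand.grid(v1 = etpGrid[[1]], v2 = etpGrid[[2]])
    ww <- outer(wGrid[[1]], wGrid[[2]])
    etpAfter <- sum(etpTwoGenes(vv$v1, vv$v2, level) * as.vector(ww))
    etpAfter - etpNow
}
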