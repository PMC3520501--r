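# Terminal decisions controlling the posterior expected FDR, and the
# utility calculus built on them.

#' Bayes terminal decision controlling the posterior expected FDR
#'
#' Ranks genes by their posterior probability of differential expression and
#' reports the largest prefix whose running mean of \eqn{1 - v_i} stays at or
#' below \code{fdrLevel}.  Genes tied in \eqn{v} share a fate: a tied block
#' enters only whole, and only if the constraint still holds.  With no
#' admissible gene, \code{D = 0} and the posterior expected FDR is defined
#' as 0.
#'
#' @param v numeric vector of posterior DE probabilities in [0, 1].
#' @param fdrLevel target posterior expected FDR level, default 0.05.
#' @return a \code{\linkS4class{PosteriorSummary}}.
#' @examples
#' bayesTerminalDecision(c(0.99, 0.98, 0.50), 0.05)
#' @export
bayesTerminalDecision <- function(v, fdrLevel = 0.05) {
    if (anyNA(v) || any(v < 0 | v > 1))
        stop("v must lie in [0, 1]")
    if (fdrLevel <= 0 || fdrLevel > 1)
        stop("fdrLevel must lie in (0, 1]")
    n <- length(v)
    d <- integer(n)
    if (n > 0L) {
        ord <- order(-v, seq_len(n))
        vs <- v[ord]
        cm <- cumsum(1 - vs) / seq_len(n)
        # block-complete prefixes: positions where the next value differs
        blockEnd <- c(vs[-n] != vs[-1L], TRUE)
        ok <- which(cm <= fdrLevel & blockEnd)
        D <- if (length(ok)) max(ok) else 0L
        if (D > 0L) d[ord[seq_len(D)]] <- 1L
    } else {
        D <- 0L
    }
    fdr <- posteriorExpectedFDR(v, d)
    new("PosteriorSummary", v = as.numeric(v), d = d,
        fdrLevel = as.numeric(fdrLevel), posteriorFDR = fdr,
        expectedTP = expectedTruePositives(v, d), D = sum(d))
}

#' Posterior expected false discovery rate of a decision vector
#'
#' \eqn{\sum_i (1 - v_i) d_i / \max(D, 1)} with \eqn{D = \sum_i d_i}; defined
#' as 0 when nothing is flagged.
#'
#' @param v posterior DE probabilities.
#' @param d 0/1 decision vector of the same length.
#' @export
posteriorExpectedFDR <- function(v, d) {
    if (length(v) != length(d))
        stop("v and d must have equal length")
    D <- sum(d)
    if (D == 0) return(0)
    sum((1 - v) * d) / D
}

#' Posterior expected number of true positives
#'
#' \eqn{\sum_i d_i v_i}: the posterior expectation of the number of correctly
#' flagged genes, with the decision vector held fixed (the expectation is
#' over the latent indicators only).
#'
#' @inheritParams posteriorExpectedFDR
#' @export
expectedTruePositives <- function(v, d) {
    if (length(v) != length(d))
        stop("v and d must have equal length")
    sum(v * d)
}

#' Posterior expected terminal utility
#'
#' Expected true positives minus the sampling cost of the batches used:
#' \eqn{\sum_i d_i v_i - c \, t}.
#'
#' @inheritParams posteriorExpectedFDR
#' @param util a \code{\linkS4class{UtilityParams}}.
#' @param t number of batches used, \code{>= 0}.
#' @export
expectedTerminalUtility <- function(v, d, util, t) {
    if (t < 0) stop("t must be non-negative")
    expectedTruePositives(v, d) - util@c * t
}
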