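#' @import methods
#' @importFrom stats dgamma qgamma rgamma rchisq rnorm rbinom runif sd var
#'   optim optimize setNames qchisq quantile dnorm rlnorm
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Expression data collected in batches
#'
#' \code{ExpressionBatch} holds a genes-by-samples expression matrix together
#' with a two-group sample label and a batch (accrual step) index per sample.
#' It extends \link[SummarizedExperiment]{SummarizedExperiment}: the matrix is
#' the single assay \code{"exprs"}, and \code{colData} carries the columns
#' \code{group} (0/1) and \code{batch} (1, 2, ...).
#'
#' Batches are the unit of sequential accrual: batch \code{t} contains the
#' samples added at step \code{t}, and analyses of "the first \code{t}
#' batches" use \code{\link{batchPrefix}}.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @aliases ExpressionBatch
#' @export
setClass("ExpressionBatch", contains = "SummarizedExperiment")

.validExpressionBatch <- function(object) {
    msg <- NULL
    cd <- colData(object)
    if (!all(c("group", "batch") %in% colnames(cd)))
        return("colData must contain 'group' and 'batch' columns")
    grp <- cd$group
    bat <- cd$batch
    if (anyNA(grp) || anyNA(bat))
        msg <- c(msg, "group and batch labels must not contain NA")
    if (!all(grp %in% c(0L, 1L)))
        msg <- c(msg, "group labels must be coded 0/1 (two groups)")
    if (length(bat) > 0L) {
        ub <- sort(unique(as.integer(bat)))
        if (!identical(ub, seq_len(max(ub))))
            msg <- c(msg, "batch indices must be contiguous 1..t with each batch non-empty")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionBatch", .validExpressionBatch)

#' Construct an ExpressionBatch
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param group per-sample group label; any vector with exactly two distinct
#'   values (mapped to 0/1 in order of first appearance) or already 0/1.
#' @param batch per-sample integer batch index, contiguous from 1.
#' @param geneIds optional gene identifiers; defaults to existing rownames or
#'   \code{gene1..geneN}.
#' @return An \code{ExpressionBatch}.
#' @examples
#' x <- matrix(rlnorm(20), nrow = 5)
#' eb <- ExpressionBatch(x, group = c(0, 0, 1, 1), batch = c(1, 1, 1, 1))
#' nGenes(eb)
#' @export
ExpressionBatch <- function(values, group, batch, geneIds = NULL) {
    values <- as.matrix(values)
    if (length(group) != ncol(values) || length(batch) != ncol(values))
        stop("'group' and 'batch' must have one entry per sample column")
    if (!all(group %in% c(0, 1))) {
        lev <- unique(group)
        if (length(lev) > 2L)
            stop("more than two groups are not supported; found: ",
                 paste(lev, collapse = ", "))
        group <- as.integer(match(group, lev) - 1L)
    }
    if (is.null(geneIds))
        geneIds <- if (!is.null(rownames(values))) rownames(values) else
            paste0("gene", seq_len(nrow(values)))
    if (anyDuplicated(geneIds))
        stop("duplicated gene identifier: ",
             geneIds[anyDuplicated(geneIds)])
    rownames(values) <- geneIds
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(group = as.integer(group),
                            batch = as.integer(batch),
                            row.names = colnames(values)))
    new("ExpressionBatch", se)
}

#' Hyperparameters of the hierarchical expression models
#'
#' Virtual parent of \code{\linkS4class{GaGaHyperParams}} and
#' \code{\linkS4class{NNHyperParams}}.  Both carry the mixing weight
#' \code{pi}, the prior probability that a gene is differentially expressed,
#' plus model-specific hyperparameters held fixed after empirical-Bayes
#' estimation so that all per-gene posteriors are closed form (or 1-D
#' quadrature).
#'
#' @aliases HyperParams
#' @export
setClass("HyperParams", representation("VIRTUAL", pi = "numeric"))

#' Gamma-gamma model hyperparameters
#'
#' The gamma-gamma (GaGa) model assumes \eqn{x_{ij} \sim
#' Ga(\alpha_i, \alpha_i/\lambda_{i z_j})} (shape/rate, so the mean is
#' \eqn{\lambda}), with conjugate hierarchical prior
#' \eqn{\lambda \sim IGa(\alpha_0, \alpha_0/\nu)} on each group mean and
#' \eqn{\alpha_i \sim Ga(\beta, \beta/\mu)} on the gene-specific shape.
#' When a gene is equally expressed the two group means are tied.
#'
#' @slot alpha0,nu inverse-gamma hyperparameters of the group-mean prior
#'   (\code{E(lambda) = (alpha0/nu)/(alpha0 - 1)}).
#' @slot beta,mu gamma hyperparameters of the shape prior
#'   (\code{E(alpha_i) = mu}).
#' @slot pi prior probability that a gene is differentially expressed.
#' @aliases GaGaHyperParams
#' @export
setClass("GaGaHyperParams", contains = "HyperParams",
         representation(alpha0 = "numeric", nu = "numeric",
                        beta = "numeric", mu = "numeric"))

setValidity("GaGaHyperParams", function(object) {
    p <- c(alpha0 = object@alpha0, nu = object@nu,
           beta = object@beta, mu = object@mu)
    if (length(object@pi) != 1L || is.na(object@pi) ||
        object@pi < 0 || object@pi > 1)
        return("pi must be a single value in [0, 1]")
    if (any(lengths(list(object@alpha0, object@nu, object@beta,
                         object@mu)) != 1L) || any(!is.finite(p)) ||
        any(p <= 0))
        return("alpha0, nu, beta, mu must be single strictly positive values")
    TRUE
})

#' @param alpha0,nu,beta,mu,pi see slot documentation.
#' @rdname GaGaHyperParams-class
#' @export
GaGaHyperParams <- function(alpha0, nu, beta, mu, pi) {
    new("GaGaHyperParams", alpha0 = as.numeric(alpha0), nu = as.numeric(nu),
        beta = as.numeric(beta), mu = as.numeric(mu), pi = as.numeric(pi))
}

#' Log-normal-normal model hyperparameters
#'
#' The NN model assumes \eqn{\log x_{ij} \sim N(\mu_{i z_j}, \sigma_i^2)}
#' with a scaled-inverse-chi-square prior
#' \eqn{\sigma_i^2 \sim \nu_0 \sigma_0^2 / \chi^2_{\nu_0}} on the
#' gene-specific variance.  With \code{scaledMeans = TRUE} (the default,
#' the "generalized variance" form) the group means are conditionally
#' conjugate, \eqn{\mu_{ik} | \sigma_i^2 \sim N(\mu_0, \tau_0^2
#' \sigma_i^2)}, and all marginal likelihoods are closed form.  With
#' \code{scaledMeans = FALSE} the mean prior is
#' \eqn{N(\mu_0, \tau_0^2)} independent of the variance, and marginals are
#' obtained by deterministic 1-D quadrature over \eqn{\sigma^2}.
#'
#' @slot mu0 prior mean of the group-specific log-scale means.
#' @slot tau0 prior spread of the group means (relative to \eqn{\sigma_i}
#'   when \code{scaledMeans}).
#' @slot nu0,sigma0 degrees of freedom and scale of the variance prior.
#' @slot pi prior probability of differential expression.
#' @slot scaledMeans logical switch described above.
#' @aliases NNHyperParams
#' @export
setClass("NNHyperParams", contains = "HyperParams",
         representation(mu0 = "numeric", tau0 = "numeric",
                        nu0 = "numeric", sigma0 = "numeric",
                        scaledMeans = "logical"))

setValidity("NNHyperParams", function(object) {
    if (length(object@pi) != 1L || is.na(object@pi) ||
        object@pi < 0 || object@pi > 1)
        return("pi must be a single value in [0, 1]")
    p <- c(object@tau0, object@nu0, object@sigma0)
    if (!is.finite(object@mu0) || any(!is.finite(p)) || any(p <= 0))
        return("tau0, nu0, sigma0 must be strictly positive and mu0 finite")
    TRUE
})

#' @param mu0,tau0,nu0,sigma0,pi,scaledMeans see slot documentation.
#' @rdname NNHyperParams-class
#' @export
NNHyperParams <- function(mu0, tau0, nu0, sigma0, pi, scaledMeans = TRUE) {
    new("NNHyperParams", mu0 = as.numeric(mu0), tau0 = as.numeric(tau0),
        nu0 = as.numeric(nu0), sigma0 = as.numeric(sigma0),
        pi = as.numeric(pi), scaledMeans = isTRUE(scaledMeans))
}

#' Per-gene latent truth
#'
#' Latent differential-expression indicators and gene-level parameters, as
#' generated by \code{\link{sampleFromPrior}}.  \code{mean0}/\code{mean1} are
#' the two group means (\eqn{\lambda} for GaGa, log-scale \eqn{\mu} for NN);
#' they are equal whenever \code{delta == 0}.  \code{shapeOrVar} is the
#' gene-specific shape \eqn{\alpha_i} (GaGa) or variance \eqn{\sigma_i^2}
#' (NN).
#'
#' @aliases GeneParams
#' @export
setClass("GeneParams",
         representation(delta = "integer", mean0 = "numeric",
                        mean1 = "numeric", shapeOrVar = "numeric"))

setValidity("GeneParams", function(object) {
    n <- length(object@delta)
    if (length(object@mean0) != n || length(object@mean1) != n ||
        length(object@shapeOrVar) != n)
        return("all GeneParams fields must have equal length")
    if (!all(object@delta %in% c(0L, 1L)))
        return("delta must be 0/1")
    if (any(object@shapeOrVar <= 0))
        return("shapeOrVar must be strictly positive")
    ee <- object@delta == 0L
    if (any(object@mean0[ee] != object@mean1[ee]))
        return("genes with delta == 0 must have equal group means")
    TRUE
})

#' A simulated dataset together with its generating truth
#'
#' @slot batch the simulated \code{\linkS4class{ExpressionBatch}}.
#' @slot truth per-gene \code{\linkS4class{GeneParams}}.
#' @slot generatingHyper the \code{\linkS4class{HyperParams}} actually used to
#'   generate the data; may differ from any analysis hyperparameters in
#'   misspecification scenarios.
#' @aliases SyntheticDataset
#' @export
setClass("SyntheticDataset",
         representation(batch = "ExpressionBatch", truth = "GeneParams",
                        generatingHyper = "HyperParams"))

setValidity("SyntheticDataset", function(object) {
    if (length(object@truth@delta) != nrow(object@batch))
        return("truth must have one entry per gene of batch")
    TRUE
})

#' Terminal decision summary
#'
#' Result of \code{\link{bayesTerminalDecision}}: per-gene posterior
#' probabilities of differential expression \code{v}, the 0/1 decisions
#' \code{d}, the number of positives \code{D}, the achieved posterior
#' expected FDR, and the posterior expected number of true positives
#' \eqn{\sum_i d_i v_i}.
#'
#' @aliases PosteriorSummary
#' @export
setClass("PosteriorSummary",
         representation(v = "numeric", d = "integer", fdrLevel = "numeric",
                        posteriorFDR = "numeric", expectedTP = "numeric",
                        D = "integer"))

setValidity("PosteriorSummary", function(object) {
    if (length(object@v) != length(object@d))
        return("v and d must have equal length")
    if (any(object@v < 0 | object@v > 1))
        return("v must lie in [0, 1]")
    if (!all(object@d %in% c(0L, 1L)))
        return("d must be 0/1")
    if (object@D != sum(object@d))
        return("D must equal the number of positives in d")
    if (object@D > 0L && object@posteriorFDR > object@fdrLevel + 1e-12)
        return("posterior expected FDR exceeds the target level")
    if (object@expectedTP < -1e-12 || object@expectedTP > object@D + 1e-12)
        return("expectedTP must lie in [0, D]")
    TRUE
})

#' Utility specification for sequential stopping
#'
#' The utility of stopping after \code{t} batches with decisions \code{d} is
#' the number of true positives minus \code{c * t}.  The sampling cost
#' \code{c} is interpretable as the minimum number of new true positives that
#' makes one more batch worthwhile.  Terminal decisions control the posterior
#' expected FDR at \code{fdrLevel} (0.05 by default).
#'
#' @param c sampling cost per batch, \code{>= 0}.
#' @param fdrLevel terminal FDR level in (0, 1].
#' @aliases UtilityParams
#' @export
setClass("UtilityParams",
         representation(c = "numeric", fdrLevel = "numeric"))

setValidity("UtilityParams", function(object) {
    if (length(object@c) != 1L || !is.finite(object@c) || object@c < 0)
        return("c must be a single non-negative number")
    if (object@fdrLevel <= 0 || object@fdrLevel > 1)
        return("fdrLevel must lie in (0, 1]")
    TRUE
})

#' @rdname UtilityParams-class
#' @export
UtilityParams <- function(c = 50, fdrLevel = 0.05) {
    new("UtilityParams", c = as.numeric(c), fdrLevel = as.numeric(fdrLevel))
}

#' Sequential design specification
#'
#' @param T maximum number of batches (horizon).
#' @param batchPerGroup integer vector of length 2: samples added per group
#'   in every batch.
#' @param t0 number of batches already observed before sequential monitoring
#'   starts (0 allowed: design from no data, using the prior predictive).
#' @aliases DesignSpec
#' @export
setClass("DesignSpec",
         representation(T = "integer", batchPerGroup = "integer",
                        t0 = "integer"))

setValidity("DesignSpec", function(object) {
    if (object@T < 1L) return("T must be >= 1")
    if (length(object@batchPerGroup) != 2L || any(object@batchPerGroup < 0L) ||
        sum(object@batchPerGroup) < 1L)
        return("batchPerGroup must be two non-negative counts, at least one positive")
    if (object@t0 < 0L || object@t0 >= object@T)
        return("t0 must satisfy 0 <= t0 < T")
    TRUE
})

#' @rdname DesignSpec-class
#' @export
DesignSpec <- function(T, batchPerGroup = c(2L, 2L), t0 = 0L) {
    if (length(batchPerGroup) == 1L)
        batchPerGroup <- rep(batchPerGroup, 2L)
    new("DesignSpec", T = as.integer(T),
        batchPerGroup = as.integer(batchPerGroup), t0 = as.integer(t0))
}

#' Linear stopping boundary
#'
#' Stopping is decided on the one-step-ahead expected gain in true positives
#' \eqn{\Delta_t(TP)}: experimentation continues while \eqn{\Delta_t(TP)}
#' lies strictly above \code{b0 + b1 * t}, and stops otherwise.  At
#' \code{t = T - 1} the boundary is replaced by the one-step-optimal (myopic)
#' rule, continue iff \eqn{\Delta_{T-1}(TP) - c > 0}.  \code{b0 = -Inf} is
#' the fixed-sample sentinel: the boundary never triggers before the horizon.
#' \code{Boundary(c, 0)} reproduces the myopic rule at every step.
#'
#' @param b0 intercept (may be \code{-Inf}).
#' @param b1 slope, finite.
#' @aliases Boundary
#' @export
setClass("Boundary", representation(b0 = "numeric", b1 = "numeric"))

setValidity("Boundary", function(object) {
    if (length(object@b0) != 1L || length(object@b1) != 1L ||
        is.na(object@b0) || is.na(object@b1))
        return("b0 and b1 must be single numbers")
    if (object@b0 == Inf) return("b0 = +Inf is not a valid boundary")
    if (!is.finite(object@b1)) return("b1 must be finite")
    TRUE
})

#' @rdname Boundary-class
#' @export
Boundary <- function(b0, b1 = 0) {
    new("Boundary", b0 = as.numeric(b0), b1 = as.numeric(b1))
}

#' Forward-simulated trajectories of the monitoring statistic
#'
#' One row per simulated future of the experiment.  \code{deltaTP[j, ]} holds
#' the realized one-step increments \eqn{\Delta_k(TP)} for steps
#' \code{k = t0 .. T-1} (the increment from \code{k} to \code{k+1} batches),
#' and \code{expectedTPAt[j, ]} the posterior expected number of true
#' positives after \code{t0 .. T} batches of (real plus simulated) data.
#'
#' @aliases TrajectorySet
#' @export
setClass("TrajectorySet",
         representation(deltaTP = "matrix", expectedTPAt = "matrix",
                        t0 = "integer", seed = "integer"))

setValidity("TrajectorySet", function(object) {
    if (nrow(object@deltaTP) != nrow(object@expectedTPAt))
        return("deltaTP and expectedTPAt must have one row per trajectory")
    if (ncol(object@expectedTPAt) != ncol(object@deltaTP) + 1L)
        return("expectedTPAt must have one more column than deltaTP")
    if (any(!is.finite(object@deltaTP)) || any(!is.finite(object@expectedTPAt)))
        return("all trajectory entries must be finite")
    TRUE
})

#' Simulation scenario for study-level operating characteristics
#'
#' Couples a generating truth (\code{generatingHyper}) with the analyst's
#' model (\code{analysisHyper}); the two may differ, e.g. the true proportion
#' of differentially expressed genes halved or doubled relative to the
#' analysis prior, to probe robustness to prior misspecification.
#'
#' @param generatingHyper,analysisHyper \code{\linkS4class{HyperParams}}.
#' @param design a \code{\linkS4class{DesignSpec}}.
#' @param util a \code{\linkS4class{UtilityParams}}.
#' @param nGenes number of genes simulated per replicate study.
#' @param nrep number of replicate studies.
#' @param m posterior-predictive draws per monitoring step.
#' @param seed integer root seed.
#' @aliases ScenarioSpec
#' @export
setClass("ScenarioSpec",
         representation(generatingHyper = "HyperParams",
                        analysisHyper = "HyperParams",
                        design = "DesignSpec", util = "UtilityParams",
                        nGenes = "integer", nrep = "integer",
                        m = "integer", seed = "integer"))

setValidity("ScenarioSpec", function(object) {
    if (object@nrep < 1L) return("nrep must be >= 1")
    if (object@nGenes < 1L) return("nGenes must be >= 1")
    if (object@m < 1L) return("m must be >= 1")
    TRUE
})

#' @rdname ScenarioSpec-class
#' @export
ScenarioSpec <- function(generatingHyper, analysisHyper = generatingHyper,
                         design, util = UtilityParams(), nGenes = 1000L,
                         nrep = 250L, m = 10L, seed = 1L) {
    new("ScenarioSpec", generatingHyper = generatingHyper,
        analysisHyper = analysisHyper, design = design, util = util,
        nGenes = as.integer(nGenes), nrep = as.integer(nrep),
        m = as.integer(m), seed = as.integer(seed))
}

#' Study-level operating characteristics
#'
#' Aggregates over replicate simulated studies: average stopping time (in
#' batches), average realized and posterior expected utility, average
#' posterior expected number of true positives at stopping, and average
#' realized FDR against the simulation truth.  \code{records} keeps the
#' per-replication rows.
#'
#' @aliases OperatingCharacteristics
#' @export
setClass("OperatingCharacteristics",
         representation(meanTau = "numeric", meanUtility = "numeric",
                        meanExpectedTP = "numeric",
                        meanRealizedFDR = "numeric",
                        records = "data.frame"))
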