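#' @rdname ExpressionBatch
#' @param x,object an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionBatch
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionBatch
#' @export
setGeneric("sampleBatches", function(x) standardGeneric("sampleBatches"))

#' @rdname ExpressionBatch
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionBatch
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname ExpressionBatch
#' @export
setGeneric("nBatches", function(x) standardGeneric("nBatches"))

#' @rdname ExpressionBatch
#' @param t number of leading batches to keep.
#' @export
setGeneric("batchPrefix", function(x, t) standardGeneric("batchPrefix"))

#' Model identifier of a hyperparameter object
#'
#' @param object a \code{\linkS4class{HyperParams}}.
#' @return \code{"gaga"} or \code{"nn"}.
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' Prior probability of differential expression
#'
#' Accessor and replacement for the mixing weight \code{pi} of a
#' \code{\linkS4class{HyperParams}} object.
#'
#' @param object a \code{\linkS4class{HyperParams}}.
#' @param value replacement value in [0, 1].
#' @export
setGeneric("priorDEProb", function(object) standardGeneric("priorDEProb"))

#' @rdname priorDEProb
#' @export
setGeneric("priorDEProb<-",
           function(object, value) standardGeneric("priorDEProb<-"))

#' Marginal likelihood of one gene under a fixed expression pattern
#'
#' Computes \eqn{\log p(x_i | \delta_i, \omega)}, the sampling model
#' integrated over the gene-level parameters against the hierarchical prior.
#' Under \code{pattern = "EE"} both groups share one mean parameter; under
#' \code{"DE"} each group has its own mean, sharing the gene-specific shape
#' (GaGa) or variance (NN).  For the NN model the density is evaluated on the
#' natural-log scale of the data (the log-scale Jacobian is common to both
#' patterns and cancels from posterior odds).
#'
#' @param hyper a \code{\linkS4class{HyperParams}} object selecting the model.
#' @param x0,x1 numeric vectors of measurements in group 0 and group 1
#'   (either may be empty, not both); strictly positive.
#' @param pattern \code{"EE"} or \code{"DE"}.
#' @param ... further arguments passed to methods (e.g. \code{quadNodes} for
#'   the GaGa shape integration).
#' @return a single log marginal density.
#' @seealso \code{\link{posteriorDEProb}}
#' @export
setGeneric("logMarginal",
           function(hyper, x0, x1, pattern = c("EE", "DE"), ...)
               standardGeneric("logMarginal"))

#' Simulate genes and data from the hierarchical prior
#'
#' Draws per-gene truth (\eqn{\delta_i \sim Bern(\pi)}, group means tied when
#' \eqn{\delta_i = 0}, gene-specific shape or variance) and an expression
#' matrix from the sampling model, as a \code{\linkS4class{SyntheticDataset}}.
#'
#' @param hyper generating \code{\linkS4class{HyperParams}}.
#' @param n number of genes.
#' @param samplesPerGroup integer vector of length 2.
#' @param nBatches how many batches the samples are split into (each batch
#'   receives \code{samplesPerGroup/nBatches} samples per group).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param ... passed to methods.
#' @export
setGeneric("sampleFromPrior",
           function(hyper, n, samplesPerGroup, nBatches = 1L, seed = NULL, ...)
               standardGeneric("sampleFromPrior"))
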