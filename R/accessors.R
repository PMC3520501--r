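#' @rdname ExpressionBatch
#' @export
setMethod("exprValues", "ExpressionBatch", function(x) assay(x, "exprs"))

#' @rdname ExpressionBatch
#' @export
setMethod("sampleGroups", "ExpressionBatch",
          function(x) colData(x)$group)

#' @rdname ExpressionBatch
#' @export
setMethod("sampleBatches", "ExpressionBatch",
          function(x) colData(x)$batch)

#' @rdname ExpressionBatch
#' @export
setMethod("geneIds", "ExpressionBatch", function(x) rownames(x))

#' @rdname ExpressionBatch
#' @export
setMethod("nGenes", "ExpressionBatch", function(x) nrow(x))

#' @rdname ExpressionBatch
#' @export
setMethod("nBatches", "ExpressionBatch",
          function(x) if (ncol(x) == 0L) 0L else max(sampleBatches(x)))

#' @rdname ExpressionBatch
#' @export
setMethod("batchPrefix", "ExpressionBatch", function(x, t) {
    t <- as.integer(t)
    if (t < 0L || t > nBatches(x))
        stop("t must lie in 0..nBatches(x)")
    x[, sampleBatches(x) <= t]
})

#' @rdname modelId
#' @export
setMethod("modelId", "GaGaHyperParams", function(object) "gaga")

#' @rdname modelId
#' @export
setMethod("modelId", "NNHyperParams", function(object) "nn")

#' @rdname priorDEProb
#' @export
setMethod("priorDEProb", "HyperParams", function(object) object@pi)

#' @rdname priorDEProb
#' @export
setReplaceMethod("priorDEProb", "HyperParams", function(object, value) {
    object@pi <- as.numeric(value)
    validObject(object)
    object
})

setMethod("show", "ExpressionBatch", function(object) {
    cat("ExpressionBatch:", nrow(object), "genes,", ncol(object),
        "samples in", nBatches(object), "batch(es)\n")
    if (ncol(object) > 0L) {
        tab <- table(group = sampleGroups(object),
                     batch = sampleBatches(object))
        cat("samples per group x batch:\n")
        print(tab)
    }
})

setMethod("show", "GaGaHyperParams", function(object) {
    cat(sprintf(paste0("GaGa hyperparameters: alpha0 = %.4g, nu = %.4g, ",
                       "beta = %.4g, mu = %.4g, pi = %.4g\n"),
                object@alpha0, object@nu, object@beta, object@mu, object@pi))
})

setMethod("show", "NNHyperParams", function(object) {
    cat(sprintf(paste0("NN hyperparameters: mu0 = %.4g, tau0 = %.4g, ",
                       "nu0 = %.4g, sigma0 = %.4g, pi = %.4g (%s mean prior)\n"),
                object@mu0, object@tau0, object@nu0, object@sigma0, object@pi,
                if (object@scaledMeans) "variance-scaled" else
                    "variance-independent"))
})

setMethod("show", "PosteriorSummary", function(object) {
    cat(sprintf(paste0("PosteriorSummary: %d genes, D = %d positives at ",
                       "FDR level %.3g\n  posterior expected FDR = %.4g, ",
                       "expected TP = %.4g\n"),
                length(object@v), object@D, object@fdrLevel,
                object@posteriorFDR, object@expectedTP))
})

setMethod("show", "Boundary", function(object) {
    cat(sprintf("Boundary: stop when Delta_t(TP) <= %.4g + %.4g * t\n",
                object@b0, object@b1))
})

setMethod("show", "DesignSpec", function(object) {
    cat(sprintf(paste0("DesignSpec: horizon T = %d batches (%d + %d samples ",
                       "per batch), t0 = %d observed\n"),
                object@T, object@batchPerGroup[1], object@batchPerGroup[2],
                object@t0))
})

setMethod("show", "TrajectorySet", function(object) {
    cat(sprintf(paste0("TrajectorySet: %d trajectories over steps %d..%d\n",
                       "  mean Delta_k(TP) at first step: %.4g\n"),
                nrow(object@deltaTP), object@t0,
                object@t0 + ncol(object@deltaTP) - 1L,
                mean(object@deltaTP[, 1L])))
})

setMethod("show", "OperatingCharacteristics", function(object) {
    cat(sprintf(paste0("OperatingCharacteristics over %d replications:\n",
                       "  mean tau = %.3g batches, mean utility = %.4g\n",
                       "  mean expected TP = %.4g, mean realized FDR = %.4g\n"),
                nrow(object@records), object@meanTau, object@meanUtility,
                object@meanExpectedTP, object@meanRealizedFDR))
})
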