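#' Scaled-down microarray simulation scenario
#'
#' A desk-scale version of the package's standard simulated-microarray
#' study: 1000 genes under the NN model (log-scale grand mean 7, gene-mean
#' spread \code{tau0 = 1.25}, variance prior \code{nu0 = 6},
#' \code{sigma0 = 0.6}), analysis prior DE proportion 0.3, batches of 2
#' samples per group up to a horizon of 10 batches with 1 pilot batch
#' observed, sampling cost \code{c = 50} and terminal FDR level 0.05.
#' \code{piScale} rescales the \emph{generating} DE proportion only (e.g.
#' 0.5 or 2 for the halved/doubled misspecification scenarios), leaving the
#' analysis prior untouched.
#'
#' The aggregate signal is calibrated so that, under the correctly specified
#' prior, the one-step-ahead expected gain in true positives starts above
#' the sampling cost and decays through it within the horizon -- the regime
#' in which sequential stopping is a live decision rather than a foregone
#' conclusion.
#'
#' @param piScale multiplier on the generating DE proportion.
#' @param nrep number of replicate studies.
#' @param seed integer root seed.
#' @param nGenes genes per study.
#' @param m posterior-predictive draws per monitoring step.
#' @return a \code{\linkS4class{ScenarioSpec}}.
#' @examples
#' scen <- scaledMicroarrayScenario(piScale = 2, nrep = 5)
#' @export
scaledMicroarrayScenario <- function(piScale = 1, nrep = 50L, seed = 1L,
                                     nGenes = 1000L, m = 8L) {
    base <- NNHyperParams(mu0 = 7, tau0 = 1.25, nu0 = 6, sigma0 = 0.6,
                          pi = 0.3)
    gen <- base
    priorDEProb(gen) <- min(0.3 * piScale, 1)
    ScenarioSpec(generatingHyper = gen, analysisHyper = base,
                 design = DesignSpec(T = 10L, batchPerGroup = c(2L, 2L),
                                     t0 = 1L),
                 util = UtilityParams(c = 50, fdrLevel = 0.05),
                 nGenes = nGenes, nrep = nrep, m = m, seed = seed)
}
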