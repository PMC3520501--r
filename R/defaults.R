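#' Reference hyperparameter settings
#'
#' Default hyperparameter values emulating an empirical-Bayes fit to a
#' two-group leukemia-microarray-style dataset, used as the package's
#' standard simulation conditions.  For the NN model: log-scale grand mean
#' 7, gene-mean spread \code{tau0 = 1} relative to the gene standard
#' deviation, variance prior with 6 degrees of freedom and scale 0.6, and a
#' prior proportion of differentially expressed genes of 0.05.  For GaGa:
#' mean expression around 500 with moderate shape heterogeneity
#' (\code{E(alpha) = 8}) and a DE proportion of 0.063.
#'
#' @param model \code{"nn"} or \code{"gaga"}.
#' @return a \code{\linkS4class{HyperParams}}.
#' @examples
#' defaultHyperParams("nn")
#' @export
defaultHyperParams <- function(model = c("nn", "gaga")) {
    model <- match.arg(model)
    if (model == "nn")
        NNHyperParams(mu0 = 7, tau0 = 1, nu0 = 6, sigma0 = 0.6, pi = 0.05)
    else
        GaGaHyperParams(alpha0 = 2.5, nu = 0.003, beta = 3, mu = 8,
                        pi = 0.063)
}
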