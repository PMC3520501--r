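# Shared fixtures, all generated in code.

nnHyp <- function(pi = 0.05, tau0 = 1, scaledMeans = TRUE)
    NNHyperParams(mu0 = 7, tau0 = tau0, nu0 = 6, sigma0 = 0.6, pi = pi,
                  scaledMeans = scaledMeans)

gagaHyp <- function(pi = 0.063)
    GaGaHyperParams(alpha0 = 2.5, nu = 0.003, beta = 3, mu = 8, pi = pi)

toyBatch <- function(n = 4, m0 = 3, m1 = 3, seed = 1, nbatch = 1) {
    set.seed(seed)
    values <- matrix(rlnorm(n * (m0 + m1), 7, 0.8), nrow = n)
    ExpressionBatch(values,
                    group = c(rep(0, m0), rep(1, m1)),
                    batch = rep(seq_len(nbatch),
                                length.out = m0 + m1) |> sort())
}

# write a small matrix + annotation pair to tempfiles; returns the paths
writeToyFiles <- function(values, group, batch, dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
    mpath <- file.path(dir, "matrix.tsv")
    apath <- file.path(dir, "annotation.tsv")
    df <- data.frame(gene = rownames(values), values, check.names = FALSE)
    write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = colnames(values), group = group,
                           batch = batch),
                apath, sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = mpath, annotation = apath, dir = dir)
}
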