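# Data ingestion, the positivity shift transform, tabular exports and run
# manifests.  Pre-processing beyond the shift (normalization, batch-effect
# removal, covariate adjustment) is upstream responsibility: readers expect
# already-processed matrices.

#' Read a genes-by-samples expression matrix
#'
#' Delimited text, genes in rows; the first column holds gene identifiers
#' and the header row holds sample identifiers.  Malformed input is rejected
#' rather than coerced: duplicated gene ids, ragged rows and non-numeric
#' cells are errors naming the offending location.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return list with \code{values} (numeric matrix, rownames = gene ids,
#'   colnames = sample ids), \code{nGenes}, \code{nSamples}.
#' @export
readExpressionMatrix <- function(path, sep = "\t") {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("expression matrix must have a header and ",
                                 "at least one gene row")
    split <- strsplit(lines, sep, fixed = TRUE)
    header <- split[[1L]]
    sampleIds <- header[-1L]
    nf <- lengths(split[-1L])
    if (any(nf != length(header)))
        stop("ragged row(s) at line(s): ",
             paste(utils::head(which(nf != length(header)) + 1L, 5L),
                   collapse = ", "))
    geneIdsV <- vapply(split[-1L], `[[`, character(1), 1L)
    dup <- geneIdsV[duplicated(geneIdsV)]
    if (length(dup))
        stop("duplicated gene id: ", paste(unique(dup), collapse = ", "))
    cells <- lapply(split[-1L], function(r) suppressWarnings(
        as.numeric(r[-1L])))
    values <- do.call(rbind, cells)
    if (anyNA(values)) {
        bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
        stop("non-numeric cell at gene '", geneIdsV[bad[1L]],
             "' (row ", bad[1L] + 1L, "), sample '", sampleIds[bad[2L]],
             "' (column ", bad[2L] + 1L, ")")
    }
    rownames(values) <- geneIdsV
    colnames(values) <- sampleIds
    list(values = values, nGenes = nrow(values), nSamples = ncol(values))
}

#' Read a sample annotation table
#'
#' Tab-delimited with columns \code{sample_id}, \code{group}, \code{batch}.
#' Exactly two distinct group labels are required (two-group comparisons are
#' this package's scope) and batch indices must be contiguous from 1.
#'
#' @param path file path.
#' @return data frame with columns \code{sample_id}, \code{group} (0/1),
#'   \code{groupLabel}, \code{batch}.
#' @export
readSampleAnnotation <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "batch")
    if (!all(need %in% colnames(ann)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    lev <- unique(ann$group)
    if (length(lev) > 2L)
        stop("unsupported: ", length(lev), " groups found (",
             paste(lev, collapse = ", "), "); only two-group comparisons ",
             "are supported")
    if (length(lev) < 2L)
        stop("both groups must be present in the annotation")
    bat <- as.integer(ann$batch)
    if (anyNA(bat)) stop("batch indices must be integers")
    ub <- sort(unique(bat))
    if (!identical(ub, seq_len(max(ub))))
        stop("batch numbering has a gap: found ",
             paste(ub, collapse = ", "))
    data.frame(sample_id = as.character(ann$sample_id),
               group = as.integer(match(ann$group, lev) - 1L),
               groupLabel = as.character(ann$group), batch = bat,
               stringsAsFactors = FALSE)
}

#' Assemble an ExpressionBatch from a matrix file and annotation
#'
#' @param matrixPath,annotationPath file paths for
#'   \code{\link{readExpressionMatrix}} and
#'   \code{\link{readSampleAnnotation}}.
#' @return an \code{\linkS4class{ExpressionBatch}} with samples ordered by
#'   batch.
#' @export
readBatchData <- function(matrixPath, annotationPath) {
    em <- readExpressionMatrix(matrixPath)
    ann <- readSampleAnnotation(annotationPath)
    missing <- setdiff(colnames(em$values), ann$sample_id)
    extra <- setdiff(ann$sample_id, colnames(em$values))
    if (length(missing) || length(extra))
        stop("header/annotation mismatch; unmatched sample(s): ",
             paste(c(missing, extra), collapse = ", "))
    ann <- ann[order(ann$batch, ann$group, ann$sample_id), ]
    values <- em$values[, ann$sample_id, drop = FALSE]
    ExpressionBatch(values, group = ann$group, batch = ann$batch)
}

#' Shift transform enforcing strict positivity
#'
#' Adds a constant offset \code{k} to every measurement so that shifted
#' values are strictly positive, as required by the gamma sampling model and
#' by the internal log transform of the NN model.  \code{k = "auto"} picks
#' \code{max(0, 1e-3 - min(values))}.  The offset used is recorded in the
#' object's metadata.
#'
#' @param batch an \code{\linkS4class{ExpressionBatch}}.
#' @param k numeric offset, or \code{"auto"}.
#' @return the shifted \code{ExpressionBatch}.
#' @export
shiftTransform <- function(batch, k = "auto") {
    values <- exprValues(batch)
    eps <- 1e-3
    if (identical(k, "auto"))
        k <- max(0, eps - min(values))
    k <- as.numeric(k)
    shifted <- values + k
    if (any(shifted <= 0))
        stop("offset k = ", k, " leaves non-positive values (minimum ",
             min(shifted), "); choose k > ", -min(values))
    out <- ExpressionBatch(shifted, sampleGroups(batch),
                           sampleBatches(batch), geneIds(batch))
    metadata(out)$shiftOffset <- k
    out
}

# ---- tabular exports (tab-delimited UTF-8, one header row) ----------------

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Export a per-gene decision table
#'
#' Per-gene posterior probability, rank, decision, and the cumulative
#' posterior expected FDR down the ranking.
#'
#' @param ps a \code{\linkS4class{PosteriorSummary}}.
#' @param geneIds gene identifiers (same order as \code{ps@v}).
#' @param path output file.
#' @export
writeDecisionTable <- function(ps, geneIds, path) {
    ord <- order(-ps@v, seq_along(ps@v))
    cm <- cumsum(1 - ps@v[ord]) / seq_along(ord)
    df <- data.frame(gene = geneIds[ord], rank = seq_along(ord),
                     v = ps@v[ord], d = ps@d[ord], cumulativeFDR = cm)
    .writeTSV(df, path)
}

#' Export forward-simulation trajectories in long format
#'
#' @param trajset a \code{\linkS4class{TrajectorySet}}.
#' @param path output file.
#' @export
writeTrajectories <- function(trajset, path) {
    B <- nrow(trajset@deltaTP)
    K <- ncol(trajset@deltaTP)
    steps <- trajset@t0 + seq_len(K) - 1L
    df <- data.frame(trajectory = rep(seq_len(B), each = K),
                     step = rep(steps, B),
                     deltaTP = as.vector(t(trajset@deltaTP)),
                     expectedTPAfter =
                         as.vector(t(trajset@expectedTPAt[, -1L,
                                                          drop = FALSE])))
    .writeTSV(df, path)
}

#' Export a boundary utility surface
#'
#' @param opt result of \code{\link{optimizeBoundary}}.
#' @param path output file.
#' @export
writeBoundarySurface <- function(opt, path) {
    .writeTSV(opt$surface, path)
}

#' Write a reproducibility manifest
#'
#' Serializes everything needed to reproduce a run bit-for-bit: seed,
#' hyperparameters, design, utility, grids, and package version.
#'
#' @param config named list of run settings.
#' @param path output JSON file.
#' @export
writeManifest <- function(config, path) {
    config$packageVersion <-
        as.character(utils::packageVersion("seqhts"))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

.hyperToList <- function(hyper) {
    if (is(hyper, "NNHyperParams"))
        list(model = "nn", mu0 = hyper@mu0, tau0 = hyper@tau0,
             nu0 = hyper@nu0, sigma0 = hyper@sigma0, pi = hyper@pi,
             scaledMeans = hyper@scaledMeans)
    else
        list(model = "gaga", alpha0 = hyper@alpha0, nu = hyper@nu,
             beta = hyper@beta, mu = hyper@mu, pi = hyper@pi)
}

.hyperFromList <- function(lst) {
    if (lst$model == "nn")
        NNHyperParams(lst$mu0, lst$tau0, lst$nu0, lst$sigma0, lst$pi,
                      if (is.null(lst$scaledMeans)) TRUE else
                          lst$scaledMeans)
    else
        GaGaHyperParams(lst$alpha0, lst$nu, lst$beta, lst$mu, lst$pi)
}

#' Write / read hyperparameters as YAML
#'
#' @param hyper a \code{\linkS4class{HyperParams}}.
#' @param path file path.
#' @export
writeHyperParams <- function(hyper, path) {
    yaml::write_yaml(.hyperToList(hyper), path)
    invisible(path)
}

#' @rdname writeHyperParams
#' @export
readHyperParams <- function(path) {
    .hyperFromList(yaml::read_yaml(path))
}
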