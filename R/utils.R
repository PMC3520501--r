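# Internal numerical helpers and the reproducible substream convention.

# Deterministic substream seed derived from a root seed and a stream index.
# Keeps results independent of evaluation order (every trajectory/replication
# re-seeds from its own substream) and below 2^31 - 1.
.substream <- function(root, i) {
    root <- as.double(root %% 2147483647)
    i <- as.double(i)
    as.integer((root * 48271 + i * 1299721 + 1) %% 2147483647)
}

.logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix plus a per-column log-weight vector.
.rowLogSumExpW <- function(lx, logw) {
    lx <- sweep(lx, 2L, logw, "+")
    m <- apply(lx, 1L, max)
    bad <- !is.finite(m)
    out <- m + log(rowSums(exp(lx - m)))
    out[bad] <- m[bad]
    out
}

# Per-group sufficient statistics for both models, kept as raw moments so
# that simulated batches can be appended cheaply.
#   GaGa needs: counts, sums, sums of logs.
#   NN needs:   counts, sums of logs, sums of squared logs.
.suffStats <- function(values, groups, model) {
    if (is.null(values) || ncol(values) == 0L) {
        n <- if (is.null(values)) 0L else nrow(values)
        z <- numeric(n)
        return(list(model = model, n = n, m0 = 0L, m1 = 0L,
                    s0 = z, s1 = z, q0 = z, q1 = z))
    }
    if (any(!is.finite(values)))
        stop("expression values must all be finite")
    if (any(values <= 0))
        stop("expression values must be strictly positive (apply ",
             "shiftTransform() first); offending gene(s): ",
             paste(utils::head(rownames(values)[
                 rowSums(values <= 0) > 0], 5L), collapse = ", "))
    i0 <- which(groups == 0L)
    i1 <- which(groups == 1L)
    if (model == "nn") {
        lv <- log(values)
        list(model = model, n = nrow(values),
             m0 = length(i0), m1 = length(i1),
             s0 = rowSums(lv[, i0, drop = FALSE]),
             s1 = rowSums(lv[, i1, drop = FALSE]),
             q0 = rowSums(lv[, i0, drop = FALSE]^2),
             q1 = rowSums(lv[, i1, drop = FALSE]^2))
    } else {
        lv <- log(values)
        list(model = model, n = nrow(values),
             m0 = length(i0), m1 = length(i1),
             s0 = rowSums(values[, i0, drop = FALSE]),
             s1 = rowSums(values[, i1, drop = FALSE]),
             q0 = rowSums(lv[, i0, drop = FALSE]),
             q1 = rowSums(lv[, i1, drop = FALSE]))
    }
}

# Append one simulated batch (new0/new1: n x k matrices, possibly 0 columns)
# to existing sufficient statistics.
.ssAppend <- function(ss, new0, new1) {
    addg <- function(mat, s, q, m, model) {
        if (is.null(mat) || ncol(mat) == 0L)
            return(list(s = s, q = q, m = m))
        if (model == "nn") {
            lm_ <- log(mat)
            list(s = s + rowSums(lm_), q = q + rowSums(lm_^2),
                 m = m + ncol(mat))
        } else {
            list(s = s + rowSums(mat), q = q + rowSums(log(mat)),
                 m = m + ncol(mat))
        }
    }
    a0 <- addg(new0, ss$s0, ss$q0, ss$m0, ss$model)
    a1 <- addg(new1, ss$s1, ss$q1, ss$m1, ss$model)
    list(model = ss$model, n = ss$n, m0 = a0$m, m1 = a1$m,
         s0 = a0$s, s1 = a1$s, q0 = a0$q, q1 = a1$q)
}

.batchFromValues <- function(values, groups, batches, geneIds = NULL) {
    ExpressionBatch(values, group = groups, batch = batches,
                    geneIds = geneIds)
}
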