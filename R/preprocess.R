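#' Filter low-expression genes
#'
#' Ranks genes by their total count across all samples and removes the
#' lowest `floor(fraction * n_genes)` of them (the study removed the 25%
#' of genes with the smallest sum of counts over all 72 samples).  Ties at
#' the boundary are broken deterministically by gene id: among equal
#' totals the lexicographically earlier gene is removed first, so the kept
#' gene at the boundary is the lexicographically later one.  Survivors
#' keep their input order.
#'
#' @param counts Integer gene x sample matrix with gene ids as rownames.
#' @param fraction Fraction of genes to remove, in `[0, 1)`.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, fraction = 0.25) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)")
  }
  n <- nrow(counts)
  m <- floor(fraction * n)
  if (m == 0L) return(counts)
  totals <- rowSums(counts)
  ord <- order(totals, rownames(counts))    # ascending total, then gene id
  drop <- ord[seq_len(m)]
  counts[sort(setdiff(seq_len(n), drop)), , drop = FALSE]
}

#' Log2 counts-per-million transformation
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` with library
#' size the post-filter column sum, following the voom convention
#' (default prior count 0.5).
#'
#' @param counts Filtered count matrix.
#' @param prior_count Pseudo-count added to each observation.
#' @return Numeric matrix of log2-CPM values, same dimnames as `counts`.
#' @export
log_cpm <- function(counts, prior_count = 0.5) {
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("all-zero column(s): ", paste(bad, collapse = ", "))
  }
  t(log2(t(counts + prior_count) / (lib + 2 * prior_count) * 1e6))
}

#' Mean-variance precision weights for log2-CPM data
#'
#' Fits a lowess curve (span 0.5) of the square root of the per-gene
#' residual standard deviation against the per-gene mean log2 count, and
#' returns per-gene weights equal to the inverse of the predicted variance,
#' with flat extrapolation outside the fitted range.  With fewer than 10
#' genes no trend can be estimated and all weights are 1.
#'
#' @param expr log2-CPM matrix from [log_cpm()].
#' @param counts The count matrix `expr` was computed from.
#' @param span Lowess span.
#' @return A list of class `weighted_expr` with elements `E` (the
#'   expression matrix) and `weights` (gene x sample positive weights).
#' @export
voom_weights <- function(expr, counts, span = 0.5) {
  stopifnot(is.matrix(expr), is.matrix(counts),
            all(dim(expr) == dim(counts)))
  n <- nrow(expr)
  if (n < 10L) {
    w <- matrix(1, n, ncol(expr), dimnames = dimnames(expr))
    return(structure(list(E = expr, weights = w), class = "weighted_expr"))
  }
  mean_log_count <- rowMeans(log2(counts + 0.5))
  res_sd <- apply(expr, 1L, sd)
  fit <- lowess(mean_log_count, sqrt(res_sd), f = span)
  pred <- approx(fit$x, fit$y, xout = mean_log_count, rule = 2)$y
  pred <- pmax(pred, 1e-4)
  w_gene <- pred^(-4)                      # sqrt(sd)^-4 = 1/variance
  w <- matrix(w_gene, n, ncol(expr), dimnames = dimnames(expr))
  structure(list(E = expr, weights = w), class = "weighted_expr")
}

#' qPCR arbitrary signal from a delta-Ct value
#'
#' Converts a delta-Ct (computed against the geometric mean of the
#' housekeeping genes) to the arbitrary signal `2^(-dct) * 10000`.
#'
#' @param dct Numeric delta-Ct value(s).
#' @return Numeric signal(s), strictly decreasing in `dct`.
#' @export
qpcr_signal <- function(dct) {
  stopifnot(is.numeric(dct), all(is.finite(dct)))
  2^(-dct) * 10000
}
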