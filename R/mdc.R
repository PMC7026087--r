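#' Within-module connectivity sum
#'
#' Sum of the strictly lower-triangular adjacency entries over the
#' module's genes (the diagonal is excluded), the quantity whose
#' stressed / non-stressed ratio defines module differential
#' connectivity.
#'
#' @param adj Adjacency matrix.
#' @param genes Module gene set (size >= 2), subset of the matrix's genes.
#' @return Scalar connectivity sum.
#' @export
module_connectivity <- function(adj, genes) {
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("module must have at least 2 genes")
  if (!all(genes %in% rownames(adj))) stop("module genes missing from adjacency")
  sub <- adj[genes, genes]
  sum(sub[lower.tri(sub)])
}

condition_connectivity <- function(expr, genes, beta, kind, estimator) {
  a <- adjacency(expr[genes, , drop = FALSE], beta, kind, estimator)
  sum(a[lower.tri(a)])
}

#' Module differential connectivity ratio
#'
#' Adjacency is computed independently per condition on the same gene set
#' and the MDC is `connectivity_stress / connectivity_ctrl`; MDC > 1 is a
#' gain of connectivity under stress, MDC < 1 a loss.
#'
#' @param expr_stress,expr_ctrl log2 expression matrices for the two
#'   conditions (>= 4 samples each) sharing the gene universe.
#' @param genes Module gene set.
#' @param beta,kind,estimator Adjacency parameters shared by both
#'   conditions.
#' @return List with `mdc`, `connectivity_stress`, `connectivity_ctrl`;
#'   `mdc` is `NA` (with a warning) when the control connectivity is 0.
#' @export
mdc_ratio <- function(expr_stress, expr_ctrl, genes, beta = 6,
                      kind = "unsigned", estimator = "pearson") {
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("module must have at least 2 genes")
  cs <- condition_connectivity(expr_stress, genes, beta, kind, estimator)
  cc <- condition_connectivity(expr_ctrl, genes, beta, kind, estimator)
  mdc <- if (cc == 0) {
    warning("control connectivity is 0; MDC undefined")
    NA_real_
  } else cs / cc
  list(mdc = mdc, connectivity_stress = cs, connectivity_ctrl = cc)
}

#' Permutation test for module differential connectivity
#'
#' Two null schemes: `shuffled_samples` replaces the module's connections
#' with random connections from each condition's network — the null
#' connectivity sum is that of a uniformly random gene clique of equal
#' size, drawn independently for the stressed and non-stressed matrices.
#' (Connections are randomized in clique blocks rather than as
#' independent lower-triangle values because the connectivity sum of any
#' real gene set carries gene-level dependence — each gene contributes to
#' all its pairs — and ignoring it makes the null too narrow.)
#' `shuffled_genes` replaces the module by a single uniformly random gene
#' set of equal size used in both conditions (random nodes, real
#' connections).  A condition-label permutation variant
#' (`shuffled_labels`: stress/control labels permuted across the pooled
#' samples, adjacency recomputed) is also available.  The two-sided p
#' value uses the add-one estimator
#' `(1 + #{|log MDC_null| >= |log MDC_obs|}) / (n_perm + 1)` on the
#' |log MDC| scale.
#'
#' @param expr_stress,expr_ctrl Condition expression matrices over the
#'   full gene universe.
#' @param genes Module gene set.
#' @param scheme `"shuffled_samples"`, `"shuffled_genes"` or
#'   `"shuffled_labels"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param beta,kind,estimator Adjacency parameters.
#' @return List with `p_value`, `mdc`, `scheme`, `n_perm`, `null_mdc`.
#' @export
mdc_permutation_test <- function(expr_stress, expr_ctrl, genes,
                                 scheme = c("shuffled_samples",
                                            "shuffled_genes",
                                            "shuffled_labels"),
                                 n_perm = 1000, seed = 1L, beta = 6,
                                 kind = "unsigned", estimator = "pearson") {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop("n_perm must be at least 100")
  genes <- as.character(genes)
  obs <- mdc_ratio(expr_stress, expr_ctrl, genes, beta, kind, estimator)
  if (!is.finite(obs$mdc) || obs$mdc <= 0) {
    stop("observed MDC is undefined; cannot test")
  }
  log_obs <- abs(log(obs$mdc))
  set.seed(seed)
  null_mdc <- numeric(n_perm)
  if (scheme == "shuffled_samples") {
    universe <- intersect(rownames(expr_stress), rownames(expr_ctrl))
    for (i in seq_len(n_perm)) {
      cs <- condition_connectivity(expr_stress, sample(universe, length(genes)),
                                   beta, kind, estimator)
      cc <- condition_connectivity(expr_ctrl, sample(universe, length(genes)),
                                   beta, kind, estimator)
      null_mdc[i] <- cs / cc
    }
  } else if (scheme == "shuffled_genes") {
    universe <- intersect(rownames(expr_stress), rownames(expr_ctrl))
    for (i in seq_len(n_perm)) {
      gr <- sample(universe, length(genes))
      cs <- condition_connectivity(expr_stress, gr, beta, kind, estimator)
      cc <- condition_connectivity(expr_ctrl, gr, beta, kind, estimator)
      null_mdc[i] <- cs / cc
    }
  } else {
    pooled <- cbind(expr_stress[genes, , drop = FALSE],
                    expr_ctrl[genes, , drop = FALSE])
    ns <- ncol(expr_stress)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(ncol(pooled))
      cs <- condition_connectivity(pooled[, idx[seq_len(ns)], drop = FALSE],
                                   genes, beta, kind, estimator)
      cc <- condition_connectivity(pooled[, idx[-seq_len(ns)], drop = FALSE],
                                   genes, beta, kind, estimator)
      null_mdc[i] <- cs / cc
    }
  }
  log_null <- abs(log(null_mdc))
  extreme <- sum(!is.finite(log_null) | log_null >= log_obs)
  list(p_value = (1 + extreme) / (n_perm + 1), mdc = obs$mdc,
       connectivity_stress = obs$connectivity_stress,
       connectivity_ctrl = obs$connectivity_ctrl,
       scheme = scheme, n_perm = n_perm, null_mdc = null_mdc)
}

#' Classify modules as gained, lost or unchanged
#'
#' Benjamini-Hochberg correction is applied separately within each
#' shuffling scheme across modules; a module is called `gained` if
#' MDC > 1 and both scheme q values fall below `q_max`, `lost` if MDC < 1
#' with both q values below `q_max`, and `unchanged` otherwise.
#'
#' @param results data.frame with one row per module and columns `module`,
#'   `mdc`, `p_shuffled_samples`, `p_shuffled_genes` (e.g. assembled from
#'   [mdc_permutation_test()] runs).
#' @param q_max Significance threshold on the q values (default 0.05).
#' @return The input with `q_shuffled_samples`, `q_shuffled_genes` and
#'   `call` columns added, plus a `proportions` attribute with the
#'   gained/lost/unchanged shares.
#' @export
classify_modules <- function(results, q_max = 0.05) {
  stopifnot(all(c("module", "mdc", "p_shuffled_samples",
                  "p_shuffled_genes") %in% names(results)))
  results$q_shuffled_samples <- p.adjust(results$p_shuffled_samples, "BH")
  results$q_shuffled_genes <- p.adjust(results$p_shuffled_genes, "BH")
  sig <- results$q_shuffled_samples < q_max &
         results$q_shuffled_genes < q_max
  results$call <- ifelse(sig & results$mdc > 1, "gained",
                  ifelse(sig & results$mdc < 1, "lost", "unchanged"))
  prop <- table(factor(results$call,
                       levels = c("gained", "lost", "unchanged"))) /
          nrow(results)
  attr(results, "proportions") <- prop
  class(results) <- c("mdc_result", "data.frame")
  results
}
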