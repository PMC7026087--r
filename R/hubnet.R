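#' Build a condition-specific gene network
#'
#' With `method = "correlation"` an edge joins two genes when the absolute
#' Spearman correlation exceeds either a fixed `edge_threshold` or a
#' permutation-calibrated threshold controlling the empirical FDR at
#' `fdr`.  With `method = "mutual_information"` pairwise mutual
#' information is estimated by equal-frequency binning
#' (`floor(sqrt(n_samples))` bins), thresholded by the same permutation
#' FDR, and pruned by the data-processing inequality: in every triangle
#' the weakest edge is removed when it is weaker than both others by more
#' than `dpi_tolerance`.
#'
#' @param expr log2 expression matrix (>= 4 samples).
#' @param method `"correlation"` or `"mutual_information"`.
#' @param edge_threshold Fixed score threshold; `NULL` (default) uses the
#'   permutation calibration.
#' @param fdr Target empirical FDR for the permutation calibration.
#' @param n_perm Permutations used for calibration.
#' @param seed RNG seed.
#' @param dpi_tolerance DPI tolerance (mutual information only).
#' @return Object of class `gene_network`: `genes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `score` with `gene_a < gene_b`), `method`,
#'   `threshold`.
#' @export
build_condition_network <- function(expr,
                                    method = c("correlation",
                                               "mutual_information"),
                                    edge_threshold = NULL, fdr = 0.05,
                                    n_perm = 20, seed = 1L,
                                    dpi_tolerance = 0.1) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  genes <- rownames(expr)
  set.seed(seed)
  if (method == "correlation") {
    score <- abs(suppressWarnings(cor(t(expr), method = "spearman")))
    score[!is.finite(score)] <- 0
  } else {
    score <- mi_matrix(expr)
  }
  diag(score) <- 0
  if (is.null(edge_threshold)) {
    null_vals <- unlist(lapply(seq_len(n_perm), function(i) {
      perm <- t(apply(expr, 1L, sample))
      s <- if (method == "correlation") {
        abs(suppressWarnings(cor(t(perm), method = "spearman")))
      } else mi_matrix(perm)
      s[upper.tri(s)]
    }))
    edge_threshold <- calibrate_threshold(score[upper.tri(score)],
                                          null_vals, n_perm, fdr)
  }
  keep <- which(upper.tri(score) & score > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[keep[, 1]], gene_b = genes[keep[, 2]],
                      score = score[keep], stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  net <- structure(list(genes = genes, edges = edges, method = method,
                        threshold = edge_threshold), class = "gene_network")
  if (method == "mutual_information") net <- dpi_prune(net, dpi_tolerance)
  net
}

# smallest score whose empirical FDR (mean null exceedances over observed
# exceedances) stays at or below the target; returned as an exclusive
# threshold sitting just below that score
calibrate_threshold <- function(obs, null_vals, n_perm, fdr) {
  cand <- sort(unique(obs), decreasing = TRUE)
  if (length(cand) == 0L) return(1)
  ns <- sort(null_vals)
  os <- sort(obs)
  ok <- vapply(cand, function(t) {
    n_obs <- length(os) - findInterval(t, os, left.open = TRUE)
    n_null <- (length(ns) - findInterval(t, ns, left.open = TRUE)) / n_perm
    n_obs > 0 && n_null / n_obs <= fdr
  }, logical(1))
  if (!any(ok)) return(max(cand))   # strict '>' excludes everything
  best <- min(cand[ok])
  prev <- os[os < best]
  if (length(prev)) (max(prev) + best) / 2 else best / 2
}

mi_matrix <- function(expr) {
  n <- ncol(expr)
  bins <- max(2L, floor(sqrt(n)))
  binned <- t(apply(expr, 1L, function(x) {
    as.integer(cut(rank(x, ties.method = "first"),
                   breaks = bins, labels = FALSE))
  }))
  g <- nrow(expr)
  mi <- matrix(0, g, g, dimnames = list(rownames(expr), rownames(expr)))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      tab <- table(binned[i, ], binned[j, ]) / n
      pi_ <- rowSums(tab); pj <- colSums(tab)
      nz <- tab > 0
      v <- sum(tab[nz] * log(tab[nz] / outer(pi_, pj)[nz]))
      mi[i, j] <- mi[j, i] <- v
    }
  }
  mi
}

# data-processing-inequality pruning: mark, then drop, the weakest edge of
# every fully connected triangle when clearly weaker than the other two
dpi_prune <- function(net, tolerance = 0.1) {
  e <- net$edges
  if (nrow(e) < 3L) return(net)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  score <- setNames(e$score, key(e$gene_a, e$gene_b))
  adj <- split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
  drop <- character(0)
  for (i in seq_len(nrow(e))) {
    a <- e$gene_a[i]; b <- e$gene_b[i]
    common <- intersect(adj[[a]], adj[[b]])
    for (u in common) {
      s_ab <- e$score[i]
      s_au <- score[[key(a, u)]]
      s_bu <- score[[key(b, u)]]
      trio <- c(ab = s_ab, au = s_au, bu = s_bu)
      w <- which.min(trio)
      if (trio[w] < min(trio[-w]) - tolerance) {
        pair <- switch(names(trio)[w], ab = key(a, b), au = key(a, u),
                       bu = key(b, u))
        drop <- c(drop, pair)
      }
    }
  }
  keep <- !(key(e$gene_a, e$gene_b) %in% drop)
  net$edges <- e[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = network$genes))
}

#' N-hop neighborhood node count
#'
#' Number of distinct nodes at shortest-path distance 1..`n_hops` from the
#' gene (unweighted hops over the network's edges), the NHNN statistic
#' used to define hubs.
#'
#' @param network A [build_condition_network()] result.
#' @param gene Gene id(s); default all nodes.
#' @param n_hops Neighborhood radius (>= 1).
#' @return Named integer vector of neighborhood sizes.
#' @export
nhnn <- function(network, gene = network$genes, n_hops = 2) {
  stopifnot(inherits(network, "gene_network"), n_hops >= 1)
  missing <- setdiff(gene, network$genes)
  if (length(missing)) {
    stop("gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  g <- as_igraph(network)
  sizes <- igraph::ego_size(g, order = n_hops, nodes = gene, mindist = 1)
  setNames(as.integer(sizes), gene)
}

#' Identify hub genes from the NHNN distribution
#'
#' A gene is a hub when its NHNN lies significantly above the average:
#' `(nhnn - mean) / sd > z_min` (default 2).  If the NHNN distribution is
#' degenerate (sd = 0) there are no hubs.
#'
#' @param network A `gene_network` (>= 10 nodes).
#' @param n_hops Neighborhood radius.
#' @param z_min Z threshold for hub status.
#' @return data.frame of class `hub_report`: `gene`, `nhnn`, `z`, `hub`;
#'   parameters stored as attributes.
#' @export
identify_hubs <- function(network, n_hops = 2, z_min = 2) {
  if (length(network$genes) < 10L) stop("need at least 10 nodes")
  nh <- nhnn(network, network$genes, n_hops)
  s <- sd(nh)
  z <- if (!is.finite(s) || s == 0) rep(0, length(nh)) else (nh - mean(nh)) / s
  rep_df <- data.frame(gene = network$genes, nhnn = unname(nh),
                       z = unname(z),
                       hub = if (s == 0 || !is.finite(s)) rep(FALSE, length(nh))
                             else unname(z) > z_min,
                       stringsAsFactors = FALSE)
  attr(rep_df, "n_hops") <- n_hops
  attr(rep_df, "z_min") <- z_min
  class(rep_df) <- c("hub_report", "data.frame")
  rep_df
}

#' Stress-specific hub genes
#'
#' Genes that attain hub status in the stressed-condition network but not
#' in the non-stressed one.
#'
#' @param report_stress,report_ctrl [identify_hubs()] reports over the
#'   same gene universe.
#' @return Character vector of stress-specific hub genes.
#' @export
stress_specific_hubs <- function(report_stress, report_ctrl) {
  if (!setequal(report_stress$gene, report_ctrl$gene)) {
    stop("hub reports cover different gene universes")
  }
  setdiff(report_stress$gene[report_stress$hub],
          report_ctrl$gene[report_ctrl$hub])
}

#' Export a high-score edge list
#'
#' Edges with score strictly above `score_min` (the study plotted
#' correlations greater than 0.95), in canonical `gene_a < gene_b` order
#' without duplicates — ready for Cytoscape-style import.
#'
#' @param network A `gene_network`.
#' @param score_min Score threshold (strict).
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
export_edges <- function(network, score_min = 0.95) {
  e <- network$edges[network$edges$score > score_min, , drop = FALSE]
  swap <- e$gene_a > e$gene_b
  tmp <- e$gene_a[swap]
  e$gene_a[swap] <- e$gene_b[swap]
  e$gene_b[swap] <- tmp
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Node attribute table for network visualization
#'
#' Joins hub status, stress-specific status and DE membership per gene.
#'
#' @param network A `gene_network`.
#' @param hub_report Optional [identify_hubs()] report.
#' @param stress_specific Optional character vector from
#'   [stress_specific_hubs()].
#' @param de_genes Optional character vector of DE genes.
#' @return data.frame with one row per node.
#' @export
node_table <- function(network, hub_report = NULL, stress_specific = NULL,
                       de_genes = NULL) {
  out <- data.frame(gene = network$genes, stringsAsFactors = FALSE)
  out$hub <- if (is.null(hub_report)) NA else
    out$gene %in% hub_report$gene[hub_report$hub]
  out$stress_specific_hub <- if (is.null(stress_specific)) NA else
    out$gene %in% stress_specific
  out$de <- if (is.null(de_genes)) NA else out$gene %in% de_genes
  out
}
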