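#' Soft-thresholded co-expression adjacency
#'
#' Pairwise gene-gene correlations across samples raised to the soft
#' power: `|r|^beta` for unsigned networks, `((1+r)/2)^beta` for signed.
#' Zero-variance genes get zero adjacency to every other gene; the
#' diagonal is 1 (it is excluded from all connectivity sums downstream).
#'
#' @param expr log2 expression matrix (genes x samples, >= 4 samples).
#' @param beta Soft power (>= 1).
#' @param kind `"unsigned"` or `"signed"`.
#' @param estimator `"pearson"` or `"spearman"`.
#' @return Symmetric gene x gene adjacency matrix with entries in [0, 1].
#' @export
adjacency <- function(expr, beta = 6, kind = c("unsigned", "signed"),
                      estimator = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 4L) stop("adjacency needs at least 4 samples")
  if (beta < 1) stop("beta must be >= 1")
  r <- suppressWarnings(cor(t(expr), method = estimator))
  r[!is.finite(r)] <- 0
  a <- if (kind == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(c(r_squared = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(c(r_squared = NA_real_, slope = NA_real_))
  x <- log10(kmean[ok]); y <- log10(freq[ok])
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2]
  c(r_squared = if (!is.na(slope) && slope > 0) -r2 else r2,
    slope = unname(slope))
}

#' Choose the soft power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned (10
#' bins) and the squared correlation of log10 frequency vs log10
#' connectivity computed, sign-flipped when the slope is positive.  The
#' smallest power reaching a fit of `r2_min` is chosen; if none does, the
#' power with the best fit is chosen and flagged.
#'
#' @param expr log2 expression matrix.
#' @param candidate_betas Candidate powers.
#' @param r2_min Scale-free fit target (default 0.8).
#' @param kind,estimator Passed to [adjacency()].
#' @return List with `beta`, `reached_target`, and the per-candidate
#'   `fit_table` (beta, r_squared, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, candidate_betas = c(1:10, 12, 14, 16),
                                r2_min = 0.8,
                                kind = "unsigned", estimator = "pearson") {
  if (length(candidate_betas) == 0L) stop("no candidate powers supplied")
  rows <- lapply(candidate_betas, function(b) {
    a <- adjacency(expr, beta = b, kind = kind, estimator = estimator)
    k <- rowSums(a) - 1
    f <- scale_free_fit(k)
    data.frame(beta = b, r_squared = f[["r_squared"]],
               slope = f[["slope"]], mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= r2_min)
  if (length(hit) > 0L) {
    beta <- tab$beta[hit[1]]
    reached <- TRUE
  } else {
    beta <- tab$beta[which.max(tab$r_squared)]
    reached <- FALSE
  }
  list(beta = beta, reached_target = reached, fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k` the row sums excluding the diagonal; `TOM_ii = 1`.
#'
#' @param adj Adjacency matrix from [adjacency()].
#' @return TOM similarity matrix in [0, 1].
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom
}

module_color_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of genes on the TOM
#' dissimilarity `1 - TOM`, cut statically at `cut_height`; clusters
#' smaller than `min_size` are left unassigned ("grey").  Surviving
#' modules are labelled by decreasing size onto a fixed color list.
#'
#' A static cut tends to absorb weakly connected bystander genes (their
#' low total connectivity inflates the topological overlap).  When the
#' expression matrix is supplied, membership is therefore pruned by
#' module-eigengene correlation: genes whose |kME| (correlation with the
#' module's first principal component) falls below `kme_min` are returned
#' to grey before sizes are re-checked.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_size Minimum module size (default 30).
#' @param cut_height Static cut height on 1 - TOM (default 0.99).
#' @param expr Optional expression matrix (same genes as `tom`) enabling
#'   kME pruning.
#' @param kme_min Minimum |kME| for module membership when pruning.
#' @return List of class `module_set`: `colors` (named gene -> label,
#'   "grey" = unassigned), `dendrogram` (hclust object), `sizes`,
#'   `cut_height`, `min_size`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.99,
                           expr = NULL, kme_min = 0.65) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  genes <- rownames(tom)
  h <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(h, h = cut_height)
  if (!is.null(expr)) {
    stopifnot(all(genes %in% rownames(expr)))
    for (cid in unique(cl)) {
      members <- which(cl == cid)
      if (length(members) < min_size) next
      x <- t(scale(t(expr[genes[members], , drop = FALSE])))
      pc1 <- prcomp(t(x), center = FALSE, scale. = FALSE)$x[, 1]
      kme <- abs(as.vector(cor(t(x), pc1)))
      cl[members[kme < kme_min]] <- 0L   # back to unassigned
    }
  }
  sizes <- table(cl)
  sizes <- sizes[names(sizes) != "0"]
  big <- names(sizes)[sizes >= min_size]
  ord <- big[order(-sizes[big], as.integer(big))]
  palette <- module_color_palette()
  labels <- if (length(ord) > length(palette)) {
    c(palette, paste0("module", seq(length(palette) + 1, length(ord))))
  } else palette
  map <- setNames(labels[seq_along(ord)], ord)
  colors <- setNames(rep("grey", length(cl)), genes)
  hit <- as.character(cl) %in% names(map)
  colors[hit] <- map[as.character(cl)[hit]]
  structure(list(colors = colors, dendrogram = h,
                 sizes = sort(table(colors), decreasing = TRUE),
                 cut_height = cut_height, min_size = min_size),
            class = "module_set")
}

module_gene_list <- function(modules) {
  cols <- modules$colors
  labs <- setdiff(unique(cols), "grey")
  setNames(lapply(labs, function(l) names(cols)[cols == l]), labs)
}

preservation_stats <- function(genes, expr_ref, expr_test, beta, kind,
                               estimator) {
  a_ref <- adjacency(expr_ref[genes, , drop = FALSE], beta, kind, estimator)
  a_test <- adjacency(expr_test[genes, , drop = FALSE], beta, kind, estimator)
  off <- lower.tri(a_test)
  density <- mean(a_test[off])
  k_ref <- rowSums(a_ref) - 1
  k_test <- rowSums(a_test) - 1
  conn <- suppressWarnings(cor(k_ref, k_test))
  if (!is.finite(conn)) conn <- 0
  c(density = density, connectivity = conn)
}

#' Permutation Z scores for module preservation
#'
#' For each module the density (mean within-module adjacency) and
#' connectivity (correlation of intramodular connectivity between the
#' reference and test networks) statistics are compared with their null
#' distribution over random gene sets of the same size, giving
#' `Z = (obs - mean_null) / sd_null` per statistic and
#' `Z_summary = mean(Z_density, Z_connectivity)`.  `Z_summary > 10` is
#' flagged as highly preserved.  A degenerate null (`sd = 0`) yields
#' `Z = 0` with a warning.
#'
#' @param modules A [detect_modules()] result (built on `expr_ref`'s
#'   network).
#' @param expr_ref,expr_test Expression matrices over the same genes.
#' @param n_perm Number of random gene sets (>= 50).
#' @param seed RNG seed.
#' @param beta,kind,estimator Network parameters, as in [adjacency()].
#' @return data.frame of class `preservation_score`: `module`, `size`,
#'   `Z_density`, `Z_connectivity`, `Z_summary`, `preserved`.
#' @export
module_preservation <- function(modules, expr_ref, expr_test, n_perm = 200,
                                seed = 1L, beta = 6, kind = "unsigned",
                                estimator = "pearson") {
  stopifnot(inherits(modules, "module_set"), n_perm >= 50)
  universe <- intersect(rownames(expr_ref), rownames(expr_test))
  mods <- module_gene_list(modules)
  set.seed(seed)
  out <- lapply(names(mods), function(lab) {
    genes <- mods[[lab]]
    if (length(genes) > length(universe)) {
      stop("module '", lab, "' is larger than the gene universe")
    }
    obs <- preservation_stats(genes, expr_ref, expr_test, beta, kind,
                              estimator)
    null <- vapply(seq_len(n_perm), function(i) {
      preservation_stats(sample(universe, length(genes)), expr_ref,
                         expr_test, beta, kind, estimator)
    }, numeric(2))
    z <- vapply(c("density", "connectivity"), function(st) {
      s <- sd(null[st, ])
      if (!is.finite(s) || s == 0) {
        warning("degenerate null (sd = 0) for ", st, " in module ", lab,
                "; Z set to 0")
        return(0)
      }
      (obs[[st]] - mean(null[st, ])) / s
    }, numeric(1))
    data.frame(module = lab, size = length(genes),
               Z_density = z[["density"]],
               Z_connectivity = z[["connectivity"]],
               Z_summary = mean(z), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$preserved <- res$Z_summary > 10
  class(res) <- c("preservation_score", "data.frame")
  res
}
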