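# shared fixtures, built in code at test time

toy_counts <- function(n_genes = 20, n_samples = 6, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

ranked_from <- function(p, direction, genes = sprintf("g%04d", seq_along(p))) {
  make_ranked_list(data.frame(gene = genes, p_value = p,
                              direction = direction,
                              stringsAsFactors = FALSE))
}

toy_network <- function(genes, gene_a, gene_b, score = 1) {
  structure(list(genes = genes,
                 edges = data.frame(gene_a = gene_a, gene_b = gene_b,
                                    score = score, stringsAsFactors = FALSE),
                 method = "correlation", threshold = 0),
            class = "gene_network")
}

# breadth-first-search oracle for the N-hop neighborhood statistic
bfs_nhnn <- function(network, gene, n_hops) {
  adj <- list()
  for (i in seq_len(nrow(network$edges))) {
    a <- network$edges$gene_a[i]; b <- network$edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- gene
  frontier <- gene
  for (h in seq_len(n_hops)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (length(nxt) == 0L) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) - 1L
}

random_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  genes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  toy_network(genes, genes[pairs[keep, 1]], genes[pairs[keep, 2]],
              score = runif(sum(keep), 0.5, 1))
}

# a small simulated dataset reused by several tests
sim_small <- function(seed = 1, n_genes = 400, module = NULL,
                      n_per_cell = 3, ...) {
  cfg <- sim_config(n_genes = n_genes, n_per_cell = n_per_cell,
                    genotypes = c("XX_F", "XY_M"), regions = c("BLA", "PFC"),
                    module_spec = if (is.null(module)) list() else list(module),
                    seed = seed, ...)
  design <- generate_design(cfg)
  out <- simulate_counts(cfg, design)
  list(cfg = cfg, design = design, counts = out$counts, truth = out$truth)
}
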