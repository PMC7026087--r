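test_that("adjacency matches the soft-power transform of correlations", {
  set.seed(1)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  r <- cor(t(expr))
  a1 <- adjacency(expr, beta = 1)
  expect_equal(a1[lower.tri(a1)], abs(r)[lower.tri(r)], tolerance = 1e-12)
  a6 <- adjacency(expr, beta = 6)
  expect_equal(a6[2, 5], abs(r[2, 5])^6, tolerance = 1e-12)
  asig <- adjacency(expr, beta = 2, kind = "signed")
  expect_equal(asig[3, 7], ((1 + r[3, 7]) / 2)^2, tolerance = 1e-12)

  # perfectly correlated pair
  expr2 <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = rnorm(10))
  expect_equal(adjacency(expr2, beta = 6)["a", "b"], 1)

  # zero-variance gene gets zero adjacency off-diagonal
  expr3 <- rbind(a = rep(1, 8), b = rnorm(8), c = rnorm(8))
  a3 <- adjacency(expr3, beta = 2)
  expect_true(all(a3["a", c("b", "c")] == 0))

  expect_error(adjacency(expr[, 1:3]), "4 samples")
  expect_error(adjacency(expr, beta = 0.5), "beta")
})

test_that("soft-threshold selection prefers scale-free fits", {
  # single-factor model with power-law-ish hubness gives scale-free k
  set.seed(2)
  n <- 300; ns <- 40
  h <- 0.95 * runif(n)^2
  z <- rnorm(ns)
  expr <- h %o% z + sqrt(1 - h^2) * matrix(rnorm(n * ns), n, ns)
  rownames(expr) <- sprintf("g%03d", 1:n)
  pick <- pick_soft_threshold(expr, candidate_betas = c(2, 4, 6, 8))
  expect_true(pick$reached_target)
  expect_gte(max(pick$fit_table$r_squared, na.rm = TRUE), 0.8)

  # pure noise: a full table comes back and the fallback is flagged
  noise <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(sprintf("g%03d", 1:200), NULL))
  pn <- pick_soft_threshold(noise, candidate_betas = c(1, 2))
  expect_equal(nrow(pn$fit_table), 2)
  expect_true(pn$beta %in% c(1, 2))

  single <- pick_soft_threshold(noise, candidate_betas = 7)
  expect_equal(single$beta, 7)
  expect_error(pick_soft_threshold(noise, numeric(0)), "candidate")
})

test_that("topological overlap matches the brute-force triple loop", {
  set.seed(3)
  a <- matrix(runif(100), 10, 10)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
  tom <- topological_overlap(a)
  for (i in 1:10) for (j in 1:10) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    shared <- sum(sapply(seq_len(10)[-c(i, j)], function(u) a[i, u] * a[u, j]))
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    expect_equal(tom[i, j],
                 (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
})

test_that("TOM stays in [0, 1] and handles sparse adjacency", {
  # two genes connected only to each other with weight 1
  a <- diag(3); a[1, 2] <- a[2, 1] <- 1
  dimnames(a) <- list(letters[1:3], letters[1:3])
  tom <- topological_overlap(a)
  expect_equal(tom["a", "b"], 1)
  expect_equal(tom["a", "c"], 0)   # no edge, no shared neighbors
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(400), 20, 20); m <- (m + t(m)) / 2; diag(m) <- 1
    tm <- topological_overlap(m)
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  }
})

test_that("planted modules are recovered and noise stays grey", {
  skip_if_not_installed("mclust")
  ids <- sim_gene_ids(800)
  mods <- list(planted_module(ids[1:40], 0.7, list(F = 0.7, M = 0.7)),
               planted_module(ids[41:80], 0.7, list(F = 0.7, M = 0.7)))
  cfg <- sim_config(n_genes = 800, n_per_cell = 3, module_spec = mods,
                    regions = "BLA", seed = 6)
  d <- generate_design(cfg)
  out <- simulate_counts(cfg, d)
  expr <- log_cpm(out$counts)
  tom <- topological_overlap(adjacency(expr))
  det <- detect_modules(tom, min_size = 30, cut_height = 0.99, expr = expr)
  truth <- ifelse(is.na(out$truth$module_assignment), "grey",
                  out$truth$module_assignment)
  expect_gte(mclust::adjustedRandIndex(det$colors, truth), 0.8)

  # order invariance: permuting the genes gives the same partition
  set.seed(7)
  perm <- sample(rownames(tom))
  det2 <- detect_modules(tom[perm, perm], min_size = 30, cut_height = 0.99,
                         expr = expr[perm, ])
  expect_equal(mclust::adjustedRandIndex(det$colors[perm], det2$colors), 1)

  # cut at the root merges everything into one module
  det3 <- detect_modules(tom, min_size = 30, cut_height = 1.0)
  expect_equal(length(setdiff(unique(det3$colors), "grey")), 1)
})

test_that("module preservation Z scores behave at the extremes", {
  ids <- sim_gene_ids(600)
  mod <- planted_module(ids[1:40], 0.7, list(F = 0.7, M = 0.7))
  cfg <- sim_config(n_genes = 600, n_per_cell = 3, module_spec = list(mod),
                    regions = "BLA", seed = 8)
  d <- generate_design(cfg)
  out <- simulate_counts(cfg, d)
  expr <- log_cpm(out$counts)
  modset <- structure(list(colors = setNames(
    ifelse(rownames(expr) %in% ids[1:40], "yellow", "grey"),
    rownames(expr))), class = "module_set")

  pres <- module_preservation(modset, expr, expr, n_perm = 80, seed = 9)
  expect_gt(pres$Z_summary, 10)
  expect_true(pres$preserved)

  # a degenerate null triggers the documented Z = 0 rule
  degenerate <- structure(list(colors = setNames(
    rep("blue", nrow(expr)), rownames(expr))), class = "module_set")
  w <- capture_warnings(p0 <- module_preservation(degenerate, expr, expr,
                                                  n_perm = 50, seed = 1))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(p0$Z_summary, 0)

  expect_error(module_preservation(
    structure(list(colors = setNames(c("red", "red"), c("zz1", "zz2"))),
              class = "module_set"), expr[1, , drop = FALSE],
    expr[1, , drop = FALSE], n_perm = 50), "universe")
})

test_that("preservation Z grows with planted correlation", {
  ids <- sim_gene_ids(500)
  zs <- sapply(c(0.3, 0.7), function(r) {
    mod <- planted_module(ids[1:40], r, list(F = r, M = r))
    cfg <- sim_config(n_genes = 500, n_per_cell = 3,
                      module_spec = list(mod), regions = "BLA", seed = 10)
    d <- generate_design(cfg)
    out <- simulate_counts(cfg, d)
    expr <- log_cpm(out$counts)
    stress <- d$sample_id[d$stress == "stress"]
    ctrl <- d$sample_id[d$stress == "ctrl"]
    modset <- structure(list(colors = setNames(
      ifelse(rownames(expr) %in% ids[1:40], "yellow", "grey"),
      rownames(expr))), class = "module_set")
    module_preservation(modset, expr[, stress], expr[, ctrl],
                        n_perm = 60, seed = 2)$Z_summary
  })
  expect_gt(zs[2], zs[1])
})
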