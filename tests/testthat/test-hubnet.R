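test_that("nhnn equals the breadth-first-search oracle on random graphs", {
  for (seed in 1:10) {
    net <- random_network(30, 0.08, seed)
    for (hops in 1:3) {
      ours <- nhnn(net, net$genes, n_hops = hops)
      oracle <- vapply(net$genes, function(g) bfs_nhnn(net, g, hops),
                       integer(1))
      expect_identical(unname(ours), unname(oracle))
    }
    # monotone in the hop radius
    n1 <- nhnn(net, net$genes, 1); n3 <- nhnn(net, net$genes, 3)
    expect_true(all(n3 >= n1))
  }
})

test_that("nhnn handles isolated nodes, paths and absent genes", {
  net <- toy_network(c("a", "b", "c", "d", "e"),
                     c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(unname(nhnn(net, "e", 5)), 0)       # isolated
  expect_equal(unname(nhnn(net, "a", 2)), 2)       # path a-b-c-d
  expect_equal(unname(nhnn(net, "a", 3)), 3)
  expect_error(nhnn(net, "zz", 1), "not in network")
})

test_that("star centers are hubs and regular lattices have none", {
  nm <- sprintf("n%02d", 1:21)
  star <- toy_network(nm, rep("n01", 20), nm[-1])
  rep_star <- identify_hubs(star, n_hops = 1)
  expect_identical(rep_star$gene[rep_star$hub], "n01")

  # ring lattice: every node has the same neighborhood size, sd = 0
  ring <- toy_network(nm, nm, nm[c(2:21, 1)])
  rep_ring <- identify_hubs(ring, n_hops = 2)
  expect_false(any(rep_ring$hub))

  expect_error(identify_hubs(toy_network(letters[1:5], "a", "b")),
               "at least 10")
})

test_that("two planted star centers are recovered among noise", {
  set.seed(30)
  genes <- sprintf("n%03d", 1:60)
  # two stars over disjoint leaf sets plus sparse random background
  ea <- cbind("n001", genes[2:21])
  eb <- cbind("n031", genes[32:51])
  pairs <- which(upper.tri(diag(60)), arr.ind = TRUE)
  bg <- pairs[runif(nrow(pairs)) < 0.01, , drop = FALSE]
  net <- toy_network(genes,
                     c(ea[, 1], eb[, 1], genes[bg[, 1]]),
                     c(ea[, 2], eb[, 2], genes[bg[, 2]]))
  hubs <- identify_hubs(net, n_hops = 1)
  expect_true(all(c("n001", "n031") %in% hubs$gene[hubs$hub]))
  expect_lte(sum(hubs$hub), 4)
})

test_that("stress-specific hubs obey the set algebra", {
  mk_report <- function(genes, hubs) {
    structure(data.frame(gene = genes, nhnn = 1, z = 0,
                         hub = genes %in% hubs,
                         stringsAsFactors = FALSE),
              class = c("hub_report", "data.frame"))
  }
  genes <- sprintf("g%02d", 1:30)
  expect_identical(stress_specific_hubs(mk_report(genes, genes[1:5]),
                                        mk_report(genes, genes[1:5])),
                   character(0))
  expect_identical(stress_specific_hubs(mk_report(genes, genes[1:5]),
                                        mk_report(genes, genes[3:8])),
                   genes[1:2])
  for (seed in 1:5) {
    set.seed(seed)
    hs <- sample(genes, 8); hc <- sample(genes, 8)
    ss <- stress_specific_hubs(mk_report(genes, hs), mk_report(genes, hc))
    expect_setequal(ss, setdiff(hs, hc))
    expect_length(intersect(ss, hc), 0)
  }
  expect_error(stress_specific_hubs(mk_report(genes, genes[1]),
                                    mk_report(genes[-1], genes[2])),
               "universes")
})

test_that("edge export uses a strict threshold and canonical ordering", {
  net <- toy_network(c("b", "a", "c"), c("b", "c"), c("a", "a"),
                     score = c(0.96, 0.94))
  e <- export_edges(net, 0.95)
  expect_equal(nrow(e), 1)
  expect_equal(e$gene_a, "a")   # canonical gene_a < gene_b
  expect_equal(e$gene_b, "b")
  expect_equal(nrow(export_edges(net, 1.0)), 0)
  nt <- node_table(net, hub_report = NULL, stress_specific = "a",
                   de_genes = c("b", "c"))
  expect_true(nt$stress_specific_hub[nt$gene == "a"])
  expect_false(nt$de[nt$gene == "a"])
})

test_that("correlation networks recover duplicated genes and stay sparse on noise", {
  set.seed(31)
  base <- rnorm(24)
  expr <- rbind(dup1 = base + rnorm(24, sd = 1e-6), dup2 = base,
                matrix(rnorm(30 * 24), 30, 24,
                       dimnames = list(sprintf("g%02d", 1:30), NULL)))
  net <- build_condition_network(expr, "correlation", seed = 2)
  e <- export_edges(net, score_min = 0.9)
  expect_true(any(e$gene_a == "dup1" & e$gene_b == "dup2"))

  noise <- matrix(rnorm(40 * 20), 40, 20,
                  dimnames = list(sprintf("g%02d", 1:40), NULL))
  nn <- build_condition_network(noise, "correlation", fdr = 0.05,
                                n_perm = 20, seed = 3)
  expect_lte(nrow(nn$edges), 0.05 * choose(40, 2))
})

test_that("fixed edge thresholds bypass the calibration", {
  set.seed(32)
  expr <- matrix(rnorm(10 * 12), 10, 12,
                 dimnames = list(letters[1:10], NULL))
  net <- build_condition_network(expr, "correlation", edge_threshold = 0.99)
  expect_equal(nrow(net$edges), 0)
  expect_error(build_condition_network(expr, "nope"))
  expect_error(build_condition_network(expr[, 1:3]), "4 samples")
})

test_that("data-processing-inequality pruning removes indirect edges", {
  set.seed(33)
  n <- 120
  a <- rnorm(n); b <- rnorm(n)
  cc <- a + b + rnorm(n, sd = 0.3)
  expr <- rbind(A = a, B = b, C = cc)
  net <- build_condition_network(expr, "mutual_information",
                                 edge_threshold = 0, seed = 4)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_false("A B" %in% key)   # indirect edge pruned by DPI
  expect_true("A C" %in% key && "B C" %in% key)

  # pruning never adds edges: result is a subset of the unpruned graph
  set.seed(34)
  expr2 <- matrix(rnorm(8 * 50), 8, 50,
                  dimnames = list(letters[1:8], NULL))
  pruned <- build_condition_network(expr2, "mutual_information",
                                    edge_threshold = 0.05, seed = 5)
  full_mi <- build_condition_network(expr2, "mutual_information",
                                     edge_threshold = 0.05, seed = 5,
                                     dpi_tolerance = Inf)
  k1 <- paste(pruned$edges$gene_a, pruned$edges$gene_b)
  k2 <- paste(full_mi$edges$gene_a, full_mi$edges$gene_b)
  expect_true(all(k1 %in% k2))
})
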