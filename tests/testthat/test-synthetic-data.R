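test_that("generate_design produces the factorial layout", {
  cfg <- sim_config(n_genes = 10, n_per_cell = 3)
  d <- generate_design(cfg)
  expect_equal(nrow(d), 72)                       # 3 x 4 x 3 x 2
  counts <- table(d$genotype, d$stress, d$region)
  expect_true(all(counts == 3))

  d1 <- generate_design(sim_config(n_genes = 5, n_per_cell = 1,
                                   genotypes = "XX_F", regions = "BLA"))
  expect_equal(nrow(d1), 2)

  d2 <- generate_design(sim_config(n_genes = 5, n_per_cell = 2))
  expect_true(all(table(d2$genotype, d2$stress, d2$region) == 2))
})

test_that("genotypes decompose into gonadal and genetic sex", {
  d <- generate_design(sim_config(n_genes = 5, n_per_cell = 1))
  m <- unique(d[, c("genotype", "gonadal_sex", "genetic_sex")])
  m <- m[order(m$genotype), ]
  expect_equal(m$gonadal_sex[m$genotype == "XX_F"], "F")
  expect_equal(m$genetic_sex[m$genotype == "XX_F"], "XX")
  expect_equal(m$gonadal_sex[m$genotype == "XY_F"], "F")
  expect_equal(m$genetic_sex[m$genotype == "XY_F"], "XY")
  expect_equal(m$gonadal_sex[m$genotype == "XX_M"], "M")
  expect_equal(m$genetic_sex[m$genotype == "XX_M"], "XX")
  expect_equal(m$gonadal_sex[m$genotype == "XY_M"], "M")
  expect_equal(m$genetic_sex[m$genotype == "XY_M"], "XY")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, genotypes = character(0)),
               "non-empty")
  expect_error(sim_config(n_genes = 10, de_frac_gonadal = 0.7,
                          de_frac_genetic = 0.7), "sum")
  expect_error(sim_config(n_genes = 10, de_frac_gonadal = -0.1), "0,1")
  expect_error(planted_module(c("a", "b"), 0.5, list(F = 0.5, M = 0.5)),
               "at least 3")
  expect_error(planted_module(c("a", "b", "c"), 1.0,
                              list(F = 0.5, M = 0.5)), "\\[0, 1\\)")
  expect_error(sim_config(n_genes = 10, stress_effect_spec = list(
    list(genes = "nope", region = "BLA", sex = "F", log2_effect = 1))),
    "universe")
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- sim_small(seed = 42)
  s2 <- sim_small(seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$de_genes_by_contrast, s2$truth$de_genes_by_contrast)
  s3 <- sim_small(seed = 43)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("null configuration has empty truth and valid counts", {
  s <- sim_small(seed = 7)
  expect_true(all(s$counts >= 0))
  expect_type(s$counts[1, 1], "integer")
  expect_identical(colnames(s$counts), s$design$sample_id)
  expect_equal(nrow(s$truth$de_genes_by_contrast$sex), 0)
  expect_true(all(is.na(s$truth$module_assignment)))
  expect_length(s$truth$stress_de, 0)
})

test_that("planted effects land in truth with the right attribution", {
  cfg <- sim_config(n_genes = 1000, n_per_cell = 3,
                    de_frac_gonadal = 0.05, de_frac_genetic = 0.03,
                    de_frac_both = 0.02, seed = 3)
  d <- generate_design(cfg)
  out <- simulate_counts(cfg, d)
  att <- out$truth$attribution
  expect_equal(sum(att == "gonadal"), 50)
  expect_equal(sum(att == "genetic"), 30)
  expect_equal(sum(att == "both"), 20)
  tr <- out$truth$de_genes_by_contrast
  expect_setequal(tr$gonadal$gene, names(att)[att %in% c("gonadal", "both")])
  expect_setequal(tr$genetic$gene, names(att)[att %in% c("genetic", "both")])
  expect_true(all(tr$sex$effect != 0))
})

test_that("realized module correlations track the requested latent values", {
  ids <- sim_gene_ids(800)
  mod <- planted_module(ids[1:30], 0.7, list(F = 0.7, M = 0.7))
  s <- sim_small(seed = 11, n_genes = 800, module = mod, n_per_cell = 6)
  chk <- planted_module_cor_check(s$counts, s$truth)
  # >= 12 samples in every condition of this design
  expect_true(all(chk$n_samples >= 12))
  expect_true(all(abs(chk$realized - chk$target) < 0.1))

  mod0 <- planted_module(ids[1:30], 0.0, list(F = 0, M = 0))
  s0 <- sim_small(seed = 12, n_genes = 800, module = mod0, n_per_cell = 6)
  chk0 <- planted_module_cor_check(s0$counts, s0$truth)
  expect_true(all(abs(chk0$realized) < 0.15))
})

test_that("unattainable module correlations raise a configuration error", {
  ids <- sim_gene_ids(100)
  mod <- planted_module(ids[1:10], 0.5, list(F = 0.99, M = 0.5),
                        baseline_log2_range = c(6, 8), dispersion = 0.4)
  cfg <- sim_config(n_genes = 100, module_spec = list(mod), seed = 1)
  d <- generate_design(cfg)
  expect_error(simulate_counts(cfg, d), "ceiling")
})

test_that("coherence plan derives concordance from planted stress effects", {
  ids <- sim_gene_ids(300)
  cfg <- sim_config(n_genes = 300, stress_effect_spec = list(
    list(genes = ids[1:50], region = "BLA", sex = "F", log2_effect = 1),
    list(genes = ids[1:50], region = "NAc", sex = "F", log2_effect = -1),
    list(genes = ids[51:90], region = "PFC", sex = "M", log2_effect = 0.8),
    list(genes = ids[51:90], region = "NAc", sex = "M", log2_effect = 0.8)),
    seed = 2)
  plan <- simulate_counts(cfg, generate_design(cfg))$truth$coherence_plan
  kinds <- vapply(plan, `[[`, "", "kind")
  sexes <- vapply(plan, `[[`, "", "sex")
  expect_equal(unname(kinds[sexes == "F"]), "discordant")
  expect_equal(unname(kinds[sexes == "M"]), "concordant")
})
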