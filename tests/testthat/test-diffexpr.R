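make_toy_de <- function() {
  set.seed(10)
  expr <- matrix(rnorm(200 * 12, 6, 1), 200, 12,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("s%02d", 1:12)))
  design <- data.frame(sample_id = colnames(expr),
                       group = rep(c("a", "b"), each = 6),
                       stringsAsFactors = FALSE)
  list(expr = expr, design = design,
       contrast = make_contrast("ab", list(group = "a"), list(group = "b")))
}

test_that("identical groups give zero effects and fold change one", {
  toy <- make_toy_de()
  expr <- cbind(toy$expr[, 1:6], toy$expr[, 1:6])
  colnames(expr) <- toy$design$sample_id
  res <- de_test(expr, toy$design, toy$contrast)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$fold_change == 1))
  expect_true(all(res$p_value == 1))
})

test_that("contrast resolution validates groups", {
  toy <- make_toy_de()
  bad <- make_contrast("bad", list(group = "a"), list(group = "zz"))
  expect_error(de_test(toy$expr, toy$design, bad), "empty group")
  overlap <- make_contrast("ov", list(group = "a"),
                           list(group = c("a", "b")))
  expect_error(de_test(toy$expr, toy$design, overlap), "overlap")
  tiny <- toy$design[c(1, 7:12), ]
  expect_error(de_test(toy$expr[, tiny$sample_id], tiny, toy$contrast),
               "at least 2")
})

test_that("welch results match t.test gene by gene", {
  toy <- make_toy_de()
  res <- de_test(toy$expr, toy$design, toy$contrast)
  for (g in sample(rownames(toy$expr), 5)) {
    tt <- t.test(toy$expr[g, 1:6], toy$expr[g, 7:12])
    expect_equal(res$p_value[res$gene == g], tt$p.value, tolerance = 1e-10)
    expect_equal(res$t_stat[res$gene == g], unname(tt$statistic),
                 tolerance = 1e-10)
  }
})

test_that("moderated t agrees with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(4)
  n <- 500
  expr <- matrix(rnorm(n * 12, 6, sqrt(rchisq(n, 4) / 4)), n, 12,
                 dimnames = list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:12)))
  design <- data.frame(sample_id = colnames(expr),
                       group = rep(c("a", "b"), each = 6))
  res <- de_test(expr, design,
                 make_contrast("ab", list(group = "a"), list(group = "b")),
                 moderated = TRUE)
  mm <- model.matrix(~ 0 + factor(rep(c("a", "b"), each = 6)))
  colnames(mm) <- c("a", "b")
  fit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(expr, mm),
                                            c(1, -1)))
  expect_gt(cor(res$t_stat, fit$t[, 1]), 0.999)
  expect_equal(res$log2fc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_lt(max(abs(res$p_value - fit$p.value[, 1])), 0.01)
})

test_that("call_de applies strict thresholds on raw p and fold change", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = log2(c(1.4, 1.3, 3.0, 1.5)),
                    fold_change = c(1.4, 1.3, 3.0, 1.5),
                    p_value = c(0.04, 0.04, 0.06, 0.001),
                    direction = 1)
  called <- call_de(res)
  expect_setequal(called$gene, c("a", "d"))   # b fails fc (strict), c fails p
})

test_that("call_de is monotone in its thresholds", {
  set.seed(2)
  res <- data.frame(gene = sprintf("g%03d", 1:300),
                    log2fc = rnorm(300),
                    p_value = runif(300), direction = 1)
  res$fold_change <- 2^abs(res$log2fc)
  base <- call_de(res, 0.05, 1.3)$gene
  expect_true(all(base %in% call_de(res, 0.10, 1.3)$gene))
  expect_true(all(base %in% call_de(res, 0.05, 1.1)$gene))
})

test_that("q values are a monotone step-up transform of p", {
  toy <- make_toy_de()
  res <- de_test(toy$expr, toy$design, toy$contrast)
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("attribution handles forced and degenerate cases", {
  sex <- data.frame(gene = c("a", "b", "c"), direction = c(1, -1, 1))
  v <- attribute_sex_differences(sex, sex, data.frame(gene = character(),
                                                      direction = numeric()))
  expect_equal(v$pct_gonadal, 100)
  expect_equal(v$pct_genetic, 0)
  expect_equal(unname(v$venn["sex_gonadal"]), 3)

  v2 <- attribute_sex_differences(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_equal(v2$pct_gonadal, 0)
  expect_equal(v2$pct_genetic, 0)
  expect_equal(sum(v2$venn), 6)

  # direction mismatch excluded only when required
  gon <- data.frame(gene = c("a", "b"), direction = c(-1, -1))
  v3 <- attribute_sex_differences(sex, gon, gon)
  expect_equal(v3$driven_gonadal, "b")
  v4 <- attribute_sex_differences(sex, gon, gon,
                                  require_direction_match = FALSE)
  expect_setequal(v4$driven_gonadal, c("a", "b"))
})

test_that("stress_overlap computes counts, jaccard and percentages", {
  a <- sprintf("g%02d", 1:10); b <- sprintf("g%02d", 6:15)
  ov <- stress_overlap(a, b)
  expect_equal(ov$n_intersect, 5)
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(ov$pct_of_a, 50)
  expect_equal(stress_overlap(a, a)$jaccard, 1)
  expect_equal(stress_overlap(a, sprintf("x%02d", 1:4))$n_intersect, 0)
})

test_that("gonadal-only planted effects are attributed to gonadal sex", {
  cfg <- sim_config(n_genes = 2000, n_per_cell = 5, de_frac_gonadal = 0.05,
                    regions = "BLA", seed = 31)
  d <- generate_design(cfg)
  out <- simulate_counts(cfg, d)
  expr <- log_cpm(out$counts)
  stratum <- list(stress = "ctrl", region = "BLA")
  de <- lapply(list(
    sex = make_contrast("sex", list(genotype = "XX_F"),
                        list(genotype = "XY_M"), stratum),
    gonadal = make_contrast("gon", list(gonadal_sex = "F"),
                            list(gonadal_sex = "M"), stratum),
    genetic = make_contrast("gen", list(genetic_sex = "XX"),
                            list(genetic_sex = "XY"), stratum)),
    function(ct) call_de(de_test(expr, d, ct, moderated = TRUE)))
  v <- attribute_sex_differences(de$sex, de$gonadal, de$genetic)
  expect_gt(v$pct_gonadal, 60)
  expect_gt(v$pct_gonadal, 3 * max(v$pct_genetic, 1))
})
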