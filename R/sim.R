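#' Gene identifiers used by the simulator
#'
#' Generates the ordered gene universe (`g00001`, `g00002`, ...) so that
#' planted gene sets in [sim_config()] can be specified before any counts
#' are drawn.
#'
#' @param n_genes Number of genes.
#' @return Character vector of length `n_genes`.
#' @export
sim_gene_ids <- function(n_genes) {
  width <- max(5L, nchar(as.character(n_genes)))
  sprintf("g%0*d", width, seq_len(n_genes))
}

#' Describe a planted co-expression module
#'
#' A module is a gene set sharing a latent factor whose within-module
#' correlation can differ between the non-stress condition and the stressed
#' condition of each gonadal sex, emulating stress-induced gain or loss of
#' co-expression that differs by sex.
#'
#' @param gene_ids Character vector of member genes (size >= 3).
#' @param cor_ctrl Target within-module correlation in non-stressed samples,
#'   in `[0, 1)`.
#' @param cor_stress_by_sex Named numeric vector/list with elements `F` and
#'   `M`: target within-module correlation in stressed samples of each
#'   gonadal sex, each in `[0, 1)`.
#' @param baseline_log2_range Range of per-gene log2 baseline means for the
#'   module's genes.  Module genes are planted among well-measured genes so
#'   that the requested correlation is attainable on top of counting noise.
#' @param dispersion Negative-binomial dispersion for the module's genes.
#' @param label Optional module label; defaults are assigned by position.
#' @return An object of class `planted_module`.
#' @export
planted_module <- function(gene_ids, cor_ctrl, cor_stress_by_sex,
                           baseline_log2_range = c(6, 10),
                           dispersion = 0.05, label = NULL) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 3L) {
    stop("a planted module needs at least 3 genes")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in module")
  cors <- c(ctrl = cor_ctrl,
            F = as.numeric(cor_stress_by_sex[["F"]]),
            M = as.numeric(cor_stress_by_sex[["M"]]))
  if (any(!is.finite(cors)) || any(cors < 0) || any(cors >= 1)) {
    stop("module correlations must lie in [0, 1)")
  }
  structure(list(gene_ids = gene_ids, cor_ctrl = cor_ctrl,
                 cor_stress_by_sex = list(F = cors[["F"]], M = cors[["M"]]),
                 baseline_log2_range = baseline_log2_range,
                 dispersion = dispersion, label = label),
            class = "planted_module")
}

#' Simulation configuration for the factorial FCG stress design
#'
#' Defines the study conditions the simulator emulates: a
#' genotype x stress x region factorial with `n_per_cell` replicates per
#' cell (the study design is 4 genotypes x 2 stress conditions x 3 regions
#' x 3 pooled replicates = 72 samples), negative-binomial counts, planted
#' sex effects attributable to gonadal sex, genetic sex or both, planted
#' region- and sex-specific stress effects, and planted co-expression
#' modules.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_per_cell Samples per genotype x stress x region cell.
#' @param genotypes FCG genotype labels, subset of
#'   `c("XX_F","XY_F","XX_M","XY_M")`.
#' @param regions Region labels.
#' @param baseline_log_mean_range Interval for the per-gene log2 baseline
#'   mean.  The default `c(3, 10)` spans moderately to highly expressed
#'   genes, as expected after low-expression filtering.
#' @param dispersion Negative-binomial dispersion: a scalar, a vector of
#'   length `n_genes`, or `NULL` to draw gene-wise dispersions log-uniform
#'   in `[0.05, 0.5]`.
#' @param lib_size_range Interval for library-size factors (log-uniform).
#' @param de_frac_gonadal,de_frac_genetic,de_frac_both Fractions of genes
#'   with planted sex effects of each attribution; must sum to at most 1.
#' @param de_effect Magnitude (log2) of planted sex effects; signs are
#'   random per gene.
#' @param stress_effect_spec List of entries
#'   `list(genes=, region=, sex=, log2_effect=)` where `region` is a region
#'   label or `"all"` and `sex` is `"F"`, `"M"` or `"both"` (gonadal sex).
#' @param module_spec List of [planted_module()] objects.
#' @param module_latent_sd Standard deviation (log2 scale) of the latent
#'   biological variation given to module genes.
#' @param seed RNG seed; the same seed gives bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_per_cell = 3,
                       genotypes = c("XX_F", "XY_F", "XX_M", "XY_M"),
                       regions = c("BLA", "PFC", "NAc"),
                       baseline_log_mean_range = c(3, 10),
                       dispersion = NULL,
                       lib_size_range = c(0.7, 1.4),
                       de_frac_gonadal = 0, de_frac_genetic = 0,
                       de_frac_both = 0, de_effect = 1.0,
                       stress_effect_spec = list(),
                       module_spec = list(),
                       module_latent_sd = 1.0,
                       seed = 1L) {
  if (length(genotypes) == 0L || length(regions) == 0L) {
    stop("genotypes and regions must be non-empty")
  }
  known <- c("XX_F", "XY_F", "XX_M", "XY_M")
  if (!all(genotypes %in% known)) {
    stop("genotypes must be a subset of ", paste(known, collapse = ", "))
  }
  fr <- c(de_frac_gonadal, de_frac_genetic, de_frac_both)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("DE fractions must lie in [0,1] and sum to at most 1")
  }
  if (n_genes < 1 || n_per_cell < 1) stop("n_genes and n_per_cell must be >= 1")
  universe <- sim_gene_ids(n_genes)
  for (sp in stress_effect_spec) {
    if (!all(c("genes", "region", "sex", "log2_effect") %in% names(sp))) {
      stop("stress_effect_spec entries need genes, region, sex, log2_effect")
    }
    if (!all(sp$genes %in% universe)) {
      stop("stress effect gene set is not a subset of the gene universe")
    }
    if (!sp$sex %in% c("F", "M", "both")) stop("stress effect sex must be F, M or both")
    if (!identical(sp$region, "all") && !all(sp$region %in% regions)) {
      stop("stress effect region not among configured regions")
    }
  }
  for (m in module_spec) {
    if (!inherits(m, "planted_module")) stop("module_spec entries must be planted_module objects")
    if (!all(m$gene_ids %in% universe)) {
      stop("module gene set is not a subset of the gene universe")
    }
  }
  mod_genes <- unlist(lapply(module_spec, `[[`, "gene_ids"))
  if (anyDuplicated(mod_genes)) stop("modules must not share genes")
  structure(list(n_genes = n_genes, n_per_cell = n_per_cell,
                 genotypes = genotypes, regions = regions,
                 baseline_log_mean_range = baseline_log_mean_range,
                 dispersion = dispersion, lib_size_range = lib_size_range,
                 de_frac_gonadal = de_frac_gonadal,
                 de_frac_genetic = de_frac_genetic,
                 de_frac_both = de_frac_both, de_effect = de_effect,
                 stress_effect_spec = stress_effect_spec,
                 module_spec = module_spec,
                 module_latent_sd = module_latent_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

genotype_sexes <- function(genotype) {
  parts <- strsplit(genotype, "_", fixed = TRUE)
  data.frame(genetic_sex = vapply(parts, `[`, "", 1L),
             gonadal_sex = vapply(parts, `[`, "", 2L))
}

#' Generate the factorial sample design
#'
#' One row per sample, with the FCG genotype decomposed into gonadal sex
#' (F/M, hormone exposure) and genetic sex (XX/XY, chromosome complement).
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `sample_id`, `genotype`, `gonadal_sex`,
#'   `genetic_sex`, `stress`, `region`.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(rep = seq_len(config$n_per_cell),
                       genotype = config$genotypes,
                       stress = c("ctrl", "stress"),
                       region = config$regions,
                       stringsAsFactors = FALSE)
  sx <- genotype_sexes(cells$genotype)
  design <- data.frame(
    sample_id = paste(cells$genotype, cells$stress, cells$region, cells$rep,
                      sep = "."),
    genotype = cells$genotype,
    gonadal_sex = sx$gonadal_sex,
    genetic_sex = sx$genetic_sex,
    stress = cells$stress,
    region = cells$region,
    stringsAsFactors = FALSE)
  rownames(design) <- NULL
  design
}

# measurement-noise variance of log2 expression for an NB gene (delta method)
nb_log2_noise_var <- function(mu, phi) {
  (1 / mu + phi) / log(2)^2
}

#' Simulate counts with planted sex, stress and module structure
#'
#' Counts are negative binomial around a log2 mean built from a per-gene
#' baseline plus every planted effect that applies to the sample's gonadal
#' sex, genetic sex, stress condition and region, scaled by a library-size
#' factor.  Module genes additionally share a per-sample latent factor; the
#' factor loading is chosen analytically (delta-method compensation for
#' counting noise) so that the realized gene-gene correlation matches the
#' requested value in each condition.
#'
#' @param config A [sim_config()].
#' @param design Output of [generate_design()] for `config`.
#' @return A list with elements `counts` (integer gene x sample matrix) and
#'   `truth` (class `sim_truth`): planted DE genes per contrast,
#'   gene attribution (gonadal/genetic/both), module assignment, the
#'   coherence plan implied by the stress effects, and the design.
#' @export
simulate_counts <- function(config, design) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(design))
  set.seed(config$seed)
  n <- config$n_genes
  ns <- nrow(design)
  genes <- sim_gene_ids(n)

  baseline <- runif(n, config$baseline_log_mean_range[1],
                    config$baseline_log_mean_range[2])
  phi <- config$dispersion
  if (is.null(phi)) {
    phi <- exp(runif(n, log(0.05), log(0.5)))
  } else if (length(phi) == 1L) {
    phi <- rep(phi, n)
  } else if (length(phi) != n) {
    stop("dispersion must be scalar or length n_genes")
  }
  lib <- exp(runif(ns, log(config$lib_size_range[1]),
                   log(config$lib_size_range[2])))
  names(baseline) <- names(phi) <- genes

  # module genes get overridden baselines/dispersions so the requested
  # correlations sit above the counting-noise floor
  module_assignment <- setNames(rep(NA_character_, n), genes)
  for (i in seq_along(config$module_spec)) {
    m <- config$module_spec[[i]]
    lab <- if (is.null(m$label)) paste0("M", i) else m$label
    config$module_spec[[i]]$label <- lab
    baseline[m$gene_ids] <- runif(length(m$gene_ids),
                                  m$baseline_log2_range[1],
                                  m$baseline_log2_range[2])
    phi[m$gene_ids] <- m$dispersion
    module_assignment[m$gene_ids] <- lab
  }

  # planted sex effects; drawn from genes free of module/stress structure
  mod_genes <- names(module_assignment)[!is.na(module_assignment)]
  stress_genes <- unique(unlist(lapply(config$stress_effect_spec, `[[`, "genes")))
  eligible <- setdiff(genes, c(mod_genes, stress_genes))
  n_gon <- round(config$de_frac_gonadal * n)
  n_gen <- round(config$de_frac_genetic * n)
  n_both <- round(config$de_frac_both * n)
  if (n_gon + n_gen + n_both > length(eligible)) {
    stop("not enough genes free of planted structure for the requested DE fractions")
  }
  pick <- sample(eligible, n_gon + n_gen + n_both)
  gon_genes <- pick[seq_len(n_gon)]
  gen_genes <- pick[n_gon + seq_len(n_gen)]
  both_genes <- pick[n_gon + n_gen + seq_len(n_both)]
  eff_sign <- setNames(sample(c(-1, 1), n_gon + n_gen + n_both, replace = TRUE),
                       pick)
  e <- config$de_effect

  logmean <- matrix(baseline, n, ns, dimnames = list(genes, design$sample_id))
  is_f <- design$gonadal_sex == "F"
  is_xx <- design$genetic_sex == "XX"
  # orientation: positive sign = higher in gonadal females / XX / stressed
  if (n_gon + n_both > 0 && any(is_f)) {
    gg <- c(gon_genes, both_genes)
    logmean[gg, is_f] <- logmean[gg, is_f] + eff_sign[gg] * e
  }
  if (n_gen + n_both > 0 && any(is_xx)) {
    gg <- c(gen_genes, both_genes)
    logmean[gg, is_xx] <- logmean[gg, is_xx] + eff_sign[gg] * e
  }

  stress_truth <- list()
  for (sp in config$stress_effect_spec) {
    in_region <- if (identical(sp$region, "all")) rep(TRUE, ns)
                 else design$region %in% sp$region
    in_sex <- if (sp$sex == "both") rep(TRUE, ns)
              else design$gonadal_sex == sp$sex
    cols <- design$stress == "stress" & in_region & in_sex
    if (any(cols)) {
      logmean[sp$genes, cols] <- logmean[sp$genes, cols] + sp$log2_effect
    }
    key <- paste0("stress_",
                  if (identical(sp$region, "all")) "all" else paste(sp$region, collapse = "+"),
                  "_", sp$sex)
    df <- data.frame(gene = sp$genes, effect = sp$log2_effect,
                     stringsAsFactors = FALSE)
    stress_truth[[key]] <- rbind(stress_truth[[key]], df)
  }

  # shared latent factors for modules, with per-condition loadings
  sigma <- config$module_latent_sd
  cond <- ifelse(design$stress == "ctrl", "ctrl", design$gonadal_sex)
  mean_lib <- mean(lib)
  for (m in config$module_spec) {
    gm <- m$gene_ids
    z <- rnorm(ns)
    eps <- matrix(rnorm(length(gm) * ns), length(gm), ns)
    w <- nb_log2_noise_var(2^baseline[gm] * mean_lib, phi[gm])
    targets <- c(ctrl = m$cor_ctrl, F = m$cor_stress_by_sex$F,
                 M = m$cor_stress_by_sex$M)
    for (cc in unique(cond)) {
      r <- targets[[cc]]
      a2 <- r * (sigma^2 + w) / sigma^2
      if (any(a2 > 1)) {
        stop("requested module correlation ", r,
             " exceeds the attainable ceiling given counting noise; ",
             "raise module_latent_sd or module expression")
      }
      a <- sqrt(a2)
      cols <- which(cond == cc)
      contrib <- sigma * (outer(a, z[cols]) +
                          sqrt(1 - a2) * eps[, cols, drop = FALSE])
      logmean[gm, cols] <- logmean[gm, cols] + contrib
    }
  }

  mu <- 2^logmean * rep(lib, each = n)
  counts <- matrix(rnbinom(n * ns, mu = mu, size = rep(1 / phi, ns)),
                   n, ns, dimnames = dimnames(logmean))
  storage.mode(counts) <- "integer"

  de_df <- function(gg) {
    if (length(gg) == 0L) {
      return(data.frame(gene = character(), effect = numeric(),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = gg, effect = eff_sign[gg] * e, stringsAsFactors = FALSE)
  }
  sex_df <- rbind(de_df(gon_genes), de_df(gen_genes),
                  transform(de_df(both_genes), effect = 2 * eff_sign[both_genes] * e))
  attribution <- c(setNames(rep("gonadal", n_gon), gon_genes),
                   setNames(rep("genetic", n_gen), gen_genes),
                   setNames(rep("both", n_both), both_genes))

  truth <- structure(list(
    de_genes_by_contrast = list(sex = sex_df,
                                gonadal = rbind(de_df(gon_genes), de_df(both_genes)),
                                genetic = rbind(de_df(gen_genes), de_df(both_genes))),
    stress_de = stress_truth,
    attribution = attribution,
    module_assignment = module_assignment,
    modules = config$module_spec,
    coherence_plan = coherence_plan(config),
    design = design), class = "sim_truth")
  list(counts = counts, truth = truth)
}

# derive, per sex and region pair, the planted concordant/discordant sets
coherence_plan <- function(config) {
  plan <- list()
  spec <- config$stress_effect_spec
  if (length(spec) < 2L) return(plan)
  expand_sex <- function(sp) if (sp$sex == "both") c("F", "M") else sp$sex
  for (sex in c("F", "M")) {
    sps <- Filter(function(sp) sex %in% expand_sex(sp) &&
                               !identical(sp$region, "all"), spec)
    if (length(sps) < 2L) next
    for (i in seq_along(sps)) for (j in seq_along(sps)) {
      if (i >= j) next
      a <- sps[[i]]; b <- sps[[j]]
      if (identical(a$region, b$region)) next
      shared <- intersect(a$genes, b$genes)
      if (length(shared) == 0L) next
      key <- paste(sex, a$region, b$region, sep = ":")
      kind <- if (sign(a$log2_effect) == sign(b$log2_effect))
                "concordant" else "discordant"
      plan[[key]] <- list(sex = sex, regions = c(a$region, b$region),
                          genes = shared, kind = kind)
    }
  }
  plan
}

#' Check realized within-module correlations against the planted targets
#'
#' Computes, per module and condition (ctrl; stress within each gonadal
#' sex), the mean pairwise Pearson correlation of log2-CPM values over the
#' module's genes, for generator self-validation.
#'
#' @param counts Count matrix from [simulate_counts()].
#' @param truth The matching `sim_truth`.
#' @return data.frame with columns `module`, `condition`, `target`,
#'   `realized`, `n_genes`, `n_samples`.
#' @export
planted_module_cor_check <- function(counts, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$modules) == 0L) stop("no modules planted")
  design <- truth$design
  expr <- log_cpm(counts)
  cond <- ifelse(design$stress == "ctrl", "ctrl", design$gonadal_sex)
  out <- list()
  for (m in truth$modules) {
    targets <- c(ctrl = m$cor_ctrl, F = m$cor_stress_by_sex$F,
                 M = m$cor_stress_by_sex$M)
    for (cc in intersect(c("ctrl", "F", "M"), unique(cond))) {
      cols <- which(cond == cc)
      cm <- cor(t(expr[m$gene_ids, cols, drop = FALSE]))
      realized <- mean(cm[lower.tri(cm)])
      out[[length(out) + 1L]] <- data.frame(
        module = m$label %||% "module", condition = cc,
        target = unname(targets[[cc]]), realized = realized,
        n_genes = length(m$gene_ids), n_samples = length(cols),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
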