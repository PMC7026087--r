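#' Pipeline configuration
#'
#' Validates every stage's parameters up front, before any computation.
#'
#' @param counts_path,design_path Input TSVs ([write_counts_tsv()] /
#'   design format).
#' @param out_dir Output directory (created if absent).
#' @param filter_fraction Low-expression filter fraction.
#' @param prior_count log2-CPM pseudo-count.
#' @param moderated Use the moderated t in all contrasts.
#' @param rrho_step RRHO rank stride (`NULL` = about a 100 x 100 grid).
#' @param beta,kind,estimator Co-expression network parameters.
#' @param cut_height,min_module_size Module detection parameters.
#' @param n_perm_preservation,n_perm_mdc Permutation counts.
#' @param q_max MDC significance threshold on q values.
#' @param hub_method,n_hops,z_min,score_min Hub-network parameters.
#' @param seed Global seed; stage seeds are derived as `seed + stage
#'   offset` (a fixed counter scheme, so stages are reproducible in
#'   isolation).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path, design_path, out_dir,
                            filter_fraction = 0.25, prior_count = 0.5,
                            moderated = FALSE, rrho_step = NULL,
                            beta = 6, kind = "unsigned",
                            estimator = "pearson", cut_height = 0.99,
                            min_module_size = 30,
                            n_perm_preservation = 200, n_perm_mdc = 1000,
                            q_max = 0.05, hub_method = "correlation",
                            n_hops = 2, z_min = 2, score_min = 0.95,
                            seed = 1L) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(design_path)) stop("design file not found: ", design_path)
  if (filter_fraction < 0 || filter_fraction >= 1) {
    stop("filter_fraction must lie in [0, 1)")
  }
  if (beta < 1 || min_module_size < 2 || n_perm_mdc < 100 ||
      n_perm_preservation < 50) {
    stop("invalid network/permutation parameters")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, offset) config$seed + offset

#' Run the full analysis pipeline
#'
#' Executes preprocess -> differential expression (sex, gonadal, genetic
#' and stress contrasts) -> RRHO across region pairs per sex ->
#' co-expression modules on the stressed network with preservation
#' against the non-stressed network -> MDC per sex -> hub networks per
#' sex and condition for every module whose connectivity changed.  Every
#' output table is written as TSV under `out_dir` and recorded in the
#' returned manifest; a rerun with the same configuration reproduces
#' identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest data.frame and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- data.frame(stage = character(), file = character(),
                         seed = integer(), stringsAsFactors = FALSE)
  note <- function(stage, file, seed = NA_integer_) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file,
                                            seed = seed))
  }
  emit <- function(stage, name, x, seed = NA_integer_, rownames_as = NULL) {
    p <- file.path(config$out_dir, name)
    write_tsv(x, p, rownames_as = rownames_as)
    note(stage, p, seed)
    p
  }

  counts <- read_counts_tsv(config$counts_path)
  design <- read_design_tsv(config$design_path)
  if (!identical(colnames(counts), design$sample_id)) {
    stop("preprocess: count columns do not match design sample order")
  }

  ## stage 1: preprocess -------------------------------------------------
  filtered <- filter_low_expression(counts, config$filter_fraction)
  expr <- log_cpm(filtered, config$prior_count)
  message("preprocess: ", nrow(filtered), "/", nrow(counts),
          " genes kept, ", ncol(expr), " samples")
  emit("preprocess", "filtered_counts.tsv", filtered,
       rownames_as = "gene_id")
  emit("preprocess", "expression.tsv", round(expr, 6),
       rownames_as = "gene_id")

  ## stage 2: differential expression ------------------------------------
  de <- list()
  for (region in unique(design$region)) {
    for (stress in c("ctrl", "stress")) {
      stratum <- list(region = region, stress = stress)
      specs <- list(
        sex = make_contrast("sex", list(genotype = "XX_F"),
                            list(genotype = "XY_M"), stratum),
        gonadal = make_contrast("gonadal", list(gonadal_sex = "F"),
                                list(gonadal_sex = "M"), stratum),
        genetic = make_contrast("genetic", list(genetic_sex = "XX"),
                                list(genetic_sex = "XY"), stratum))
      for (nm in names(specs)) {
        key <- paste(nm, region, stress, sep = "_")
        de[[key]] <- de_test(expr, design, specs[[nm]],
                             moderated = config$moderated)
        emit("diffexpr", paste0("de_", key, ".tsv"),
             transform(de[[key]], log2fc = round(log2fc, 6),
                       t_stat = round(t_stat, 4)))
      }
    }
    for (genotype in c("XX_F", "XY_M")) {
      key <- paste("stress", region, genotype, sep = "_")
      ct <- make_contrast(key, list(stress = "stress"),
                          list(stress = "ctrl"),
                          list(region = region, genotype = genotype))
      de[[key]] <- de_test(expr, design, ct, moderated = config$moderated)
      emit("diffexpr", paste0("de_", key, ".tsv"),
           transform(de[[key]], log2fc = round(log2fc, 6),
                     t_stat = round(t_stat, 4)))
    }
  }
  venn <- list()
  for (region in unique(design$region)) {
    for (stress in c("ctrl", "stress")) {
      vp <- attribute_sex_differences(
        call_de(de[[paste("sex", region, stress, sep = "_")]]),
        call_de(de[[paste("gonadal", region, stress, sep = "_")]]),
        call_de(de[[paste("genetic", region, stress, sep = "_")]]))
      venn[[paste(region, stress, sep = "_")]] <- vp
    }
  }
  venn_df <- do.call(rbind, lapply(names(venn), function(k) {
    v <- venn[[k]]
    data.frame(stratum = k, n_sex_de = v$n_sex,
               pct_gonadal = round(v$pct_gonadal, 2),
               pct_genetic = round(v$pct_genetic, 2),
               t(v$venn), stringsAsFactors = FALSE)
  }))
  emit("diffexpr", "venn_attribution.tsv", venn_df)

  ## stage 3: RRHO coherence ---------------------------------------------
  regions <- unique(design$region)
  rrho_summary <- list()
  rrho_maps <- list()
  if (length(regions) >= 2) {
    for (genotype in c("XX_F", "XY_M")) {
      for (i in seq_along(regions)) for (j in seq_along(regions)) {
        if (i >= j) next
        ra <- make_ranked_list(de[[paste("stress", regions[i], genotype,
                                         sep = "_")]])
        rb <- make_ranked_list(de[[paste("stress", regions[j], genotype,
                                         sep = "_")]])
        map <- rrho_map(ra, rb, step = config$rrho_step)
        qs <- classify_quadrants(map)
        key <- paste(genotype, regions[i], regions[j], sep = "_")
        rrho_maps[[key]] <- map
        rrho_summary[[key]] <- data.frame(
          pair = key, call = qs$call,
          max_concordant = max(qs$quadrants$max_cell[
            qs$quadrants$quadrant %in% c("up-up", "down-down")], na.rm = TRUE),
          max_discordant = max(qs$quadrants$max_cell[
            qs$quadrants$quadrant %in% c("up-down", "down-up")], na.rm = TRUE),
          stringsAsFactors = FALSE)
        grid <- map$grid
        dimnames(grid) <- list(map$thresholds, map$thresholds)
        emit("rrho", paste0("rrho_", key, ".tsv"), round(grid, 4),
             rownames_as = "rank_threshold")
      }
    }
    emit("rrho", "rrho_summary.tsv", do.call(rbind, rrho_summary))
  }

  ## stage 4: co-expression modules on the stressed network --------------
  stressed <- design$sample_id[design$stress == "stress"]
  unstressed <- design$sample_id[design$stress == "ctrl"]
  tom <- topological_overlap(
    adjacency(expr[, stressed], config$beta, config$kind, config$estimator))
  modules <- detect_modules(tom, config$min_module_size, config$cut_height,
                            expr = expr[, stressed])
  message("coexpression: ",
          length(setdiff(unique(modules$colors), "grey")), " modules")
  emit("coexpression", "module_assignment.tsv",
       data.frame(gene = names(modules$colors),
                  module = unname(modules$colors)))
  pres_seed <- stage_seed(config, 4L)
  preservation <- module_preservation(
    modules, expr[, stressed], expr[, unstressed],
    n_perm = config$n_perm_preservation, seed = pres_seed,
    beta = config$beta, kind = config$kind, estimator = config$estimator)
  emit("coexpression", "module_preservation.tsv",
       transform(preservation, Z_density = round(Z_density, 3),
                 Z_connectivity = round(Z_connectivity, 3),
                 Z_summary = round(Z_summary, 3)), seed = pres_seed)

  ## stage 5: MDC per sex -------------------------------------------------
  kept <- preservation$module[preservation$preserved]
  mod_list <- module_gene_list(modules)[kept]
  mdc_tabs <- list()
  mdc_seed <- stage_seed(config, 5L)
  for (genotype in c("XX_F", "XY_M")) {
    gsamp <- design$genotype == genotype
    es <- expr[, design$sample_id[gsamp & design$stress == "stress"]]
    ec <- expr[, design$sample_id[gsamp & design$stress == "ctrl"]]
    rows <- lapply(names(mod_list), function(lab) {
      ps <- mdc_permutation_test(es, ec, mod_list[[lab]],
                                 scheme = "shuffled_samples",
                                 n_perm = config$n_perm_mdc,
                                 seed = mdc_seed, beta = config$beta,
                                 kind = config$kind,
                                 estimator = config$estimator)
      pg <- mdc_permutation_test(es, ec, mod_list[[lab]],
                                 scheme = "shuffled_genes",
                                 n_perm = config$n_perm_mdc,
                                 seed = mdc_seed + 1L, beta = config$beta,
                                 kind = config$kind,
                                 estimator = config$estimator)
      data.frame(module = lab, mdc = ps$mdc,
                 connectivity_stress = ps$connectivity_stress,
                 connectivity_ctrl = ps$connectivity_ctrl,
                 p_shuffled_samples = ps$p_value,
                 p_shuffled_genes = pg$p_value, stringsAsFactors = FALSE)
    })
    if (length(rows)) {
      tab <- classify_modules(do.call(rbind, rows), config$q_max)
      mdc_tabs[[genotype]] <- tab
      emit("mdc", paste0("mdc_", genotype, ".tsv"),
           transform(tab, mdc = round(mdc, 4)), seed = mdc_seed)
    }
  }

  ## stage 6: hub networks for modules with connectivity changes ---------
  focus <- unique(unlist(lapply(mdc_tabs, function(t)
    t$module[t$call != "unchanged"])))
  hub_seed <- stage_seed(config, 6L)
  hub_rows <- list()
  for (lab in focus) {
    genes <- mod_list[[lab]]
    for (genotype in c("XX_F", "XY_M")) {
      gsamp <- design$genotype == genotype
      nets <- lapply(c(stress = "stress", ctrl = "ctrl"), function(cc) {
        cols <- design$sample_id[gsamp & design$stress == cc]
        build_condition_network(expr[genes, cols],
                                method = config$hub_method,
                                seed = hub_seed)
      })
      reports <- lapply(nets, identify_hubs, n_hops = config$n_hops,
                        z_min = config$z_min)
      ssh <- stress_specific_hubs(reports$stress, reports$ctrl)
      hub_rows[[paste(lab, genotype)]] <- data.frame(
        module = lab, genotype = genotype,
        n_hubs_stress = sum(reports$stress$hub),
        n_hubs_ctrl = sum(reports$ctrl$hub),
        n_stress_specific = length(ssh), stringsAsFactors = FALSE)
      emit("hubnet", paste0("edges_", lab, "_", genotype, "_stress.tsv"),
           export_edges(nets$stress, config$score_min), seed = hub_seed)
      emit("hubnet", paste0("nodes_", lab, "_", genotype, ".tsv"),
           node_table(nets$stress, reports$stress, ssh), seed = hub_seed)
    }
  }
  if (length(hub_rows)) {
    emit("hubnet", "hub_summary.tsv", do.call(rbind, hub_rows),
         seed = hub_seed)
  }

  emit("manifest", "manifest.tsv", manifest)
  invisible(list(manifest = manifest, de = de, venn = venn,
                 rrho = rrho_summary, rrho_maps = rrho_maps,
                 modules = modules, preservation = preservation,
                 mdc = mdc_tabs, hubs = hub_rows))
}

#' Build the bundled synthetic demonstration dataset
#'
#' Generates a dataset with the qualitative structure of the study:
#' gonadal-only, genetic-only and shared sex effects; stress effects that
#' are anti-coherent between BLA and NAc in gonadal females and coherent
#' between PFC and NAc in gonadal males; and a module whose connectivity
#' gains under stress in females but collapses in males, plus a stable
#' module and a module gaining in both sexes.  Writes counts, design and
#' ground-truth sidecars to `dir` and returns a ready-to-run
#' [pipeline_config()].
#'
#' @param seed RNG seed.
#' @param dir Output directory.
#' @param n_genes Gene universe size.
#' @param n_perm_mdc,n_perm_preservation Permutation counts passed to the
#'   pipeline config.
#' @return List with `config` (pipeline_config), `sim` (sim_config),
#'   `truth`, and the written paths.
#' @export
make_demo <- function(seed = 1L, dir = tempfile("fcgnet_demo"),
                      n_genes = 2000, n_perm_mdc = 1000,
                      n_perm_preservation = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sim_gene_ids(n_genes)
  s1 <- ids[1:200]            # female BLA-up / NAc-down (anti-coherent)
  s2 <- ids[201:400]          # male PFC-up / NAc-up (coherent)
  m_opp <- ids[401:460]       # female gain / male loss
  m_stable <- ids[461:510]
  m_gain <- ids[511:550]
  sim <- sim_config(
    n_genes = n_genes, n_per_cell = 3,
    de_frac_gonadal = 0.02, de_frac_genetic = 0.02, de_frac_both = 0.01,
    stress_effect_spec = list(
      list(genes = s1, region = "BLA", sex = "F", log2_effect = 1.0),
      list(genes = s1, region = "NAc", sex = "F", log2_effect = -1.0),
      list(genes = s2, region = "PFC", sex = "M", log2_effect = 0.8),
      list(genes = s2, region = "NAc", sex = "M", log2_effect = 0.8)),
    module_spec = list(
      planted_module(m_opp, cor_ctrl = 0.45,
                     cor_stress_by_sex = list(F = 0.85, M = 0.05),
                     label = "planted_opposite"),
      planted_module(m_stable, cor_ctrl = 0.6,
                     cor_stress_by_sex = list(F = 0.6, M = 0.6),
                     label = "planted_stable"),
      planted_module(m_gain, cor_ctrl = 0.3,
                     cor_stress_by_sex = list(F = 0.7, M = 0.7),
                     label = "planted_gain")),
    seed = seed)
  design <- generate_design(sim)
  out <- simulate_counts(sim, design)
  counts_path <- file.path(dir, "counts.tsv")
  design_path <- file.path(dir, "design.tsv")
  write_counts_tsv(out$counts, counts_path)
  write_tsv(design, design_path)
  write_truth_sidecar(out$truth, dir)
  config <- pipeline_config(counts_path, design_path,
                            out_dir = file.path(dir, "results"),
                            n_perm_mdc = n_perm_mdc,
                            n_perm_preservation = n_perm_preservation,
                            seed = seed)
  list(config = config, sim = sim, truth = out$truth,
       counts_path = counts_path, design_path = design_path, dir = dir)
}
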