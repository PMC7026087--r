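#!/usr/bin/env Rscript
# Differential expression per region and condition: overall sex
# differences (XX Female vs XY Male), gonadal-sex and genetic-sex
# contrasts, and the stress contrast within each "pure" genotype.  Sex
# differences are then attributed to gonadal and/or genetic sex by
# direction-consistent set overlap (the Venn logic of the study), and
# cross-region overlap of stress DE genes is quantified.

library(fcgnet)

expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df[[1]]
design <- read_design_tsv("results/demo/design.tsv")

de <- list()
for (region in unique(design$region)) {
  stratum <- list(region = region, stress = "ctrl")
  cts <- list(
    sex = make_contrast("sex", list(genotype = "XX_F"),
                        list(genotype = "XY_M"), stratum),
    gonadal = make_contrast("gonadal", list(gonadal_sex = "F"),
                            list(gonadal_sex = "M"), stratum),
    genetic = make_contrast("genetic", list(genetic_sex = "XX"),
                            list(genetic_sex = "XY"), stratum))
  de[[region]] <- lapply(cts, function(ct)
    de_test(expr, design, ct, moderated = TRUE))
  v <- attribute_sex_differences(call_de(de[[region]]$sex),
                                 call_de(de[[region]]$gonadal),
                                 call_de(de[[region]]$genetic))
  cat(sprintf("%s (non-stress): %d sex-DE genes; %.0f%% gonadal-driven, %.0f%% genetic-driven\n",
              region, v$n_sex, v$pct_gonadal, v$pct_genetic))
}

# sex-specific stress signatures overlap very little across sexes
for (region in unique(design$region)) {
  sets <- lapply(c("XX_F", "XY_M"), function(gt) {
    ct <- make_contrast("stress", list(stress = "stress"),
                        list(stress = "ctrl"),
                        list(region = region, genotype = gt))
    call_de(de_test(expr, design, ct, moderated = TRUE))
  })
  ov <- stress_overlap(sets[[1]], sets[[2]])
  cat(sprintf("%s: stress DE overlap between sexes %d genes (%.1f%% of female set)\n",
              region, ov$n_intersect,
              ifelse(is.na(ov$pct_of_a), 0, ov$pct_of_a)))
  write_tsv(sets[[1]], sprintf("results/stress_de_%s_XX_F.tsv", region))
  write_tsv(sets[[2]], sprintf("results/stress_de_%s_XY_M.tsv", region))
}

for (region in names(de)) {
  for (nm in names(de[[region]])) {
    write_tsv(de[[region]][[nm]],
              sprintf("results/de_%s_%s_ctrl.tsv", nm, region))
  }
}
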