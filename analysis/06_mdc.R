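#!/usr/bin/env Rscript
# Module differential connectivity: for each detected module and each
# "pure" genotype, the ratio of summed within-module adjacency in
# stressed vs non-stressed samples, tested against the two permutation
# nulls (random connections; random genes), BH-corrected within scheme,
# and classified gained / lost / unchanged.  The planted
# "planted_opposite" module should gain in females and lose in males.

library(fcgnet)

expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df[[1]]
design <- read_design_tsv("results/demo/design.tsv")
assign <- read.delim("results/module_assignment.tsv")
pres <- read.delim("results/module_preservation.tsv")
mods <- split(assign$gene, assign$module)
# only modules surviving preservation go into downstream analyses
mods <- mods[intersect(names(mods), pres$module[pres$preserved])]

for (gt in c("XX_F", "XY_M")) {
  keep <- design$genotype == gt
  es <- expr[, design$sample_id[keep & design$stress == "stress"]]
  ec <- expr[, design$sample_id[keep & design$stress == "ctrl"]]
  rows <- lapply(names(mods), function(lab) {
    ps <- mdc_permutation_test(es, ec, mods[[lab]], "shuffled_samples",
                               n_perm = 1000, seed = 21)
    pg <- mdc_permutation_test(es, ec, mods[[lab]], "shuffled_genes",
                               n_perm = 1000, seed = 22)
    data.frame(module = lab, mdc = ps$mdc,
               connectivity_stress = ps$connectivity_stress,
               connectivity_ctrl = ps$connectivity_ctrl,
               p_shuffled_samples = ps$p_value,
               p_shuffled_genes = pg$p_value)
  })
  tab <- classify_modules(do.call(rbind, rows))
  cat("==", gt, "==\n")
  print(tab[, c("module", "mdc", "q_shuffled_samples",
                "q_shuffled_genes", "call")])
  write_tsv(tab, sprintf("results/mdc_%s.tsv", gt))
}
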