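#!/usr/bin/env Rscript
# Weighted co-expression network on all stressed samples (all regions
# pooled, as in the study), topological-overlap clustering into modules,
# and permutation preservation scores of each module against the
# independent non-stressed network (Z_summary > 10 = highly preserved).

library(fcgnet)

expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df[[1]]
design <- read_design_tsv("results/demo/design.tsv")

stressed <- design$sample_id[design$stress == "stress"]
ctrl <- design$sample_id[design$stress == "ctrl"]

pick <- pick_soft_threshold(expr[, stressed], candidate_betas = c(2, 4, 6, 8))
cat(sprintf("soft power: %d (scale-free fit %s)\n", pick$beta,
            ifelse(pick$reached_target, ">= 0.8", "best available")))

tom <- topological_overlap(adjacency(expr[, stressed], beta = 6))
modules <- detect_modules(tom, min_size = 30, cut_height = 0.99,
                          expr = expr[, stressed])
print(modules$sizes)

pres <- module_preservation(modules, expr[, stressed], expr[, ctrl],
                            n_perm = 200, seed = 11)
print(pres)

write_tsv(data.frame(gene = names(modules$colors),
                     module = unname(modules$colors)),
          "results/module_assignment.tsv")
write_tsv(pres, "results/module_preservation.tsv")
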