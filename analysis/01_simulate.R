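#!/usr/bin/env Rscript
# Generate the synthetic study: a 4-genotype (FCG) x 2-stress x 3-region
# factorial with 3 replicates per cell (72 samples), planted gonadal /
# genetic / shared sex effects, sex-specific cross-region stress
# signatures (anti-coherent BLA/NAc pair in gonadal females, coherent
# PFC/NAc pair in males), and three co-expression modules — one with a
# sex-opposite connectivity response to stress.
#
# Writes counts, design, ground truth and a ready-to-run pipeline config
# under results/demo/.

library(fcgnet)

demo <- make_demo(seed = 1, dir = "results/demo", n_genes = 2000)

cat("samples:", nrow(demo$truth$design), "\n")
cat("planted sex-DE genes:", length(demo$truth$attribution), "\n")
cat("planted modules:",
    paste(vapply(demo$truth$modules, `[[`, "", "label"), collapse = ", "),
    "\n")
cat("counts written to", demo$counts_path, "\n")
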