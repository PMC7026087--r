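#!/usr/bin/env Rscript
# Filter the lowest-expressed 25% of genes (smallest total count across
# all samples) and transform to log2 counts per million, the same
# preprocessing contract as the study.  Writes the filtered counts and
# the expression matrix under results/.

library(fcgnet)

counts <- read_counts_tsv("results/demo/counts.tsv")
design <- read_design_tsv("results/demo/design.tsv")

filtered <- filter_low_expression(counts, fraction = 0.25)
expr <- log_cpm(filtered, prior_count = 0.5)

cat(sprintf("genes: %d -> %d after filtering (removed %d)\n",
            nrow(counts), nrow(filtered), nrow(counts) - nrow(filtered)))
cat(sprintf("library sizes: %.2g - %.2g reads\n",
            min(colSums(filtered)), max(colSums(filtered))))

dir.create("results", showWarnings = FALSE)
write_counts_tsv(filtered, "results/filtered_counts.tsv")
write_tsv(round(expr, 6), "results/expression.tsv", rownames_as = "gene_id")
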