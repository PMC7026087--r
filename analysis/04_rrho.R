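#!/usr/bin/env Rscript
# Threshold-free transcriptional coherence between brain regions.  For
# each "pure" genotype the stress signatures of every region pair are
# compared by rank-rank hypergeometric overlap on the signed
# -log10(p) x direction ranking, and the four-quadrant pattern is
# classified as coherent / anti-coherent.  The planted structure has an
# anti-coherent BLA/NAc pair in females and a coherent PFC/NAc pair in
# males.

library(fcgnet)

expr_df <- read.delim("results/expression.tsv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df[[1]]
design <- read_design_tsv("results/demo/design.tsv")

regions <- unique(design$region)
for (gt in c("XX_F", "XY_M")) {
  ranked <- lapply(regions, function(rg) {
    ct <- make_contrast("stress", list(stress = "stress"),
                        list(stress = "ctrl"),
                        list(region = rg, genotype = gt))
    make_ranked_list(de_test(expr, design, ct, moderated = TRUE))
  })
  names(ranked) <- regions
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i >= j) next
    map <- rrho_map(ranked[[i]], ranked[[j]])
    q <- classify_quadrants(map)
    cat(sprintf("%s %s-%s: %s (max concordant %.1f, max discordant %.1f)\n",
                gt, regions[i], regions[j], q$call,
                max(q$quadrants$max_cell[q$quadrants$quadrant %in%
                                         c("up-up", "down-down")]),
                max(q$quadrants$max_cell[q$quadrants$quadrant %in%
                                         c("up-down", "down-up")])))
    grid <- map$grid
    dimnames(grid) <- list(map$thresholds, map$thresholds)
    write_tsv(round(grid, 4),
              sprintf("results/rrho_%s_%s_%s.tsv", gt, regions[i],
                      regions[j]),
              rownames_as = "rank_threshold")
  }
}
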