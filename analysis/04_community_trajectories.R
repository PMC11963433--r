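#!/usr/bin/env Rscript
# 16S-style community trajectories: rarefaction to the minimum shared depth,
# Bray-Curtis distance of every sample to its mouse's week-8 baseline, the
# per-timepoint yMB vs iMB comparison, and an unconstrained PCoA.

suppressPackageStartupMessages(library(rejuvenome))
inp <- "results/inputs"
out <- "results"
seed <- 20260928L

ctab <- utils::read.delim(file.path(inp, "asv_counts.tsv"),
                          check.names = FALSE)
counts <- as.matrix(ctab[, -1]); rownames(counts) <- ctab$sample_id
meta <- utils::read.delim(file.path(inp, "asv_meta.tsv"))

cat(sprintf("rarefying %d samples to the minimum shared depth %d\n",
            nrow(counts), min(rowSums(counts))))
db <- distance_to_baseline(counts, meta, baseline_week = 8, seed = seed)
utils::write.table(db$distances, file.path(out, "baseline_distances.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(db$tests, file.path(out, "baseline_distance_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("distance-to-baseline, yMB vs iMB per timepoint:\n")
print(db$tests)

rare <- rarefy_counts(counts, seed = seed)
rel <- relative_abundance(rare)
D <- bray_curtis_matrix(rel)
pc <- pcoa_ordination(D, k = 2)
ord <- data.frame(meta, pc$points)
utils::write.table(ord, file.path(out, "pcoa_coordinates.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("PCo1/PCo2 explain %.1f%% / %.1f%% of the positive inertia\n",
            100 * pc$variance_explained[1], 100 * pc$variance_explained[2]))
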