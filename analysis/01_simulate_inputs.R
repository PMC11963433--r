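#!/usr/bin/env Rscript
# Generates every synthetic input used by the downstream analyses and writes
# them, with their ground truth, under results/inputs/.  All later scripts
# read only from there, so the whole workflow is reproducible from one seed.

suppressPackageStartupMessages(library(rejuvenome))
seed <- 20260928L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Longitudinal KO table: 200 null features, 50 with inverted age slopes,
## 10 mice per arm sampled at weeks 8, 40, 72 and 120, plus a handful of
## concordant features so every direction class occurs.
cfg <- screen_sim_config(n_null = 200, n_inverted = 50,
                         n_concordant_up = 10, n_concordant_down = 10,
                         seed = seed)
ko <- gen_ko_table(cfg)
write_feature_table(ko$table, file.path(out, "ko"))
utils::write.table(ko$truth, file.path(out, "ko_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

## A toy pathway annotation: features grouped into pathways of ~12, so the
## planted inverted features concentrate in the first few pathways.
feat <- ko$truth$feature_id[order(ko$truth$class != "inverted")]
ann <- data.frame(feature_id = feat,
                  pathway_id = sprintf("map%03d", (seq_along(feat) - 1) %/% 12))
utils::write.table(ann, file.path(out, "pathways.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

## Toy model pairs for all six ecological relationship types.
dir.create(file.path(out, "models"), showWarnings = FALSE)
kinds <- c("competition", "neutralism", "commensalism", "mutualism",
           "amensalism", "exploitation")
for (k in kinds) {
  p <- gen_toy_model_pairs(k, seed = seed)
  write_model_json(p$model1, file.path(out, "models",
                                       paste0(k, "_member1.json")))
  write_model_json(p$model2, file.path(out, "models",
                                       paste0(k, "_member2.json")))
  jsonlite::write_json(as.list(p$medium),
                       file.path(out, "models", paste0(k, "_medium.json")),
                       auto_unbox = TRUE, digits = NA)
}

## ASV counts drifting from the week-8 baseline, iMB twice as fast as yMB.
asv <- gen_asv_table(seed = seed)
utils::write.table(data.frame(sample_id = rownames(asv$counts), asv$counts),
                   file.path(out, "asv_counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(asv$meta, file.path(out, "asv_meta.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

## Single-cell matrix: mesenchymal signature damped in yMB enterocytes and
## TA cells, 5 genes strongly fold-changed in enterocytes.
cm <- gen_cell_matrix(n_cells_per_type = 60,
                      cell_types = c("enterocytes", "TA_cells",
                                     "macrophages"),
                      score_shift = c(enterocytes = -0.6, TA_cells = -0.6),
                      extra_genes = inflammation_signature(),
                      n_de_genes = 5, lfc = 1.5, seed = seed)
write_cell_matrix(cm, file.path(out, "cells"))
writeLines(cm$planted_de, file.path(out, "cells", "planted_de.txt"))

## Host phenotypes: higher late-life weight and slower death in yMB.
ph <- gen_phenotype(n_per_group = 10, auc_offset = 200,
                    survival_hazard_ratio = 3, seed = seed)
for (nm in names(ph))
  utils::write.table(ph[[nm]], file.path(out, paste0(nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

cat("inputs written under", out, "\n")
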