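test_that("QC keeps boundary cells and applies all four rules conjunctively", {
  # five cells: one clean, one per violated criterion
  genes <- c("mt-1", "Actb", sprintf("g%d", 1:8))
  counts <- matrix(0, 10, 5,
                   dimnames = list(genes, sprintf("c%d", 1:5)))
  counts["Actb", ] <- c(2500, 100, 3000, 1500, 40)     # housekeeping reads
  counts["mt-1", ] <- c(100, 20, 0, 900, 5)            # mito reads
  counts["g1", ]   <- c(2400, 79, 2500, 600, 450)
  # totals:        5000   199  5500  3000  495
  # cell1: total exactly 5000, mito 2%, hk 50%          -> kept
  # cell2: total 199 (< 200)                            -> removed
  # cell3: total 5500 (> 5000)                          -> removed
  # cell4: mito 30% (> 25%)                             -> removed
  # cell5: hk 40/495 < 10%                              -> removed
  cm <- tiny_cells(counts, mito = "mt-1", hk = "Actb")
  filt <- qc_filter(cm)
  expect_identical(colnames(filt$counts), "c1")
  rep <- attr(filt, "qc_report")
  expect_equal(unname(rep["n_kept"]), 1)
  expect_equal(unname(rep["removed_low_counts"]), 1)
  expect_equal(unname(rep["removed_high_counts"]), 1)
  expect_equal(unname(rep["removed_mito"]), 1)
  expect_equal(unname(rep["removed_housekeeping"]), 1)
  # order independence: the survivor set is a pure conjunction, so a column
  # permutation of the input permutes but never changes the survivors
  perm <- c(5, 3, 1, 2, 4)
  cmp <- cm
  cmp$counts <- cmp$counts[, perm]
  cmp$cell_meta <- cmp$cell_meta[perm, ]
  expect_identical(colnames(qc_filter(cmp)$counts), "c1")
  expect_error(qc_filter(cm, min_counts = 1e6), "no cells")
})

test_that("log normalization is depth-invariant and maps zeros to zeros", {
  counts <- matrix(c(5, 0, 5, 10, 0, 10), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  cm <- lognorm(tiny_cells(counts))
  n <- as.matrix(cm$norm)
  expect_equal(n[, "c1"], n[, "c2"], tolerance = 1e-12)  # c2 = 2 x c1
  expect_equal(n["g2", "c1"], 0)
  one <- matrix(c(7, 0), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  n1 <- as.matrix(lognorm(tiny_cells(one), scale = 1e4)$norm)
  expect_equal(n1["g1", "c1"], log1p(1e4), tolerance = 1e-12)
})

test_that("module score is zero under the self-control identity and seeded", {
  cm <- gen_cell_matrix(n_cells_per_type = 10, n_genes = 300, seed = 5)
  cm <- lognorm(cm)
  sig <- mesenchymal_signature()
  self <- module_score(cm, sig, control_genes = sig)
  expect_true(all(abs(self) < 1e-12))
  s1 <- module_score(cm, sig, seed = 7)
  s2 <- module_score(cm, sig, seed = 7)
  expect_identical(s1, s2)
  expect_error(module_score(cm, c("NoSuchGene")), "no signature gene")
  expect_warning(module_score(cm, c(sig, "NoSuchGene")), "absent")
})

test_that("a planted signature shift lowers the score in the targeted cells", {
  cm <- gen_cell_matrix(n_cells_per_type = 40,
                        cell_types = c("enterocytes", "TA_cells"),
                        score_shift = c(enterocytes = -0.8),
                        n_genes = 500, seed = 3)
  cm <- lognorm(cm)
  sc <- module_score(cm, mesenchymal_signature(), seed = 3)
  res <- score_compare(sc, cm$cell_meta)
  ent <- res[res$cell_type == "enterocytes", ]
  expect_lt(ent$mean_yMB, ent$mean_iMB)
  expect_lt(ent$fdr, 0.05)
})

test_that("score comparison is symmetric under label swap", {
  cm <- gen_cell_matrix(n_cells_per_type = 20, n_genes = 200,
                        signature = inflammation_signature(), seed = 6)
  cm <- lognorm(cm)
  sc <- module_score(cm, inflammation_signature(), seed = 6)
  r1 <- score_compare(sc, cm$cell_meta)
  swapped <- cm$cell_meta
  swapped$treatment <- ifelse(swapped$treatment == "yMB", "iMB", "yMB")
  r2 <- score_compare(sc, swapped)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("differential expression finds exactly the planted gene", {
  cm <- gen_cell_matrix(n_cells_per_type = 60, cell_types = "enterocytes",
                        n_de_genes = 1, lfc = 1.5, n_genes = 2000, seed = 2)
  cm <- lognorm(cm)
  de <- de_per_celltype(cm)
  expect_identical(de$gene_id, cm$planted_de)
  expect_identical(de$direction, "up")
  # identical groups produce no calls
  null_cm <- gen_cell_matrix(n_cells_per_type = 30,
                             cell_types = "enterocytes",
                             n_genes = 500, seed = 4)
  null_cm <- lognorm(null_cm)
  expect_equal(nrow(de_per_celltype(null_cm)), 0)
})

test_that("the fold-change filter excludes sub-threshold genes regardless of p", {
  # two groups of many cells differing by a tiny but consistent offset
  set.seed(9)
  n <- 400
  counts <- rbind(flat = rpois(2 * n, 20) + rep(c(0, 1), each = n),
                  ref = rpois(2 * n, 50))
  colnames(counts) <- sprintf("c%d", 1:(2 * n))
  cm <- lognorm(tiny_cells(counts,
                           treatment = rep(c("iMB", "yMB"), each = n)))
  lfc <- rowMeans(as.matrix(cm$norm)[, (n + 1):(2 * n)]) -
    rowMeans(as.matrix(cm$norm)[, 1:n])
  expect_lt(abs(lfc["flat"]), 0.1)  # the offset is below the fold threshold
  de <- de_per_celltype(cm, min_lfc = 0.1)
  expect_false("flat" %in% de$gene_id)
  de2 <- de_per_celltype(cm, min_lfc = 0.01)
  expect_true("flat" %in% de2$gene_id)  # only the fold filter held it back
})

test_that("cell-type proportions sum to one per mouse and test sanely", {
  cm <- gen_cell_matrix(n_cells_per_type = 15, seed = 8)
  pr <- suppressWarnings(proportion_compare(cm))
  expect_equal(unname(rowSums(pr$proportions)),
               rep(1, nrow(pr$proportions)), tolerance = 1e-12)
  # equal designed compositions: no cell type should be strongly significant
  expect_true(all(pr$tests$p > 0.01))
})

test_that("cell matrices round-trip through MTX + TSV", {
  cm <- gen_cell_matrix(n_cells_per_type = 4, n_genes = 80, seed = 10)
  dir <- withr::local_tempdir()
  write_cell_matrix(cm, dir)
  back <- read_cell_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$cell_meta, cm$cell_meta)
  expect_equal(back$gene_meta, cm$gene_meta)
})
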