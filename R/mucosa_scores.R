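#' Quality-control filter for a single-cell matrix
#'
#' Keeps cells with `min_counts <= total counts <= max_counts`, a
#' mitochondrial read fraction of at most `max_mito`, and a housekeeping
#' read fraction of at least `min_housekeeping` ("less than 200 or more than
#' 5000 reads" are removed, so both count bounds are kept inclusive).  The
#' four criteria are conjunctive, so removal order is immaterial.
#'
#' @param cm a `cell_matrix` (see [gen_cell_matrix()]): sparse `counts`
#'   genes x cells, `cell_meta`, `gene_meta` with `mito` and `housekeeping`
#'   flags.
#' @param min_counts,max_counts inclusive total-count bounds per cell.
#' @param max_mito maximum mitochondrial fraction.
#' @param min_housekeeping minimum housekeeping fraction.
#' @return The filtered `cell_matrix` with a `qc_report` attribute counting
#'   removals per criterion (a cell can violate several).
#' @export
qc_filter <- function(cm, min_counts = 200, max_counts = 5000,
                      max_mito = 0.25, min_housekeeping = 0.10) {
  stopifnot(inherits(cm, "cell_matrix"))
  total <- Matrix::colSums(cm$counts)
  mito_frac <- Matrix::colSums(cm$counts[cm$gene_meta$mito, , drop = FALSE]) /
    pmax(total, 1)
  hk_frac <- Matrix::colSums(cm$counts[cm$gene_meta$housekeeping, ,
                                       drop = FALSE]) / pmax(total, 1)
  low <- total < min_counts
  high <- total > max_counts
  mito <- mito_frac > max_mito
  hk <- hk_frac < min_housekeeping
  keep <- !(low | high | mito | hk)
  if (!any(keep)) stop("no cells survive QC")
  report <- c(n_input = length(keep), n_kept = sum(keep),
              removed_low_counts = sum(low), removed_high_counts = sum(high),
              removed_mito = sum(mito), removed_housekeeping = sum(hk))
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm$cell_meta <- cm$cell_meta[keep, , drop = FALSE]
  if (!is.null(cm$norm)) cm$norm <- cm$norm[, keep, drop = FALSE]
  attr(cm, "qc_report") <- report
  cm
}

#' Library-size log normalization
#'
#' Per cell: counts scaled to `scale` total, then `log(1 + x)` (natural
#' log).  Depth-invariant: doubling every count of a cell leaves its
#' normalized values unchanged.
#'
#' @param cm a `cell_matrix`.
#' @param scale target library size.
#' @return The `cell_matrix` with a sparse `norm` slot added.
#' @export
lognorm <- function(cm, scale = 10000) {
  stopifnot(inherits(cm, "cell_matrix"))
  total <- Matrix::colSums(cm$counts)
  if (any(total == 0)) stop("cell(s) with zero total counts")
  norm <- cm$counts
  norm@x <- norm@x / rep.int(total, diff(norm@p)) * scale
  norm@x <- log1p(norm@x)
  cm$norm <- norm
  cm
}

#' Gene-signature module score per cell
#'
#' Mean normalized expression of the signature genes minus the mean of a
#' seeded control set: all genes are binned by average expression
#' (`n_bins` near-equal-size bins), and `n_ctrl` control genes are drawn
#' from the bin of each signature gene, so the control matches the
#' signature's expression profile.  Signature genes absent from the matrix
#' are dropped with a warning; an entirely absent signature is an error.
#'
#' @param cm a `cell_matrix` with a `norm` slot ([lognorm()]).
#' @param signature character vector of gene ids.
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed seed for the control draw.
#' @param control_genes optional explicit control set overriding the binned
#'   draw (the self-control identity `control_genes = signature` gives a
#'   score of exactly 0).
#' @return Numeric score per cell (named by barcode).
#' @export
module_score <- function(cm, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1L, control_genes = NULL) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (is.null(cm$norm)) stop("run lognorm() first")
  genes <- rownames(cm$norm)
  present <- intersect(signature, genes)
  if (!length(present)) stop("no signature gene is present in the matrix")
  if (length(present) < length(signature))
    warning("dropping ", length(signature) - length(present),
            " absent signature gene(s)")
  if (is.null(control_genes)) {
    avg <- Matrix::rowMeans(cm$norm)
    bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
               labels = FALSE)
    names(bin) <- genes
    set.seed(seed)
    control_genes <- unlist(lapply(present, function(g) {
      pool <- genes[bin == bin[[g]]]
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }))
  } else {
    if (!all(control_genes %in% genes)) stop("unknown control gene(s)")
  }
  sig_mean <- Matrix::colMeans(cm$norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(cm$norm[control_genes, , drop = FALSE])
  stats::setNames(sig_mean - ctrl_mean, colnames(cm$norm))
}

#' Compare module scores between treatments per cell type
#'
#' Mann-Whitney test of yMB vs iMB scores within each cell type, BH-adjusted
#' across cell types.
#'
#' @param scores per-cell score ([module_score()]).
#' @param cell_meta the matrix's `cell_meta` (aligned with `scores`).
#' @return data.frame per cell type: group means, `U`, `p`, `fdr`.
#' @export
score_compare <- function(scores, cell_meta) {
  stopifnot(length(scores) == nrow(cell_meta))
  cts <- sort(unique(cell_meta$cell_type))
  rows <- lapply(cts, function(ct) {
    sy <- scores[cell_meta$cell_type == ct & cell_meta$treatment == "yMB"]
    si <- scores[cell_meta$cell_type == ct & cell_meta$treatment == "iMB"]
    if (!length(sy) || !length(si)) return(NULL)
    mw <- mann_whitney(sy, si, mode = "asymptotic")
    data.frame(cell_type = ct, mean_yMB = mean(sy), mean_iMB = mean(si),
               U = mw$U, p = mw$p)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Per-cell-type differential expression between treatments
#'
#' Per gene and cell type: a Wilcoxon rank-sum test on the log-normalized
#' expression of yMB vs iMB cells, with the log-fold difference taken as the
#' difference of group means of the natural-log-normalized expression.
#' Genes are reported when `|log-fold| >= min_lfc` and the
#' Bonferroni-adjusted p is below `alpha`, with the full gene complement of
#' the dataset (`m = nrow(counts)`) as the correction family.  A cell type
#' missing one of the treatments is skipped with a warning.
#'
#' @param cm a `cell_matrix` with `norm` ([lognorm()]).
#' @param min_lfc minimum absolute log-fold difference (natural-log scale).
#' @param alpha Bonferroni-adjusted p threshold.
#' @param cell_types subset of cell types to test (default all).
#' @return data.frame of reported genes: `cell_type`, `gene_id`, `lfc`,
#'   `p`, `p_bonf`, `direction` (`up` = higher in yMB).
#' @export
de_per_celltype <- function(cm, min_lfc = 0.1, alpha = 0.05,
                            cell_types = unique(cm$cell_meta$cell_type)) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (is.null(cm$norm)) stop("run lognorm() first")
  m_genes <- nrow(cm$counts)
  out <- list()
  for (ct in cell_types) {
    iy <- cm$cell_meta$cell_type == ct & cm$cell_meta$treatment == "yMB"
    ii <- cm$cell_meta$cell_type == ct & cm$cell_meta$treatment == "iMB"
    if (!any(iy) || !any(ii)) {
      warning("cell type '", ct, "' missing a treatment; skipped")
      next
    }
    My <- as.matrix(cm$norm[, iy, drop = FALSE])
    Mi <- as.matrix(cm$norm[, ii, drop = FALSE])
    lfc <- rowMeans(My) - rowMeans(Mi)
    cand <- which(abs(lfc) >= min_lfc)
    if (!length(cand)) next
    p <- vapply(cand, function(g) {
      x <- My[g, ]; y <- Mi[g, ]
      if (length(unique(c(x, y))) == 1L) return(1)
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE)$p.value)
    }, 0)
    p_bonf <- pmin(1, p * m_genes)
    keep <- p_bonf < alpha
    if (!any(keep)) next
    out[[ct]] <- data.frame(
      cell_type = ct, gene_id = rownames(cm$norm)[cand[keep]],
      lfc = lfc[cand[keep]], p = p[keep], p_bonf = p_bonf[keep],
      direction = ifelse(lfc[cand[keep]] > 0, "up", "down"),
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(cell_type = character(0), gene_id = character(0),
                      lfc = numeric(0), p = numeric(0), p_bonf = numeric(0),
                      direction = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-mouse cell-type proportions and their group comparison
#'
#' Computes each mouse's cell-type composition (proportions summing to 1
#' per mouse) and compares the two treatment arms per cell type with a
#' Mann-Whitney test across mice.
#'
#' @param cm a `cell_matrix`.
#' @return list with `proportions` (mice x cell types) and `tests`
#'   (per-cell-type `U`, `p`).
#' @export
proportion_compare <- function(cm) {
  stopifnot(inherits(cm, "cell_matrix"))
  tab <- table(cm$cell_meta$mouse_id, cm$cell_meta$cell_type)
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  grp <- cm$cell_meta$treatment[match(rownames(prop),
                                      cm$cell_meta$mouse_id)]
  tests <- do.call(rbind, lapply(colnames(prop), function(ct) {
    py <- prop[grp == "yMB", ct]; pi_ <- prop[grp == "iMB", ct]
    mw <- mann_whitney(py, pi_, mode = "asymptotic")
    data.frame(cell_type = ct, mean_yMB = mean(py), mean_iMB = mean(pi_),
               U = mw$U, p = mw$p)
  }))
  list(proportions = prop, tests = tests)
}

#' Write / read a cell matrix in MatrixMarket + TSV form
#'
#' Writes `matrix.mtx`, `features.tsv` (gene id, mito, housekeeping),
#' `barcodes.tsv` and `cell_meta.tsv` under a directory.
#'
#' @param cm a `cell_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_cell_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(cm$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  gene_meta <- utils::read.delim(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cell_meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"))
  dimnames(counts) <- list(gene_meta$gene_id, barcodes)
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta), class = "cell_matrix")
}
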