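# Independent oracles and tiny fixture builders shared across tests.

# Benjamini-Hochberg by the textbook recipe: sort, p * m / rank, cumulative
# minimum from the largest rank down, cap at 1.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Exact hypergeometric upper tail by direct enumeration of the overlap
# distribution with binomial coefficients.
hand_hyper_tail <- function(overlap, pathway, universe, n_sig) {
  ks <- overlap:min(pathway, n_sig)
  sum(choose(pathway, ks) * choose(universe - pathway, n_sig - ks)) /
    choose(universe, n_sig)
}

# Two-sided exact Mann-Whitney p by brute-force enumeration of all group
# assignments (tie-free inputs only).
perm_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Mantel-Cox statistic from first principles: at every distinct event time,
# observed events in group 1 minus the hypergeometric expectation, with the
# hypergeometric variance, over the current risk sets.
hand_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Minimal hand-built feature table: counts matrix plus balanced metadata.
tiny_table <- function(abundance, ages = NULL, scale = "raw") {
  n <- nrow(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("f%02d", seq_len(ncol(abundance)))
  if (is.null(ages)) ages <- rep(8, n)
  meta <- data.frame(sample_id = rownames(abundance),
                     mouse_id = sprintf("m%02d", seq_len(n)),
                     age_weeks = ages,
                     treatment = rep(c("yMB", "iMB"), length.out = n))
  feature_table(abundance, meta, scale = scale)
}

# Single-substrate chain model used by the LP tests (uptake bound U).
tiny_chain <- function(id = "bug", U = 10) {
  metabolic_model(
    id,
    data.frame(id = c("A_e", "A_c"),
               compartment = c("extracellular", "cytosol")),
    list(EX_A_e = list(stoich = c(A_e = -1), lb = -U, ub = 1000),
         T_A = list(stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
         BIOMASS = list(stoich = c(A_c = -1), lb = 0, ub = 1000)),
    "BIOMASS")
}

# Hand-built cell_matrix from a dense count matrix (genes x cells).
tiny_cells <- function(counts, cell_type = NULL, treatment = NULL,
                       mouse_id = NULL, mito = NULL, hk = NULL) {
  genes <- rownames(counts); cells <- colnames(counts)
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                         "CsparseMatrix"),
    cell_meta = data.frame(
      barcode = cells,
      cell_type = cell_type %||% rep("typeA", length(cells)),
      mouse_id = mouse_id %||% rep("m01", length(cells)),
      treatment = treatment %||% rep(c("yMB", "iMB"),
                                     length.out = length(cells))),
    gene_meta = data.frame(gene_id = genes,
                           mito = genes %in% (mito %||% character(0)),
                           housekeeping = genes %in% (hk %||% character(0)))),
    class = "cell_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
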