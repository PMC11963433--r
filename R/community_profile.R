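#' Rarefy an ASV count table
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (default: the minimum sample sum, the "minimum shared read count"), which
#' removes differential sequencing depth before diversity calculations.
#'
#' @param counts integer samples x ASVs matrix.
#' @param depth target depth; must not exceed any sample's total.
#' @param seed integer seed for the subsampling.
#' @return Integer matrix of the same shape with all row sums equal to
#'   `depth`.
#' @export
rarefy_counts <- function(counts, depth = min(rowSums(counts)), seed = 1L) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tot <- rowSums(counts)
  if (any(tot < depth)) {
    bad <- rownames(counts)[tot < depth]
    stop("sample(s) with fewer than ", depth, " reads: ",
         paste(bad, collapse = ", "))
  }
  set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    if (tot[i] == depth) next
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    keep <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(keep, nbins = ncol(counts))
  }
  storage.mode(out) <- "integer"
  out
}

#' Per-sample relative abundance
#'
#' @param counts samples x ASVs count matrix with positive row sums.
#' @return Matrix of proportions; rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("sample(s) with zero total reads")
  counts / tot
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|u - v|) / sum(u + v)`, bounded in [0, 1]: 0 for identical
#' profiles, 1 for disjoint supports.
#'
#' @param u,v non-negative numeric vectors of equal length.
#' @return The dissimilarity.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  s <- sum(u + v)
  if (s == 0) stop("both profiles are all-zero")
  sum(abs(u - v)) / s
}

#' All-pairs Bray-Curtis distance matrix
#'
#' @param mat samples x features non-negative matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  if (any(mat < 0)) stop("abundances must be non-negative")
  rs <- rowSums(mat)
  if (any(rs == 0)) stop("sample(s) with zero total")
  man <- as.matrix(stats::dist(mat, method = "manhattan"))
  d <- man / outer(rs, rs, "+")
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Bray-Curtis distance of every sample to the week-8 baseline
#'
#' For each sample, the distance to its own mouse's baseline-week sample
#' when present (`mode = "own"`), else to the centroid (mean relative
#' abundance) of the baseline samples of its treatment arm; `mode =
#' "centroid"` uses the centroid throughout.  By default counts are rarefied
#' to the minimum shared depth first.  yMB and iMB distances are compared
#' per timepoint with a Mann-Whitney test.
#'
#' @param counts samples x ASVs counts.
#' @param meta data.frame with `sample_id`, `mouse_id`, `age_weeks`,
#'   `treatment` matching the rows of `counts`.
#' @param baseline_week age of the baseline samples.
#' @param mode `"own"` (own-mouse baseline, centroid fallback) or
#'   `"centroid"`.
#' @param rarefy if `TRUE`, rarefy to the minimum sample sum first.
#' @param seed seed for rarefaction.
#' @return list with `distances` (per-sample data.frame) and `tests`
#'   (per-timepoint Mann-Whitney yMB vs iMB, baseline week excluded).
#' @export
distance_to_baseline <- function(counts, meta, baseline_week = 8,
                                 mode = c("own", "centroid"),
                                 rarefy = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nrow(counts) == nrow(meta),
            all(rownames(counts) == meta$sample_id))
  if (!any(meta$age_weeks == baseline_week))
    stop("no samples at the baseline week ", baseline_week)
  if (rarefy) counts <- rarefy_counts(counts, seed = seed)
  rel <- relative_abundance(counts)
  base_idx <- which(meta$age_weeks == baseline_week)
  centroids <- lapply(c(yMB = "yMB", iMB = "iMB"), function(tr) {
    idx <- base_idx[meta$treatment[base_idx] == tr]
    if (!length(idx)) return(NULL)
    colMeans(rel[idx, , drop = FALSE])
  })
  dist <- numeric(nrow(rel))
  ref <- character(nrow(rel))
  for (i in seq_len(nrow(rel))) {
    own <- base_idx[meta$mouse_id[base_idx] == meta$mouse_id[i]]
    if (mode == "own" && length(own)) {
      dist[i] <- bray_curtis(rel[i, ], rel[own[1], ])
      ref[i] <- "own_baseline"
    } else {
      cen <- centroids[[meta$treatment[i]]]
      if (is.null(cen)) stop("no baseline samples for arm ", meta$treatment[i])
      dist[i] <- bray_curtis(rel[i, ], cen)
      ref[i] <- "group_centroid"
    }
  }
  distances <- data.frame(meta, distance = dist, reference = ref)
  later <- sort(unique(meta$age_weeks[meta$age_weeks != baseline_week]))
  tests <- do.call(rbind, lapply(later, function(w) {
    dy <- dist[meta$age_weeks == w & meta$treatment == "yMB"]
    di <- dist[meta$age_weeks == w & meta$treatment == "iMB"]
    mw <- mann_whitney(dy, di, mode = "asymptotic")
    data.frame(age_weeks = w, mean_yMB = mean(dy), mean_iMB = mean(di),
               U = mw$U, p = mw$p)
  }))
  list(distances = distances, tests = tests)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (double-centering plus
#' eigendecomposition).  Coordinates are returned for the top `k` positive
#' eigenvalues; negative eigenvalues (possible for non-Euclidean distances
#' such as Bray-Curtis) are reported but their axes dropped, with a warning
#' if that leaves fewer than `k` axes.
#'
#' @param d symmetric distance matrix with zero diagonal (or a `dist`).
#' @param k number of axes requested.
#' @return list with `points` (samples x axes), `eigenvalues` (all of
#'   them), and `variance_explained` over the positive part.
#' @export
pcoa_ordination <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) ||
      any(abs(diag(d)) > 1e-12))
    stop("need a symmetric distance matrix with zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes")
    k <- length(pos)
  }
  axes <- pos[seq_len(k)]
  pts <- e$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(e$values[axes]), nrow = k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eigenvalues = e$values,
       variance_explained = e$values[axes] / sum(e$values[pos]))
}
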