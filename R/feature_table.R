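#' Longitudinal feature-abundance table
#'
#' Container for a samples x features abundance matrix joined to per-sample
#' metadata (mouse, age, treatment).  A `scale` tag records where the table
#' sits in the raw -> relative -> transformed pipeline, and every transform
#' checks and updates it so the steps cannot be applied out of order.
#'
#' @param abundance numeric matrix, samples in rows, features in columns;
#'   must be non-negative with both dimnames set.
#' @param meta data.frame with one row per sample and columns `sample_id`,
#'   `mouse_id`, `age_weeks`, `treatment` (values `"yMB"` or `"iMB"`).
#' @param scale one of `"raw"`, `"relative"`, `"transformed"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(abundance, meta,
                          scale = c("raw", "relative", "transformed")) {
  scale <- match.arg(scale)
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("`abundance` must have sample rownames and feature colnames")
  if (scale != "transformed" && any(abundance < 0))
    stop("negative abundances are not allowed")
  req <- c("sample_id", "mouse_id", "age_weeks", "treatment")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(rownames(abundance) %in% meta$sample_id))
    stop("every sample in `abundance` needs a metadata row")
  if (!all(meta$treatment %in% c("yMB", "iMB")))
    stop("treatment must be 'yMB' or 'iMB'")
  meta <- meta[match(rownames(abundance), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(abundance = abundance, meta = meta, scale = scale),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features [%s scale]\n",
              nrow(x$abundance), ncol(x$abundance), x$scale))
  cat(sprintf("  mice: %d  ages: %s  treatments: %s\n",
              length(unique(x$meta$mouse_id)),
              paste(sort(unique(x$meta$age_weeks)), collapse = ","),
              paste(sort(unique(x$meta$treatment)), collapse = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' Keep features present in a minimum fraction of samples
#'
#' A feature is retained when it is non-zero in at least
#' `min_prevalence` of the samples; the comparison is inclusive
#' (prevalence == threshold is kept).  Operates on the raw zero pattern, which
#' total-sum scaling preserves, so filtering before or after TSS is
#' equivalent.
#'
#' @param table a [feature_table()] on the raw or relative scale.
#' @param min_prevalence fraction of samples in (0, 1].
#' @return The filtered `feature_table`, feature order preserved.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1 ||
      min_prevalence <= 0 || min_prevalence > 1)
    stop("`min_prevalence` must be a single value in (0, 1]")
  if (table$scale == "transformed")
    stop("prevalence_filter expects a raw or relative table")
  n <- nrow(table$abundance)
  prev <- colSums(table$abundance > 0)
  # inclusive "at least": compare counts, not floating fractions
  keep <- prev >= min_prevalence * n - 1e-12
  if (!any(keep))
    warning("no features pass the prevalence filter")
  table$abundance <- table$abundance[, keep, drop = FALSE]
  table
}

#' Total-sum scaling
#'
#' Divides every sample (row) by its total so that each sample sums to one.
#'
#' @param table a [feature_table()] on the raw scale.
#' @return The table on the relative scale.
#' @export
tss_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "raw")
    stop("tss_normalize expects a raw-scale table")
  tot <- rowSums(table$abundance)
  if (any(tot == 0)) {
    bad <- rownames(table$abundance)[tot == 0]
    stop("sample(s) with zero total abundance: ", paste(bad, collapse = ", "))
  }
  table$abundance <- table$abundance / tot
  table$scale <- "relative"
  table
}

#' Offset log10 transform for sparse relative abundances
#'
#' Computes `log10(x + 0.01) + 2`, which maps zero exactly to zero while
#' perturbing non-zero relative abundances only minimally; used for KEGG
#' ortholog tables that contain structural zeros.
#'
#' @param x non-negative numeric vector, matrix, or a relative-scale
#'   [feature_table()].
#' @return The transformed values (a `feature_table` on the transformed
#'   scale when the input is one).
#' @export
transform_ko <- function(x) {
  if (inherits(x, "feature_table")) {
    if (x$scale != "relative")
      stop("transform_ko expects a relative-scale table")
    x$abundance <- transform_ko(x$abundance)
    x$scale <- "transformed"
    return(x)
  }
  if (any(x < 0)) stop("transform_ko requires non-negative input")
  log10(x + 0.01) + 2
}

#' Plain log10 transform for strictly positive abundances
#'
#' For feature families without zeros (e.g. ecological relationship
#' frequencies observed in every sample) a plain `log10(x)` is used.
#'
#' @param x positive numeric vector, matrix, or relative-scale
#'   [feature_table()].
#' @return log10 of the input.
#' @export
transform_eco <- function(x) {
  if (inherits(x, "feature_table")) {
    if (x$scale != "relative")
      stop("transform_eco expects a relative-scale table")
    x$abundance <- transform_eco(x$abundance)
    x$scale <- "transformed"
    return(x)
  }
  if (any(x <= 0))
    stop("transform_eco requires strictly positive input")
  log10(x)
}

#' Write / read a feature table as TSV
#'
#' The abundance matrix and metadata are written side by side
#' (`<stem>_abundance.tsv`, `<stem>_meta.tsv`).
#'
#' @param table a [feature_table()].
#' @param stem path stem without extension.
#' @return `stem`, invisibly.
#' @export
write_feature_table <- function(table, stem) {
  stopifnot(inherits(table, "feature_table"))
  ab <- data.frame(sample_id = rownames(table$abundance),
                   table$abundance, check.names = FALSE)
  utils::write.table(ab, paste0(stem, "_abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- table$meta
  meta$scale <- table$scale
  utils::write.table(meta, paste0(stem, "_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(stem) {
  ab <- utils::read.delim(paste0(stem, "_abundance.tsv"), check.names = FALSE)
  meta <- utils::read.delim(paste0(stem, "_meta.tsv"))
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$sample_id
  feature_table(m, meta[, setdiff(names(meta), "scale")],
                scale = meta$scale[1])
}
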