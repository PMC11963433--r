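#' Fit the per-feature linear mixed-effects model
#'
#' Models one feature's transformed abundance as
#' `y ~ age * treatment + (1 | mouse)` by REML, with iMB as the treatment
#' reference level and age in weeks, uncentered, so the fixed-effect
#' coefficient of age is directly the iMB age slope and the yMB slope is
#' `beta_age + beta_interaction`.  The interaction is tested with a Wald t
#' test using containment degrees of freedom
#' `n_obs - n_mice - 2` (the residual df for within-mouse age effects,
#' which equals the Satterthwaite df in a balanced design).  If the mixed
#' model
#' errors out (e.g. zero residual variance in noise-free data) the fit falls
#' back to ordinary least squares, which coincides with the mixed model when
#' the mouse variance is zero; only a fit that fails both routes is reported
#' as failed.
#'
#' @param table a transformed-scale [feature_table()].
#' @param feature_id feature column to fit.
#' @param refit_from optional previous `lmer` fit to refit with a new
#'   response (much faster in a screen over many features).
#' @return list with `coef` (fixed effects), `slope_iMB`, `slope_yMB`,
#'   `p_interaction`, `singular`, `method` (`"lmm"`, `"ols"` or
#'   `"failed"`), and `fit` (the lmer object or `NULL`).
#' @export
fit_feature_lmm <- function(table, feature_id, refit_from = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "transformed")
    stop("the screen expects a transformed-scale table")
  if (length(unique(table$meta$treatment)) < 2)
    stop("both treatments must be present")
  df <- data.frame(
    y = table$abundance[, feature_id],
    age = table$meta$age_weeks,
    treatment = factor(table$meta$treatment, levels = c("iMB", "yMB")),
    mouse = factor(table$meta$mouse_id))
  fit <- NULL
  if (!is.null(refit_from))
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::refit(refit_from, newresp = df$y))), error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(y ~ age * treatment + (1 | mouse), data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore")))),
      error = function(e) NULL)
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    method <- "lmm"
    singular <- lme4::isSingular(fit)
  } else {
    ols <- tryCatch(stats::lm(y ~ age * treatment, data = df),
                    error = function(e) NULL)
    if (is.null(ols) || any(is.na(stats::coef(ols))))
      return(list(coef = NULL, slope_iMB = NA_real_, slope_yMB = NA_real_,
                  p_interaction = NA_real_, singular = NA, method = "failed",
                  fit = NULL))
    beta <- stats::coef(ols)
    se <- sqrt(diag(stats::vcov(ols)))
    method <- "ols"
    singular <- TRUE
    fit <- NULL
  }
  ia <- "age:treatmentyMB"
  df_t <- max(1, nrow(df) - nlevels(df$mouse) - 2)
  p <- if (se[ia] < 1e-12) {
    if (abs(beta[ia]) < 1e-12) 1 else 0  # noise-free degenerate fit
  } else 2 * stats::pt(-abs(beta[ia] / se[ia]), df = df_t)
  list(coef = beta,
       slope_iMB = unname(beta["age"]),
       slope_yMB = unname(beta["age"] + beta[ia]),
       p_interaction = unname(p),
       singular = singular, method = method, fit = fit)
}

#' Classify the age-dependence direction of a feature
#'
#' Given the per-treatment age slopes of a significant feature: strictly
#' opposite signs give `inverted` (the age trend reverses under the young
#' microbiome), both positive `concordant_up`, both negative
#' `concordant_down`.  An exact zero slope is a measure-zero event and is
#' labelled `indeterminate` rather than silently binned.
#'
#' @param slope_yMB,slope_iMB finite age slopes (transformed units / week).
#' @return One of `"inverted"`, `"concordant_up"`, `"concordant_down"`,
#'   `"indeterminate"`.
#' @export
classify_direction <- function(slope_yMB, slope_iMB) {
  if (!is.finite(slope_yMB) || !is.finite(slope_iMB))
    stop("slopes must be finite")
  if (slope_yMB == 0 || slope_iMB == 0) return("indeterminate")
  if (sign(slope_yMB) != sign(slope_iMB)) return("inverted")
  if (slope_yMB > 0) "concordant_up" else "concordant_down"
}

#' Mixed-model interaction screen over all features
#'
#' Fits [fit_feature_lmm()] per feature, Benjamini-Hochberg-adjusts the
#' age-by-treatment interaction p values across all converged features
#' (failed fits are excluded before adjustment, with a warning), and assigns
#' a direction class only where `fdr <= alpha`.
#'
#' @param table a transformed-scale [feature_table()].
#' @param alpha FDR threshold for calling a feature age-treatment dependent.
#' @return data.frame with one row per feature: slopes, `p_interaction`,
#'   `fdr_interaction`, `direction`, `method`.
#' @export
screen_features <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  feats <- colnames(table$abundance)
  if (length(feats) < 2)
    stop("need at least 2 features for a BH-adjusted screen")
  template <- NULL
  rows <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- fit_feature_lmm(table, feats[k], refit_from = template)
    if (is.null(template) && f$method == "lmm") template <- f$fit
    rows[[k]] <- data.frame(
      feature_id = feats[k], slope_iMB = f$slope_iMB,
      slope_yMB = f$slope_yMB, p_interaction = f$p_interaction,
      method = f$method)
  }
  res <- do.call(rbind, rows)
  ok <- res$method != "failed" & !is.na(res$p_interaction)
  if (any(!ok))
    warning(sum(!ok), " feature fit(s) failed and were excluded from FDR")
  res$fdr_interaction <- NA_real_
  res$fdr_interaction[ok] <- stats::p.adjust(res$p_interaction[ok],
                                             method = "BH")
  res$direction <- "not_significant"
  res$direction[!ok] <- "fit_failed"
  sig <- ok & res$fdr_interaction <= alpha
  res$direction[sig] <- mapply(classify_direction,
                               res$slope_yMB[sig], res$slope_iMB[sig])
  res
}

#' Hypergeometric pathway over-representation
#'
#' One-sided upper-tail hypergeometric test of each pathway's overlap with a
#' significant feature set, BH-adjusted across the tested pathways.
#' Pathways are tested when their size within the universe is in
#' `[min_gs, max_gs]`; rows are reported when `p <= p_cut` and the overlap
#' is at least `min_overlap` features.  The universe defaults to all
#' annotated features (every feature carrying at least one pathway
#' membership).
#'
#' @param significant character vector of significant feature ids.
#' @param annotation data.frame with columns `feature_id`, `pathway_id`.
#' @param universe background feature set; must contain `significant`.
#' @param min_gs,max_gs tested pathway size limits.
#' @param p_cut raw-p reporting threshold.
#' @param min_overlap minimum overlap to report.
#' @return data.frame: `pathway_id`, `overlap`, `size`, `n_significant`,
#'   `universe_size`, `p`, `fdr`, `members` (comma-joined overlap).
#' @export
pathway_enrichment <- function(significant, annotation,
                               universe = unique(annotation$feature_id),
                               min_gs = 3, max_gs = 500,
                               p_cut = 0.05, min_overlap = 3) {
  stopifnot(all(c("feature_id", "pathway_id") %in% names(annotation)))
  if (!all(significant %in% universe))
    stop("significant set must be contained in the universe")
  if (!length(significant))
    return(data.frame(pathway_id = character(0), overlap = integer(0),
                      size = integer(0), n_significant = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      fdr = numeric(0), members = character(0)))
  ann <- annotation[annotation$feature_id %in% universe, ]
  N <- length(universe)
  n_sig <- length(unique(significant))
  paths <- split(unique(ann[c("feature_id", "pathway_id")])$feature_id,
                 unique(ann[c("feature_id", "pathway_id")])$pathway_id)
  sizes <- lengths(paths)
  tested <- names(paths)[sizes >= min_gs & sizes <= max_gs]
  if (!length(tested)) return(pathway_enrichment(character(0), annotation))
  rows <- lapply(tested, function(pw) {
    members <- paths[[pw]]
    ov <- intersect(members, significant)
    data.frame(pathway_id = pw, overlap = length(ov),
               size = length(members), n_significant = n_sig,
               universe_size = N,
               p = stats::phyper(length(ov) - 1, length(members),
                                 N - length(members), n_sig,
                                 lower.tail = FALSE),
               members = paste(sort(ov), collapse = ","))
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$p <= p_cut & res$overlap >= min_overlap, , drop = FALSE]
  res <- res[order(res$p), c("pathway_id", "overlap", "size",
                             "n_significant", "universe_size", "p", "fdr",
                             "members")]
  rownames(res) <- NULL
  res
}

#' Mean pathway log2 fold change between two ages
#'
#' Per member feature, the log2 ratio of its mean relative abundance at
#' `t_old` weeks over `t_young` weeks within each treatment arm; the pathway
#' value is the arithmetic mean over member features.  A group mean of
#' exactly zero gets a pseudocount of half the smallest non-zero relative
#' abundance in the table and the feature is flagged.
#'
#' @param table a relative-scale [feature_table()].
#' @param members feature ids belonging to the pathway.
#' @param t_old,t_young ages in weeks; both must be sampled in both arms.
#' @return list with `pathway_log2fc` (named per treatment), `per_feature`
#'   (data.frame) and `pseudocount_used`.
#' @export
pathway_log2fc <- function(table, members, t_old = 120, t_young = 72) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "relative")
    stop("pathway_log2fc expects relative abundances")
  miss <- setdiff(members, colnames(table$abundance))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  meta <- table$meta
  for (tr in c("yMB", "iMB")) for (tt in c(t_old, t_young))
    if (!any(meta$treatment == tr & meta$age_weeks == tt))
      stop("no samples for treatment ", tr, " at week ", tt)
  nz <- table$abundance[table$abundance > 0]
  pseudo <- min(nz) / 2
  used_pseudo <- FALSE
  per <- do.call(rbind, lapply(members, function(f) {
    row <- lapply(c(yMB = "yMB", iMB = "iMB"), function(tr) {
      m_old <- mean(table$abundance[meta$treatment == tr &
                                      meta$age_weeks == t_old, f])
      m_young <- mean(table$abundance[meta$treatment == tr &
                                        meta$age_weeks == t_young, f])
      flag <- m_old == 0 || m_young == 0
      if (m_old == 0) m_old <- pseudo
      if (m_young == 0) m_young <- pseudo
      c(log2(m_old / m_young), flag)
    })
    data.frame(feature_id = f,
               log2fc_yMB = row$yMB[1], log2fc_iMB = row$iMB[1],
               pseudocount = as.logical(row$yMB[2] | row$iMB[2]))
  }))
  used_pseudo <- any(per$pseudocount)
  list(pathway_log2fc = c(yMB = mean(per$log2fc_yMB),
                          iMB = mean(per$log2fc_iMB)),
       per_feature = per, pseudocount_used = used_pseudo)
}
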