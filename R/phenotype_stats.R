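#' Trapezoidal area under the curve over a time window
#'
#' Integrates a (time, value) series by the trapezoid rule over
#' `[window_start, window_end]`.  When no observation falls exactly on a
#' window edge the series is linearly interpolated there, so the window of
#' interest (e.g. weeks 80-120 of a weight curve, or the 0-120 min span of a
#' glucose tolerance test) need not coincide with the sampling grid.
#'
#' @param time,value numeric vectors of equal length; `time` strictly
#'   increasing.
#' @param window_start,window_end window limits; must lie within the observed
#'   time range.  Defaults to the full series.
#' @return The trapezoidal integral (value units x time units).
#' @export
auc_trapezoid <- function(time, value, window_start = min(time),
                          window_end = max(time)) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (length(time) < 2) stop("need at least 2 points for an AUC")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (window_start >= window_end) stop("window_start must be < window_end")
  if (window_start < min(time) || window_end > max(time))
    stop("AUC window outside the observed time range")
  edges <- setdiff(c(window_start, window_end), time)
  if (length(edges)) {
    value <- c(value, stats::approx(time, value, xout = edges)$y)
    time <- c(time, edges)
    value <- value[order(time)]
    time <- sort(time)
  }
  keep <- time >= window_start & time <= window_end
  t <- time[keep]; v <- value[keep]
  if (length(t) < 2) stop("fewer than 2 points in window")
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  In `"auto"` mode the p
#' value is exact (full enumeration of the U null distribution) when both
#' groups have at most `exact_max` observations and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_max exact-enumeration cutoff per group for `"auto"`.
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         exact_max = 8) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both groups; p = 1")
    return(list(U = U, p = 1))
  }
  exact <- switch(mode,
                  exact = TRUE,
                  asymptotic = FALSE,
                  auto = !ties && length(x) <= exact_max && length(y) <= exact_max)
  if (exact && ties)
    stop("exact Mann-Whitney p is undefined with ties; use asymptotic mode")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' Compares right-censored survival between two groups with the standard
#' Mantel-Cox statistic over pooled event times (1 df chi-square).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event observed (death), 0 = right-censored.
#' @param group two-level group labels.
#' @return list with `chisq`, `p`, and the per-group observed and expected
#'   event counts.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("log-rank test needs exactly 2 groups")
  if (!any(event == 1)) stop("no events observed")
  if (any(time <= 0)) stop("times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Group comparison of windowed AUCs
#'
#' Convenience wrapper: computes [auc_trapezoid()] per subject from a long
#' time-series table and compares groups with [mann_whitney()].
#'
#' @param series data.frame with columns `subject_id`, `group`, `time`,
#'   `value`.
#' @param window_start,window_end integration window.
#' @param mode passed to [mann_whitney()].
#' @return list with the per-subject `auc` table and the test (`U`, `p`).
#' @export
compare_auc <- function(series, window_start, window_end, mode = "auto") {
  stopifnot(all(c("subject_id", "group", "time", "value") %in% names(series)))
  sp <- split(series, series$subject_id)
  auc <- data.frame(
    subject_id = names(sp),
    group = vapply(sp, function(d) as.character(d$group[1]), ""),
    auc = vapply(sp, function(d) {
      o <- order(d$time)
      auc_trapezoid(d$time[o], d$value[o], window_start, window_end)
    }, 0),
    row.names = NULL)
  gs <- unique(auc$group)
  if (length(gs) != 2) stop("need exactly 2 groups")
  mw <- mann_whitney(auc$auc[auc$group == gs[1]],
                     auc$auc[auc$group == gs[2]], mode = mode)
  list(auc = auc, U = mw$U, p = mw$p)
}
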