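test_that("trapezoidal AUC matches hand-worked integrals", {
  # constant 5 over a 40-week window
  expect_equal(auc_trapezoid(c(80, 100, 120), c(5, 5, 5)), 200)
  # two trapezoids: (5+10)/2*15 + (10+5)/2*15 = 225
  expect_equal(auc_trapezoid(c(0, 15, 30), c(5, 10, 5)), 225)
  # a single segment is (v1+v2)/2 * (t2-t1)
  expect_equal(auc_trapezoid(c(10, 20), c(3, 7)), 50)
  # window edges interpolate linearly: value at t=5 is 7.5
  expect_equal(auc_trapezoid(c(0, 10), c(5, 10), 5, 10), (7.5 + 10) / 2 * 5)
  expect_error(auc_trapezoid(c(0, 10), c(1, 2), -5, 10), "window")
  expect_error(auc_trapezoid(c(0, 10, 5), c(1, 2, 3)), "increasing")
})

test_that("AUC is additive over adjacent windows", {
  set.seed(2)
  t <- c(0, sort(runif(10, 0, 100)), 100)
  v <- rnorm(12, 10)
  whole <- auc_trapezoid(t, v, 10, 90)
  expect_equal(auc_trapezoid(t, v, 10, 47) + auc_trapezoid(t, v, 47, 90),
               whole, tolerance = 1e-10)
})

test_that("Mann-Whitney exact p matches enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  # brute-force permutation oracle over tie-free inputs, n <= 6
  set.seed(5)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    vals <- sample(100, nx + ny)           # distinct -> tie-free
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(mann_whitney(x, y, mode = "exact")$p, perm_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties, identity and symmetry", {
  expect_warning(res <- mann_whitney(c(1, 1, 2), c(1, 2, 1)), NA)
  expect_warning(out <- mann_whitney(c(3, 3), c(3, 3)), "identical")
  expect_equal(out$p, 1)
  set.seed(6)
  x <- rnorm(10); y <- rnorm(12)
  a <- mann_whitney(x, y, mode = "asymptotic")
  b <- mann_whitney(y, x, mode = "asymptotic")
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(unname(a$U + b$U), length(x) * length(y))
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("log-rank matches a hand-worked 6-subject table", {
  # group A events at 2, 4, 6; group B events at 8, 10 and one censored at 9
  time <- c(2, 4, 6, 8, 10, 9)
  event <- c(1, 1, 1, 1, 1, 0)
  group <- rep(c("A", "B"), each = 3)
  res <- logrank_test(time, event, group)
  expect_equal(res$chisq, hand_logrank_chisq(time, event, group),
               tolerance = 1e-8)
  expect_lt(res$p, 0.05)
  # identical event-time vectors in both groups: no signal
  t2 <- c(1, 2, 3, 1, 2, 3)
  res2 <- logrank_test(t2, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "events")
})

test_that("early censoring joins no risk set and leaves the statistic unchanged", {
  time <- c(5, 7, 9, 11, 13, 15)
  event <- rep(1, 6)
  group <- rep(c("A", "B"), 3)
  base <- logrank_test(time, event, group)
  # a subject censored before the first event never enters an event-time
  # risk set
  aug <- logrank_test(c(time, 1), c(event, 0), c(group, "A"))
  expect_equal(aug$chisq, base$chisq, tolerance = 1e-12)
  # a censored subject *after* some events does join earlier risk sets
  aug2 <- logrank_test(c(time, 10), c(event, 0), c(group, "A"))
  expect_false(isTRUE(all.equal(aug2$chisq, base$chisq)))
  expect_equal(aug2$chisq,
               hand_logrank_chisq(c(time, 10), c(event, 0), c(group, "A")),
               tolerance = 1e-8)
})

test_that("null phenotype simulations are calibrated", {
  # exact Mann-Whitney p values are discrete at n = 6, so calibration is
  # checked at fixed cutoffs (super-uniformity) rather than by a KS test
  ps_mw <- vapply(1:200, function(s) {
    ph <- gen_phenotype(n_per_group = 6, auc_offset = 0, seed = s)
    suppressWarnings(compare_auc(ph$weights, 80, 120)$p)
  }, 0)
  expect_lt(mean(ps_mw <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(ps_mw <= 0.20), 0.20 + 2 * sqrt(0.20 * 0.80 / 200))
  expect_gt(stats::median(ps_mw), 0.25)

  # null survival: log-rank flags at most its nominal rate
  ps_lr <- vapply(1:200, function(s) {
    ph <- gen_phenotype(n_per_group = 10, survival_hazard_ratio = 1,
                        seed = s + 1000)
    logrank_test(ph$survival$time, ph$survival$event, ph$survival$group)$p
  }, 0)
  expect_lt(mean(ps_lr <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("group AUC comparison detects a planted weight offset", {
  detected <- vapply(1:10, function(s) {
    ph <- gen_phenotype(n_per_group = 10, auc_offset = 200, seed = s)
    compare_auc(ph$weights, 80, 120)$p < 0.05
  }, TRUE)
  expect_gte(mean(detected), 0.8)
})
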