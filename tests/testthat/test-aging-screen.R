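test_that("noise-free planted slopes are recovered exactly", {
  cfg <- screen_sim_config(n_null = 0, n_inverted = 5, noise_sd = 0,
                           mouse_sd = 0, seed = 1)
  sim <- gen_ko_table(cfg)
  res <- screen_features(sim$table)
  expect_lt(max(abs(res$slope_yMB - sim$truth$slope_yMB)), 1e-6)
  expect_lt(max(abs(res$slope_iMB - sim$truth$slope_iMB)), 1e-6)
  expect_true(all(res$direction == "inverted"))
})

test_that("balanced-design mixed-model fixed effects equal the OLS estimates", {
  cfg <- screen_sim_config(n_null = 3, n_inverted = 2, noise_sd = 0.2,
                           mouse_sd = 0.3, seed = 6)
  sim <- gen_ko_table(cfg)
  for (f in colnames(sim$table$abundance)) {
    fit <- fit_feature_lmm(sim$table, f)
    df <- data.frame(y = sim$table$abundance[, f],
                     age = sim$table$meta$age_weeks,
                     treatment = factor(sim$table$meta$treatment,
                                        levels = c("iMB", "yMB")))
    ols <- coef(lm(y ~ age * treatment, data = df))
    expect_equal(unname(fit$coef), unname(ols), tolerance = 1e-6)
  }
})

test_that("direction classification follows the sign logic", {
  expect_identical(classify_direction(0.2, -0.3), "inverted")
  expect_identical(classify_direction(-0.2, 0.3), "inverted")
  expect_identical(classify_direction(0.1, 0.2), "concordant_up")
  expect_identical(classify_direction(-0.1, -0.2), "concordant_down")
  expect_identical(classify_direction(0, -0.2), "indeterminate")
  expect_error(classify_direction(NA_real_, 1), "finite")
})

test_that("swapping treatment labels mirrors the slopes but keeps the classes", {
  cfg <- screen_sim_config(n_null = 0, n_inverted = 4, n_concordant_up = 3,
                           noise_sd = 0.05, seed = 12)
  sim <- gen_ko_table(cfg)
  res <- screen_features(sim$table)
  swapped <- sim$table
  swapped$meta$treatment <- ifelse(swapped$meta$treatment == "yMB",
                                   "iMB", "yMB")
  res_sw <- screen_features(swapped)
  expect_equal(res_sw$slope_yMB, res$slope_iMB, tolerance = 1e-6)
  expect_equal(res_sw$slope_iMB, res$slope_yMB, tolerance = 1e-6)
  expect_identical(res_sw$direction == "inverted",
                   res$direction == "inverted")
})

test_that("screen FDR values equal a hand Benjamini-Hochberg computation", {
  cfg <- screen_sim_config(n_null = 30, n_inverted = 5, seed = 3)
  sim <- gen_ko_table(cfg)
  res <- screen_features(sim$table)
  expect_equal(res$fdr_interaction, hand_bh(res$p_interaction),
               tolerance = 1e-12)
  expect_true(all(res$fdr_interaction >= res$p_interaction - 1e-12))
  expect_true(all(res$direction[res$fdr_interaction > 0.05] %in%
                    c("not_significant", "fit_failed")))
})

test_that("screen refuses degenerate inputs", {
  cfg <- screen_sim_config(n_null = 2, seed = 1)
  sim <- gen_ko_table(cfg)
  one <- sim$table
  one$abundance <- one$abundance[, 1, drop = FALSE]
  expect_error(screen_features(one), "2 features")
  expect_error(screen_features(sim$table, alpha = 1.5), "alpha")
})

test_that("pathway enrichment matches the exact hypergeometric tail", {
  # universe of 20 features, one pathway of 5, 6 significant, overlap 4
  universe <- sprintf("K%02d", 1:20)
  ann <- data.frame(feature_id = universe[1:5], pathway_id = "map001")
  sig <- universe[c(1:4, 10, 11)]
  res <- pathway_enrichment(sig, ann, universe = universe)
  expect_equal(nrow(res), 1)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, 0.013932, tolerance = 1e-4)
  expect_equal(res$p, hand_hyper_tail(4, 5, 20, 6), tolerance = 1e-12)
})

test_that("saturated overlap gives p = 1 and tiny pathways are never tested", {
  universe <- sprintf("K%02d", 1:5)
  ann <- rbind(
    data.frame(feature_id = universe, pathway_id = "map_all"),
    data.frame(feature_id = universe[1:2], pathway_id = "map_tiny"))
  res <- pathway_enrichment(universe, ann, universe = universe,
                            p_cut = 1, min_overlap = 0)
  expect_identical(res$pathway_id, "map_all")   # size-2 pathway skipped
  expect_equal(res$p, 1)
})

test_that("enrichment p values match enumeration on random small instances", {
  set.seed(99)
  for (rep in 1:20) {
    N <- sample(8:25, 1)
    K <- sample(3:min(8, N - 1), 1)
    n <- sample(2:(N - 1), 1)
    universe <- sprintf("F%03d", seq_len(N))
    ann <- data.frame(feature_id = universe[seq_len(K)], pathway_id = "pw")
    sig <- sample(universe, n)
    res <- pathway_enrichment(sig, ann, universe = universe,
                              p_cut = 1, min_overlap = 0)
    ov <- length(intersect(sig, universe[seq_len(K)]))
    expect_equal(res$p, hand_hyper_tail(ov, K, N, n), tolerance = 1e-12)
  }
})

test_that("pathway log2 fold changes average member fold changes", {
  # three features whose relative abundance doubles, doubles, and x16
  # between weeks 72 and 120 -> per-feature log2fc 1, 1, 4 -> mean 2
  ages <- rep(c(72, 120), each = 4)
  treat <- rep(c("yMB", "yMB", "iMB", "iMB"), 2)
  vals <- cbind(f1 = ifelse(ages == 72, 0.02, 0.04),
                f2 = ifelse(ages == 72, 0.01, 0.02),
                f3 = ifelse(ages == 72, 0.005, 0.08))
  filler <- 1 - rowSums(vals)
  ab <- cbind(vals, filler = filler)
  rownames(ab) <- sprintf("s%d", seq_len(8))
  meta <- data.frame(sample_id = rownames(ab),
                     mouse_id = sprintf("m%d", rep(1:4, 2)),
                     age_weeks = ages, treatment = treat)
  tab <- feature_table(ab, meta, scale = "relative")
  one <- pathway_log2fc(tab, "f1")
  expect_equal(unname(one$pathway_log2fc["yMB"]), 1, tolerance = 1e-12)
  three <- pathway_log2fc(tab, c("f1", "f2", "f3"))
  expect_equal(unname(three$pathway_log2fc["yMB"]), 2, tolerance = 1e-12)
  expect_equal(unname(three$pathway_log2fc["iMB"]), 2, tolerance = 1e-12)
  # opposite fold changes cancel in the arithmetic mean
  ab2 <- cbind(up = ifelse(ages == 72, 0.02, 0.04),
               down = ifelse(ages == 72, 0.04, 0.02))
  ab2 <- cbind(ab2, filler = 1 - rowSums(ab2))
  rownames(ab2) <- rownames(ab)
  tab2 <- feature_table(ab2, meta, scale = "relative")
  both <- pathway_log2fc(tab2, c("up", "down"))
  expect_equal(unname(both$pathway_log2fc["yMB"]), 0, tolerance = 1e-12)
})

test_that("zero group means fall back to a flagged pseudocount", {
  ages <- rep(c(72, 120), each = 4)
  treat <- rep(c("yMB", "yMB", "iMB", "iMB"), 2)
  ab <- cbind(gone = ifelse(ages == 120, 0, 0.05),
              filler = ifelse(ages == 120, 1, 0.95))
  rownames(ab) <- sprintf("s%d", 1:8)
  meta <- data.frame(sample_id = rownames(ab),
                     mouse_id = sprintf("m%d", rep(1:4, 2)),
                     age_weeks = ages, treatment = treat)
  tab <- feature_table(ab, meta, scale = "relative")
  res <- pathway_log2fc(tab, "gone")
  expect_true(res$pseudocount_used)
  expect_true(all(is.finite(res$pathway_log2fc)))
})
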