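test_that("FBA solves the hand-solvable chain model", {
  m <- tiny_chain(U = 10)
  sol <- fba(m)
  expect_equal(sol$growth, 10, tolerance = 1e-9)
  # steady state and bounds hold at the optimum
  S <- rbind(A_e = c(-1, -1, 0), A_c = c(0, 1, -1))
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-9)
  expect_true(all(sol$fluxes >= c(-10, 0, 0) - 1e-9))

  starved <- fba(m, medium = c(EX_A_e = 0))
  expect_equal(starved$growth, 0, tolerance = 1e-9)
})

test_that("growth is scale-covariant in the bounds", {
  m <- tiny_chain(U = 7)
  g1 <- fba(m)$growth
  m2 <- m
  for (rid in names(m2$reactions)) {
    m2$reactions[[rid]]$lb <- 2 * m2$reactions[[rid]]$lb
    m2$reactions[[rid]]$ub <- 2 * m2$reactions[[rid]]$ub
  }
  expect_equal(fba(m2)$growth, 2 * g1, tolerance = 1e-9)
})

test_that("the LP core satisfies steady state and bounds on all fixtures", {
  kinds <- c("competition", "neutralism", "commensalism", "mutualism",
             "amensalism", "exploitation")
  for (k in kinds) {
    p <- gen_toy_model_pairs(k, seed = 2)
    comm <- build_pair(p$model1, p$model2, medium = p$medium)
    S <- rejuvenome:::stoich_matrix(comm)
    sol <- fba(comm)
    expect_identical(sol$status, "optimal")
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
    lb <- vapply(comm$reactions, `[[`, 0, "lb")
    ub <- vapply(comm$reactions, `[[`, 0, "ub")
    expect_true(all(sol$fluxes >= lb - 1e-8 & sol$fluxes <= ub + 1e-8))
  }
})

test_that("model validation catches structural defects", {
  mets <- data.frame(id = c("A_e", "A_c"),
                     compartment = c("extracellular", "cytosol"))
  expect_error(metabolic_model("x", mets,
    list(R1 = list(stoich = c(ghost = 1), lb = 0, ub = 1)), "R1"),
    "undeclared")
  expect_error(metabolic_model("x", mets,
    list(R1 = list(stoich = c(A_c = 1), lb = 2, ub = 1)), "R1"),
    "lb > ub")
  expect_error(metabolic_model("x", mets,
    list(R1 = list(stoich = c(A_c = -1), lb = 0, ub = 1)), "R2"),
    "not found")
})

test_that("disjoint-substrate pairs grow as in mono-culture", {
  p <- gen_toy_model_pairs("neutralism", seed = 4)
  med1 <- p$medium[names(p$medium) %in% p$model1$exchanges]
  med2 <- p$medium[names(p$medium) %in% p$model2$exchanges]
  g1 <- fba(p$model1, medium = med1)$growth
  g2 <- fba(p$model2, medium = med2)$growth
  comm <- build_pair(p$model1, p$model2, medium = p$medium)
  pg <- pair_growth(comm)
  expect_equal(unname(pg$g_pair), c(g1, g2), tolerance = 1e-8)
})

test_that("a shared substrate splits by the FVA midpoint", {
  p <- gen_toy_model_pairs("competition", seed = 1)
  U <- -p$medium[["EX_A_e"]]
  comm <- build_pair(p$model1, p$model2, medium = p$medium)
  pg <- pair_growth(comm)
  expect_equal(pg$g_total, U, tolerance = 1e-8)
  # degenerate optimum: each member can take anything from 0 to all of it
  expect_equal(unname(pg$fva[[1]]), c(0, U), tolerance = 1e-8)
  expect_equal(unname(pg$g_pair), c(U / 2, U / 2), tolerance = 1e-8)
})

test_that("an obligate byproduct consumer grows only in co-culture", {
  p <- gen_toy_model_pairs("commensalism", seed = 5)
  med2 <- p$medium[names(p$medium) %in% p$model2$exchanges]
  g2_alone <- fba(p$model2, medium = if (length(med2)) med2 else NULL)$growth
  expect_equal(g2_alone, 0, tolerance = 1e-9)
  comm <- build_pair(p$model1, p$model2, medium = p$medium)
  pg <- pair_growth(comm)
  expect_gt(pg$g_pair[[2]], 1)
})

test_that("sign-pair classification maps to the six classical types", {
  expect_identical(classify_pair(1, 1, 0.5, 0.5), "competition")
  expect_identical(classify_pair(1, 1, 1, 1), "neutralism")
  expect_identical(classify_pair(1, 0, 1, 0.3), "commensalism")
  expect_identical(classify_pair(0, 0, 1, 1), "mutualism")
  expect_identical(classify_pair(1, 1, 1, 0.2), "amensalism")
  expect_identical(classify_pair(0, 1, 0.8, 0.5), "exploitation")
  expect_error(classify_pair(-1, 1, 1, 1), "non-negative")
})

test_that("classification is symmetric and closed over sign patterns", {
  # swapping members never changes the unordered class
  set.seed(7)
  for (i in 1:50) {
    g <- runif(4, 0, 2)
    expect_identical(classify_pair(g[1], g[2], g[3], g[4]),
                     classify_pair(g[2], g[1], g[4], g[3]))
  }
  # exhaustive sign-pattern enumeration yields exactly 6 distinct classes
  deltas <- c(-0.5, 0, 0.5)
  rels <- character(0)
  for (d1 in deltas) for (d2 in deltas)
    rels <- c(rels, classify_pair(1, 1, 1 + d1, 1 + d2))
  expect_setequal(unique(rels),
                  c("mutualism", "commensalism", "exploitation",
                    "neutralism", "amensalism", "competition"))
})

test_that("the full FBA chain recovers the intended class for every fixture", {
  kinds <- c("competition", "neutralism", "commensalism", "mutualism",
             "amensalism", "exploitation")
  for (seed in c(1, 2, 3)) {
    for (k in kinds) {
      p <- gen_toy_model_pairs(k, seed = seed)
      res <- classify_all_pairs(list(p$model1, p$model2), medium = p$medium)
      expect_identical(res$relationship, k)
    }
  }
})

test_that("community frequencies match a hand tally", {
  pair_labels <- data.frame(
    model1 = c("a", "a", "a", "b", "b", "c"),
    model2 = c("b", "c", "d", "c", "d", "d"),
    relationship = c("competition", "competition", "mutualism",
                     "competition", "neutralism", "competition"))
  ab <- rbind(s1 = c(a = 0.4, b = 0.3, c = 0.2, d = 0.1),
              s2 = c(a = 0.5, b = 0.5, c = 0,   d = 0),
              s3 = c(a = 1,   b = 0,   c = 0,   d = 0))
  prof <- community_frequencies(pair_labels, ab)
  # s1: all six pairs -> 4/6 competition, 1/6 mutualism, 1/6 neutralism
  expect_equal(prof$competition[1], 4 / 6, tolerance = 1e-12)
  expect_equal(prof$mutualism[1], 1 / 6, tolerance = 1e-12)
  expect_equal(prof$n_pairs[1], 6)
  # s2: only the a-b pair
  expect_equal(prof$competition[2], 1)
  expect_equal(prof$n_pairs[2], 1)
  # s3: a single member, empty profile
  expect_equal(prof$n_pairs[3], 0)
  expect_true(is.na(prof$competition[3]))
  # frequencies sum to 1 where defined
  fsum <- rowSums(prof[1:2, rejuvenome:::RELATIONSHIP_TYPES])
  expect_equal(unname(fsum), c(1, 1), tolerance = 1e-12)
})

test_that("group comparison of relationship frequencies is symmetric", {
  pair_labels <- data.frame(model1 = "a", model2 = "b",
                            relationship = "competition")
  ab <- matrix(0.5, 8, 2, dimnames = list(sprintf("s%d", 1:8), c("a", "b")))
  prof <- community_frequencies(pair_labels, ab)
  grp <- rep(c("yMB", "iMB"), each = 4)
  expect_warning(res <- compare_relationship_groups(prof, grp),
                 "identical")
  expect_equal(res$p, 1)
})

test_that("metabolic models round-trip through JSON", {
  p <- gen_toy_model_pairs("mutualism", seed = 6)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model_json(p$model1, path)
  back <- read_model_json(path)
  expect_equal(back$reactions, p$model1$reactions, tolerance = 1e-12)
  expect_identical(back$biomass, p$model1$biomass)
  expect_equal(fba(back, medium = c(EX_A_e = -5))$growth,
               fba(p$model1, medium = c(EX_A_e = -5))$growth,
               tolerance = 1e-9)
})
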