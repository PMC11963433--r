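# Seeded generators for every input the pipeline consumes, with ground-truth
# labels so recovery and calibration can be measured.  One global seed fans
# out to per-component child seeds through child_seed(), so adding draws to
# one generator never perturbs another.

#' Derive a per-component child seed from a global seed
#'
#' Deterministic splitting rule: `(seed * 48271 + offset) mod (2^31 - 1)`,
#' with a fixed offset per component stream.  All arithmetic stays below
#' 2^53, so the result is exact and always a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stream component name (`"ko"`, `"models"`, `"asv"`, `"cells"`,
#'   `"phenotype"`) or an arbitrary integer offset.
#' @return An integer child seed.
#' @export
child_seed <- function(seed, stream) {
  offsets <- c(ko = 101, models = 211, asv = 307, cells = 401,
               phenotype = 503)
  off <- if (is.character(stream)) {
    if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
    offsets[[stream]]
  } else as.numeric(stream)
  as.integer((abs(as.numeric(seed)) %% 44488 * 48271 + off) %% (2^31 - 1))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Configuration for the longitudinal KO-table generator
#'
#' @param n_mice_per_group mice per treatment arm.
#' @param timepoints strictly increasing ages (weeks); at least 2.
#' @param n_null,n_inverted,n_concordant_up,n_concordant_down feature counts
#'   per ground-truth class.
#' @param slope_magnitude planted age slope (transformed units / week).
#' @param mouse_sd SD of the per-mouse random intercept.
#' @param noise_sd residual SD on the transformed scale.
#' @param seed integer seed.
#' @return A validated `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_mice_per_group = 10,
                              timepoints = c(8, 40, 72, 120),
                              n_null = 200, n_inverted = 50,
                              n_concordant_up = 0, n_concordant_down = 0,
                              slope_magnitude = 0.005,
                              mouse_sd = 0.1, noise_sd = 0.1,
                              seed = 1L) {
  cfg <- list(n_mice_per_group = n_mice_per_group, timepoints = timepoints,
              n_null = n_null, n_inverted = n_inverted,
              n_concordant_up = n_concordant_up,
              n_concordant_down = n_concordant_down,
              slope_magnitude = slope_magnitude, mouse_sd = mouse_sd,
              noise_sd = noise_sd, seed = seed)
  for (f in c("n_null", "n_inverted", "n_concordant_up", "n_concordant_down"))
    if (cfg[[f]] < 0) stop("configuration error: ", f, " must be >= 0")
  if (cfg$n_mice_per_group < 1)
    stop("configuration error: n_mice_per_group must be >= 1")
  if (length(cfg$timepoints) < 2)
    stop("configuration error: timepoints needs at least 2 ages")
  if (is.unsorted(cfg$timepoints, strictly = TRUE))
    stop("configuration error: timepoints must be strictly increasing")
  if (cfg$mouse_sd < 0 || cfg$noise_sd < 0)
    stop("configuration error: mouse_sd and noise_sd must be >= 0")
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Simulate a longitudinal KO feature table with planted age dependencies
#'
#' Generates a samples x features table directly on the transformed scale,
#' under exactly the model the screen assumes: per feature, a fixed intercept
#' plus a per-treatment age slope, a per-mouse random intercept, and Gaussian
#' residual noise.  Planted classes: `inverted` features have age slopes of
#' opposite sign in the two arms (+/- `slope_magnitude`, direction
#' alternating across features); `concordant_up` / `concordant_down` have
#' same-sign slopes of unequal magnitude (1.5 and 0.5 x `slope_magnitude`),
#' so their interaction is real but direction-concordant; `null` features
#' share one common age slope (drawn N(0, `slope_magnitude`/2)) in both
#' arms, i.e. a main effect of age but no interaction.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with `table` (a transformed-scale [feature_table()]) and
#'   `truth` (data.frame: `feature_id`, `class`, `slope_yMB`, `slope_iMB`).
#' @export
gen_ko_table <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(child_seed(cfg$seed, "ko"))
  classes <- rep(c("null", "inverted", "concordant_up", "concordant_down"),
                 c(cfg$n_null, cfg$n_inverted, cfg$n_concordant_up,
                   cfg$n_concordant_down))
  n_feat <- length(classes)
  if (n_feat == 0) stop("configuration error: no features requested")
  feat_ids <- sprintf("K%05d", seq_len(n_feat))
  s <- cfg$slope_magnitude
  slope_iMB <- numeric(n_feat)
  slope_yMB <- numeric(n_feat)
  flip <- rep_len(c(1, -1), n_feat)  # alternate planted direction
  common <- stats::rnorm(n_feat, 0, s / 2)
  for (k in seq_len(n_feat)) {
    slopes <- switch(classes[k],
      null = c(common[k], common[k]),
      inverted = c(-s, s) * flip[k],
      concordant_up = c(1.5 * s, 0.5 * s),
      concordant_down = c(-1.5 * s, -0.5 * s))
    slope_iMB[k] <- slopes[1]; slope_yMB[k] <- slopes[2]
  }
  intercepts <- stats::runif(n_feat, 0.5, 1.5)

  mice <- c(sprintf("iMB_m%02d", seq_len(cfg$n_mice_per_group)),
            sprintf("yMB_m%02d", seq_len(cfg$n_mice_per_group)))
  treat <- rep(c("iMB", "yMB"), each = cfg$n_mice_per_group)
  meta <- expand.grid(mouse_id = mice, age_weeks = cfg$timepoints,
                      stringsAsFactors = FALSE)
  meta$treatment <- treat[match(meta$mouse_id, mice)]
  meta$sample_id <- sprintf("%s_w%03d", meta$mouse_id, meta$age_weeks)
  meta <- meta[, c("sample_id", "mouse_id", "age_weeks", "treatment")]

  # per mouse x feature random intercept, constant across timepoints
  b <- matrix(stats::rnorm(length(mice) * n_feat, 0, cfg$mouse_sd),
              length(mice), n_feat, dimnames = list(mice, feat_ids))
  slope_by_treat <- rbind(iMB = slope_iMB, yMB = slope_yMB)
  mu <- matrix(intercepts, nrow(meta), n_feat, byrow = TRUE) +
    outer(meta$age_weeks, rep(1, n_feat)) *
      slope_by_treat[meta$treatment, , drop = FALSE] +
    b[meta$mouse_id, , drop = FALSE]
  y <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                   nrow(mu), ncol(mu))
  dimnames(y) <- list(meta$sample_id, feat_ids)
  list(table = feature_table(y, meta, scale = "transformed"),
       truth = data.frame(feature_id = feat_ids, class = classes,
                          slope_yMB = slope_yMB, slope_iMB = slope_iMB))
}

# -- toy metabolic model pairs ----------------------------------------------

chain_model <- function(id, substrate, U, extra_mets = NULL,
                        extra_rx = NULL, biomass_stoich = NULL) {
  # single-substrate grower: EX_<S> uptake -> transport -> biomass
  se <- paste0(substrate, "_e"); sc <- paste0(substrate, "_c")
  mets <- data.frame(id = c(se, sc), compartment = c("extracellular", "cytosol"))
  rx <- list()
  rx[[paste0("EX_", se)]] <- list(stoich = stats::setNames(-1, se),
                                  lb = 0, ub = 1000)
  rx[[paste0("T_", substrate)]] <- list(
    stoich = stats::setNames(c(-1, 1), c(se, sc)), lb = 0, ub = 1000)
  if (is.null(biomass_stoich)) biomass_stoich <- stats::setNames(-1, sc)
  rx[["BIOMASS"]] <- list(stoich = biomass_stoich, lb = 0, ub = 1000)
  if (!is.null(extra_mets)) mets <- rbind(mets, extra_mets)
  if (!is.null(extra_rx)) rx <- c(rx, extra_rx)
  metabolic_model(id, mets, rx, "BIOMASS")
}

#' Hand-constructed model pairs with a known ecological relationship
#'
#' Builds a pair of toy metabolic models plus a shared medium whose
#' full-chain classification (mono-culture FBA, co-culture FBA, sign
#' classification) is the requested relationship by construction:
#' \describe{
#'   \item{competition}{two growers of the same limiting substrate}
#'   \item{neutralism}{growers of disjoint substrates}
#'   \item{commensalism}{a secretor plus an obligate consumer of its byproduct}
#'   \item{mutualism}{obligate cross-feeders (each needs the other's byproduct)}
#'   \item{amensalism}{a grower with a forced drain on the substrate its
#'     neighbor needs, itself growing on something else}
#'   \item{exploitation}{a consumer that needs its neighbor's byproduct and
#'     outcompetes the neighbor for the shared substrate}
#' }
#' The seed jitters the shared uptake limit (uniform in 8..12 mmol/gDW/h) so
#' classifications can be checked across many instantiations.
#'
#' @param kind one of the six relationship names.
#' @param seed integer seed.
#' @return list with `model1`, `model2`, `medium` (named lower bounds for
#'   shared exchanges) and `kind`.
#' @export
gen_toy_model_pairs <- function(kind = c("competition", "neutralism",
                                         "commensalism", "mutualism",
                                         "amensalism", "exploitation"),
                                seed = 1L) {
  kind <- match.arg(kind)
  set.seed(child_seed(seed, "models"))
  U <- round(stats::runif(1, 8, 12), 3)
  sn <- stats::setNames
  med <- function(...) unlist(list(...))
  out <- switch(kind,
    competition = {
      m1 <- chain_model("bug1", "A", U)
      m2 <- chain_model("bug2", "A", U)
      list(m1, m2, med(EX_A_e = -U))
    },
    neutralism = {
      m1 <- chain_model("bug1", "A", U)
      m2 <- chain_model("bug2", "B", U)
      list(m1, m2, med(EX_A_e = -U, EX_B_e = -U))
    },
    commensalism = {
      # bug1 grows on A and secretes D; bug2 grows only on D
      m1 <- chain_model("bug1", "A", U,
        extra_mets = data.frame(id = "D_e", compartment = "extracellular"),
        extra_rx = list(EX_D_e = list(stoich = sn(-1, "D_e"),
                                      lb = 0, ub = 1000)),
        biomass_stoich = sn(c(-1, 1), c("A_c", "D_e")))
      m2 <- chain_model("bug2", "D", U)
      list(m1, m2, med(EX_A_e = -U))
    },
    mutualism = {
      # bug1 needs A + C, secretes D; bug2 needs B + D, secretes C
      cross <- function(id, eats, needs, makes) {
        ne <- paste0(needs, "_e"); nc <- paste0(needs, "_c")
        me <- paste0(makes, "_e")
        chain_model(id, eats, U,
          extra_mets = data.frame(id = c(ne, nc, me),
                                  compartment = c("extracellular", "cytosol",
                                                  "extracellular")),
          extra_rx = stats::setNames(list(
            list(stoich = sn(-1, ne), lb = 0, ub = 1000),
            list(stoich = sn(c(-1, 1), c(ne, nc)), lb = 0, ub = 1000),
            list(stoich = sn(-1, me), lb = 0, ub = 1000)),
            c(paste0("EX_", ne), paste0("T_", needs), paste0("EX_", me))),
          biomass_stoich = sn(c(-1, -1, 1),
                              c(paste0(eats, "_c"), nc, me)))
      }
      m1 <- cross("bug1", "A", "C", "D")
      m2 <- cross("bug2", "B", "D", "C")
      list(m1, m2, med(EX_A_e = -U, EX_B_e = -U))
    },
    amensalism = {
      # bug1 grows on B but is forced to drain U units of A; bug2 needs A
      m1 <- chain_model("bug1", "B", U,
        extra_mets = data.frame(id = c("A_e", "A_c"),
                                compartment = c("extracellular", "cytosol")),
        extra_rx = list(
          EX_A_e = list(stoich = sn(-1, "A_e"), lb = 0, ub = 1000),
          T_A = list(stoich = sn(c(-1, 1), c("A_e", "A_c")), lb = 0, ub = 1000),
          DRAIN_A = list(stoich = sn(-1, "A_c"), lb = U, ub = U)))
      m2 <- chain_model("bug2", "A", U)
      list(m1, m2, med(EX_A_e = -U, EX_B_e = -U))
    },
    exploitation = {
      # bug2 grows on A secreting D; bug1 needs both A and D (0.5 each per
      # unit biomass) and wins the joint optimum, cutting bug2's share of A
      m1 <- chain_model("bug1", "A", U,
        extra_mets = data.frame(id = c("D_e", "D_c"),
                                compartment = c("extracellular", "cytosol")),
        extra_rx = list(
          EX_D_e = list(stoich = sn(-1, "D_e"), lb = 0, ub = 1000),
          T_D = list(stoich = sn(c(-1, 1), c("D_e", "D_c")), lb = 0, ub = 1000)),
        biomass_stoich = sn(c(-0.5, -0.5), c("A_c", "D_c")))
      m2 <- chain_model("bug2", "A", U,
        extra_mets = data.frame(id = "D_e", compartment = "extracellular"),
        extra_rx = list(EX_D_e = list(stoich = sn(-1, "D_e"),
                                      lb = 0, ub = 1000)),
        biomass_stoich = sn(c(-1, 1), c("A_c", "D_e")))
      list(m1, m2, med(EX_A_e = -U))
    })
  list(model1 = out[[1]], model2 = out[[2]], medium = out[[3]], kind = kind)
}

#' Simulate an ASV count table drifting away from a week-8 baseline
#'
#' Per mouse, a baseline composition and a drift target are drawn from a
#' Dirichlet around a shared community profile; at age `w` the expected
#' composition is the mixture `(1 - d) * baseline + d * target` with
#' `d = min(1, drift_per_week * (w - baseline_week))`.  Counts are
#' Dirichlet-multinomial (Dirichlet resampling of the expected composition,
#' then multinomial at a per-sample depth), which gives the overdispersion
#' that rarefaction has to absorb.
#'
#' @param n_mice_per_group mice per arm.
#' @param timepoints ages in weeks; the first is the baseline.
#' @param drift_per_week named numeric `c(yMB = ..., iMB = ...)`, mixture
#'   rate per week.
#' @param depth_range integer range for per-sample read depth.
#' @param n_asv number of ASVs.
#' @param concentration Dirichlet concentration for mouse-level compositions.
#' @param dm_concentration Dirichlet-multinomial concentration (lower = more
#'   overdispersed counts).
#' @param seed integer seed.
#' @return list with `counts` (integer samples x ASVs matrix) and `meta`.
#' @export
gen_asv_table <- function(n_mice_per_group = 10,
                          timepoints = c(8, 40, 72, 120),
                          drift_per_week = c(yMB = 0.004, iMB = 0.008),
                          depth_range = c(8000, 12000),
                          n_asv = 60, concentration = 50,
                          dm_concentration = 200, seed = 1L) {
  stopifnot(all(c("yMB", "iMB") %in% names(drift_per_week)),
            length(depth_range) == 2, depth_range[1] <= depth_range[2])
  set.seed(child_seed(seed, "asv"))
  w <- exp(stats::rnorm(n_asv, 0, 1.2))
  base <- w / sum(w)
  mice <- c(sprintf("iMB_m%02d", seq_len(n_mice_per_group)),
            sprintf("yMB_m%02d", seq_len(n_mice_per_group)))
  treat <- rep(c("iMB", "yMB"), each = n_mice_per_group)
  p0 <- lapply(seq_along(mice), function(i) rdirichlet1(concentration * base))
  qt <- lapply(seq_along(mice), function(i) rdirichlet1(concentration * base))
  baseline_week <- timepoints[1]
  meta <- expand.grid(mouse_id = mice, age_weeks = timepoints,
                      stringsAsFactors = FALSE)
  meta$treatment <- treat[match(meta$mouse_id, mice)]
  meta$sample_id <- sprintf("%s_w%03d", meta$mouse_id, meta$age_weeks)
  meta <- meta[order(meta$mouse_id, meta$age_weeks),
               c("sample_id", "mouse_id", "age_weeks", "treatment")]
  counts <- matrix(0L, nrow(meta), n_asv,
                   dimnames = list(meta$sample_id,
                                   sprintf("ASV%03d", seq_len(n_asv))))
  for (i in seq_len(nrow(meta))) {
    mi <- match(meta$mouse_id[i], mice)
    d <- min(1, drift_per_week[[meta$treatment[i]]] *
               (meta$age_weeks[i] - baseline_week))
    pw <- (1 - d) * p0[[mi]] + d * qt[[mi]]
    pi_s <- rdirichlet1(dm_concentration * pw)
    depth <- if (depth_range[1] == depth_range[2]) depth_range[1] else
      sample(depth_range[1]:depth_range[2], 1)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, pi_s))
  }
  list(counts = counts, meta = meta)
}

#' Default mesenchymal gene signature
#'
#' Mesenchymal hallmark transcripts used to score the propensity of
#' epithelial cells to express a mesenchymal program.
#' @return character vector of gene symbols.
#' @export
mesenchymal_signature <- function() {
  c("Vim", "Ctnnb1", "Fn1", "Aifm2", "Tgfb1", "Tgfbr1",
    "Smad2", "Smad3", "Smad4")
}

#' Default inflammaging gene signature
#'
#' Genes associated with inflammation during aging, used for the
#' inflammatory module score in immune cells.
#' @return character vector of gene symbols.
#' @export
inflammation_signature <- function() {
  c("Tnf", "Ifng", "Il1b", "Il2", "Il6", "Cxcl15", "Ccl20", "Ccl9",
    "Ccr1", "Nfkb1", "Myd88", "Tlr6")
}

default_housekeeping <- function() {
  c("Actb", "Gapdh", "B2m", "Rpl13a", "Rplp0", "Hprt", "Tbp", "Ppia",
    "Ywhaz", "Sdha")
}

#' Simulate a labelled single-cell count matrix with planted effects
#'
#' Counts are negative binomial with log-normal gene means and a fixed
#' per-gene dispersion; per-cell library size factors are log-normal.
#' Housekeeping genes get high means and mitochondrial (`mt-`) genes
#' moderate means so the QC fractions behave realistically.  Planted
#' effects: for cell types named in `score_shift`, the `signature` genes of
#' yMB cells are shifted multiplicatively by `exp(shift)`; the first
#' `n_de_genes` background genes are shifted by `exp(lfc)` in yMB cells of
#' `de_cell_type`.
#'
#' @param n_cells_per_type cells per cell type per mouse.
#' @param cell_types character vector of cell-type labels.
#' @param signature gene set whose expression `score_shift` perturbs.
#' @param score_shift named numeric, shift (natural-log scale) per targeted
#'   cell type; types not named get 0.
#' @param n_de_genes number of planted differential genes.
#' @param lfc planted log fold change (natural log) for the DE genes.
#' @param de_cell_type cell type carrying the planted DE genes.
#' @param extra_genes additional named genes to include unperturbed (e.g. a
#'   second signature that is scored but not shifted).
#' @param n_genes total genes including signature/housekeeping/mito.
#' @param n_mice_per_group mice per treatment arm.
#' @param dispersion NB size parameter range (fixed per gene).
#' @param seed integer seed.
#' @return A `cell_matrix`: list with sparse `counts` (genes x cells),
#'   `cell_meta` (`barcode`, `cell_type`, `mouse_id`, `treatment`),
#'   `gene_meta` (`gene_id`, `mito`, `housekeeping`), and `planted_de`
#'   (the planted DE gene ids).
#' @export
gen_cell_matrix <- function(n_cells_per_type = 50,
                            cell_types = c("enterocytes", "TA_cells",
                                           "macrophages"),
                            signature = mesenchymal_signature(),
                            score_shift = c(),
                            n_de_genes = 0, lfc = 0,
                            de_cell_type = cell_types[1],
                            extra_genes = character(0),
                            n_genes = 2000, n_mice_per_group = 3,
                            dispersion = c(1, 4), seed = 1L) {
  set.seed(child_seed(seed, "cells"))
  if (length(score_shift) && !all(names(score_shift) %in% cell_types))
    stop("score_shift names absent from cell_types: ",
         paste(setdiff(names(score_shift), cell_types), collapse = ", "))
  mito <- sprintf("mt-Gene%02d", 1:10)
  hk <- default_housekeeping()
  special <- c(signature, setdiff(extra_genes, signature), hk, mito)
  if (anyDuplicated(special)) stop("signature overlaps housekeeping/mito genes")
  n_bg <- n_genes - length(special)
  if (n_bg < n_de_genes)
    stop("n_genes too small for the requested planted DE genes")
  bg <- sprintf("Gene%04d", seq_len(n_bg))
  genes <- c(special, bg)
  mu <- exp(stats::rnorm(length(genes), 0, 1.0)) * 0.3
  names(mu) <- genes
  mu[hk] <- exp(stats::rnorm(length(hk), 3.1, 0.3))      # high expression
  mu[mito] <- exp(stats::rnorm(length(mito), 1.0, 0.3))  # moderate
  scored <- union(signature, extra_genes)
  mu[scored] <- pmax(mu[scored], 0.5)                    # scoreable baseline
  size <- stats::runif(length(genes), dispersion[1], dispersion[2])
  names(size) <- genes
  planted_de <- if (n_de_genes > 0) bg[seq_len(n_de_genes)] else character(0)

  mice <- c(sprintf("iMB_m%02d", seq_len(n_mice_per_group)),
            sprintf("yMB_m%02d", seq_len(n_mice_per_group)))
  treat <- rep(c("iMB", "yMB"), each = n_mice_per_group)
  cell_meta <- expand.grid(cell = seq_len(n_cells_per_type),
                           cell_type = cell_types, mouse_id = mice,
                           stringsAsFactors = FALSE)
  cell_meta$treatment <- treat[match(cell_meta$mouse_id, mice)]
  cell_meta$barcode <- sprintf("cell%05d", seq_len(nrow(cell_meta)))
  cell_meta <- cell_meta[, c("barcode", "cell_type", "mouse_id", "treatment")]
  n_cells <- nrow(cell_meta)
  libf <- exp(stats::rnorm(n_cells, 0, 0.2))

  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, cell_meta$barcode))
  for (j in seq_len(n_cells)) {
    mu_j <- mu * libf[j]
    if (cell_meta$treatment[j] == "yMB") {
      ct <- cell_meta$cell_type[j]
      if (ct %in% names(score_shift))
        mu_j[signature] <- mu_j[signature] * exp(score_shift[[ct]])
      if (length(planted_de) && ct == de_cell_type)
        mu_j[planted_de] <- mu_j[planted_de] * exp(lfc)
    }
    counts[, j] <- stats::rnbinom(length(genes), mu = mu_j, size = size)
  }
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_meta = cell_meta,
    gene_meta = data.frame(gene_id = genes, mito = genes %in% mito,
                           housekeeping = genes %in% hk),
    planted_de = planted_de), class = "cell_matrix")
}

#' Simulate host phenotype tables
#'
#' Weight trajectories (weeks 8..120, sampled every 8 weeks, saturating
#' growth plus mouse-level intercepts and noise), intraperitoneal glucose
#' tolerance test curves (minutes 0/15/30/60/90/120, a rise-and-clear shape),
#' and right-censored survival times (exponential, censored at week 120).
#'
#' @param n_per_group mice per arm.
#' @param auc_offset weight-units x weeks added to yMB AUC over weeks
#'   80-120 (spread uniformly over that window).
#' @param gtt_offset constant glucose offset (mmol/l) added to yMB curves.
#' @param survival_hazard_ratio hazard(iMB) / hazard(yMB); > 1 means iMB
#'   dies faster.
#' @param seed integer seed.
#' @return list of data.frames `weights`, `gtt` (both `subject_id`, `group`,
#'   `time`, `value`) and `survival` (`subject_id`, `group`, `time`,
#'   `event`).
#' @export
gen_phenotype <- function(n_per_group = 10, auc_offset = 0, gtt_offset = 0,
                          survival_hazard_ratio = 1, seed = 1L) {
  set.seed(child_seed(seed, "phenotype"))
  groups <- rep(c("iMB", "yMB"), each = n_per_group)
  ids <- sprintf("%s_m%02d", groups, c(seq_len(n_per_group),
                                       seq_len(n_per_group)))
  wk <- seq(8, 120, by = 8)
  weights <- do.call(rbind, lapply(seq_along(ids), function(i) {
    base <- 20 + 15 * wk / (wk + 30) + stats::rnorm(1, 0, 1.5)
    v <- base + stats::rnorm(length(wk), 0, 0.8)
    if (groups[i] == "yMB") v <- v + ifelse(wk >= 80, auc_offset / 40, 0)
    data.frame(subject_id = ids[i], group = groups[i], time = wk, value = v)
  }))
  mins <- c(0, 15, 30, 60, 90, 120)
  shape <- c(5, 14, 16, 12, 9, 7)
  gtt <- do.call(rbind, lapply(seq_along(ids), function(i) {
    v <- shape + stats::rnorm(1, 0, 1) + stats::rnorm(length(mins), 0, 0.8)
    if (groups[i] == "yMB") v <- v + gtt_offset
    data.frame(subject_id = ids[i], group = groups[i], time = mins, value = v)
  }))
  h0 <- log(2) / 100
  haz <- ifelse(groups == "yMB", h0 / survival_hazard_ratio, h0)
  t_ev <- stats::rexp(length(ids), rate = haz)
  surv <- data.frame(subject_id = ids, group = groups,
                     time = pmin(t_ev, 120),
                     event = as.integer(t_ev <= 120))
  list(weights = weights, gtt = gtt, survival = surv)
}
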