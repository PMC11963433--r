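#' Toy genome-scale metabolic model
#'
#' A minimal stoichiometric model for flux balance analysis: metabolites with
#' a compartment, reactions with a stoichiometry map and finite flux bounds,
#' and a biomass reaction whose flux is the growth rate.  Exchange reactions
#' carry one extracellular metabolite with coefficient -1, so positive flux is
#' secretion and negative flux (negative lower bound) is uptake.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id` and `compartment`
#'   (`"cytosol"` or `"extracellular"`).
#' @param reactions named list; each element has `stoich` (named numeric,
#'   metabolite id -> coefficient), `lb`, `ub`.
#' @param biomass id of the biomass reaction.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (!all(metabolites$compartment %in% c("cytosol", "extracellular")))
    stop("compartments must be 'cytosol' or 'extracellular'")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (is.null(names(reactions)) || anyDuplicated(names(reactions)))
    stop("reactions must be a uniquely named list")
  for (rid in names(reactions)) {
    r <- reactions[[rid]]
    if (!all(names(r$stoich) %in% metabolites$id))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(setdiff(names(r$stoich), metabolites$id), collapse = ", "))
    if (r$lb > r$ub) stop("reaction ", rid, " has lb > ub")
  }
  if (!biomass %in% names(reactions))
    stop("biomass reaction '", biomass, "' not found")
  if (reactions[[biomass]]$ub <= 0)
    stop("biomass reaction must have a positive upper bound")
  ex <- vapply(names(reactions), function(rid) {
    s <- reactions[[rid]]$stoich
    length(s) == 1 &&
      metabolites$compartment[match(names(s), metabolites$id)] == "extracellular"
  }, TRUE)
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 biomass = biomass, exchanges = names(reactions)[ex]),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions (%d exchange), biomass '%s'\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$exchanges), x$biomass))
  invisible(x)
}

stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  S <- matrix(0, length(mets), length(model$reactions),
              dimnames = list(mets, names(model$reactions)))
  for (rid in names(model$reactions)) {
    s <- model$reactions[[rid]]$stoich
    S[names(s), rid] <- s
  }
  S
}

apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  bad <- setdiff(names(medium), model$exchanges)
  if (length(bad))
    stop("medium references non-exchange reaction(s): ",
         paste(bad, collapse = ", "))
  for (rid in names(medium))
    model$reactions[[rid]]$lb <- medium[[rid]]
  model
}

#' Flux balance analysis
#'
#' Maximizes biomass flux subject to steady state (`S v = 0`) and the flux
#' bounds, by linear programming.  An infeasible model gets growth 0 with an
#' `infeasible` flag rather than an error, because in co-culture work an
#' organism that cannot grow on a medium is a result, not a defect.
#'
#' @param model a [metabolic_model()].
#' @param medium optional named numeric of lower-bound overrides for exchange
#'   reactions (negative = uptake allowed).
#' @param objective reaction id to maximize; defaults to the biomass reaction.
#' @param extra_eq optional list(`coef` = named numeric over reactions,
#'   `rhs`) appended as an equality row (used by flux variability analysis).
#' @param minimize maximize `-objective` instead.
#' @return list with `growth` (objective optimum), `fluxes` (named vector),
#'   `status`.
#' @export
fba <- function(model, medium = NULL, objective = model$biomass,
                extra_eq = NULL, minimize = FALSE) {
  model <- apply_medium(model, medium)
  S <- stoich_matrix(model)
  rids <- colnames(S)
  lb <- vapply(model$reactions, `[[`, 0, "lb")[rids]
  ub <- vapply(model$reactions, `[[`, 0, "ub")[rids]
  obj <- numeric(length(rids)); names(obj) <- rids
  obj[objective] <- if (minimize) -1 else 1
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    row <- numeric(length(rids)); names(row) <- rids
    row[names(extra_eq$coef)] <- extra_eq$coef
    A <- rbind(A, row)
    b <- c(b, extra_eq$rhs)
  }
  sol <- solve_lp(obj, A, b, lb, ub)
  if (sol$status == "unbounded")
    stop("unbounded objective: model '", model$id, "' is defective")
  if (sol$status == "infeasible")
    return(list(growth = 0, fluxes = stats::setNames(rep(NA_real_, length(rids)), rids),
                status = "infeasible"))
  fl <- stats::setNames(sol$x, rids)
  g <- if (minimize) -sol$objective else sol$objective
  list(growth = unname(fl[objective]), objective_value = g, fluxes = fl,
       status = "optimal")
}

#' Merge two models into a co-culture community model
#'
#' Cytosolic metabolites and all reactions are namespaced by model id; the
#' extracellular compartment is shared.  Each member's own exchange reactions
#' are replaced by a single community exchange per extracellular metabolite,
#' so medium bounds are applied once and resources are contested.  Each
#' member keeps its own biomass reaction.
#'
#' @param model1,model2 [metabolic_model()] objects with distinct ids.
#' @param medium named numeric of lower bounds for the shared community
#'   exchange reactions (named `EX_<metabolite>`); exchanges not listed allow
#'   secretion only.
#' @return A `community_model`: a `metabolic_model` plus `members` and
#'   `member_biomass`.
#' @export
build_pair <- function(model1, model2, medium = NULL) {
  if (model1$id == model2$id) stop("member models must have distinct ids")
  ns <- function(model) {
    pre <- paste0(model$id, ".")
    ext <- model$metabolites$id[model$metabolites$compartment == "extracellular"]
    remap <- function(x) ifelse(x %in% ext, x, paste0(pre, x))
    mets <- model$metabolites
    mets$id <- remap(mets$id)
    rx <- list()
    for (rid in setdiff(names(model$reactions), model$exchanges)) {
      r <- model$reactions[[rid]]
      names(r$stoich) <- remap(names(r$stoich))
      rx[[paste0(pre, rid)]] <- r
    }
    list(metabolites = mets, reactions = rx, ext = ext,
         biomass = paste0(pre, model$biomass))
  }
  n1 <- ns(model1); n2 <- ns(model2)
  cyto1 <- n1$metabolites[n1$metabolites$compartment == "cytosol", ]
  cyto2 <- n2$metabolites[n2$metabolites$compartment == "cytosol", ]
  if (length(intersect(cyto1$id, cyto2$id)))
    stop("metabolite id collision after namespacing")
  ext_ids <- union(n1$ext, n2$ext)
  mets <- rbind(cyto1, cyto2,
                data.frame(id = ext_ids, compartment = "extracellular"))
  reactions <- c(n1$reactions, n2$reactions)
  for (m in ext_ids) {
    ex_id <- paste0("EX_", m)
    lbm <- if (!is.null(medium) && ex_id %in% names(medium)) medium[[ex_id]] else 0
    reactions[[ex_id]] <- list(stoich = stats::setNames(-1, m),
                               lb = lbm, ub = 1000)
  }
  cm <- metabolic_model(paste0(model1$id, "+", model2$id), mets, reactions,
                        biomass = n1$biomass)
  cm$members <- c(model1$id, model2$id)
  cm$member_biomass <- c(n1$biomass, n2$biomass)
  class(cm) <- c("community_model", class(cm))
  cm
}

#' Co-culture growth of a model pair
#'
#' The allocation of a shared optimum between the two members is not unique
#' in general, so a protocol must be chosen.  The default maximizes the joint
#' biomass `g1 + g2`, then runs flux variability analysis on each member's
#' biomass at that optimum and reports the midpoint of its feasible range —
#' a deterministic, symmetric resolution of degenerate optima.  Alternatives:
#' `"lexicographic"` (maximize member 1, then member 2 given member 1) and
#' `"equal_split"` (each member grown alone on the medium with uptake bounds
#' halved).
#'
#' @param community a community model from [build_pair()].
#' @param protocol `"joint_fva"`, `"lexicographic"` or `"equal_split"`.
#' @return list with `g_pair` (named growth per member), `g_total`,
#'   `status`, and for `"joint_fva"` the per-member FVA ranges.
#' @export
pair_growth <- function(community,
                        protocol = c("joint_fva", "lexicographic", "equal_split")) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(community, "community_model"))
  bio <- community$member_biomass
  if (protocol == "equal_split") {
    half <- community
    for (rid in half$exchanges)
      half$reactions[[rid]]$lb <- half$reactions[[rid]]$lb / 2
    g <- vapply(bio, function(bb) fba(half, objective = bb)$growth, 0)
    names(g) <- community$members
    return(list(g_pair = g, g_total = sum(g), status = "optimal"))
  }
  joint <- stats::setNames(c(1, 1), bio)
  # maximize g1 + g2 through a synthetic joint objective
  tot <- fba_joint(community, joint)
  if (tot$status == "infeasible") {
    g <- stats::setNames(c(0, 0), community$members)
    return(list(g_pair = g, g_total = 0, status = "infeasible"))
  }
  g_total <- tot$objective_value
  if (protocol == "lexicographic") {
    g1 <- fba(community, objective = bio[1])$growth
    g2 <- fba(community, objective = bio[2],
              extra_eq = list(coef = stats::setNames(1, bio[1]), rhs = g1))$growth
    g <- stats::setNames(c(g1, g2), community$members)
    return(list(g_pair = g, g_total = g1 + g2, status = "optimal"))
  }
  fix <- list(coef = joint, rhs = g_total)
  rng <- lapply(bio, function(bb) {
    lo <- fba(community, objective = bb, extra_eq = fix, minimize = TRUE)
    hi <- fba(community, objective = bb, extra_eq = fix)
    c(min = lo$objective_value, max = hi$growth)
  })
  names(rng) <- community$members
  g <- vapply(rng, function(r) mean(r), 0)
  list(g_pair = g, g_total = g_total, status = "optimal", fva = rng)
}

# FBA with a composite objective over several reactions
fba_joint <- function(model, coef) {
  S <- stoich_matrix(model)
  rids <- colnames(S)
  lb <- vapply(model$reactions, `[[`, 0, "lb")[rids]
  ub <- vapply(model$reactions, `[[`, 0, "ub")[rids]
  obj <- numeric(length(rids)); names(obj) <- rids
  obj[names(coef)] <- coef
  sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub)
  if (sol$status == "unbounded")
    stop("unbounded joint objective: model '", model$id, "' is defective")
  if (sol$status == "infeasible")
    return(list(status = "infeasible", objective_value = 0))
  list(status = "optimal", objective_value = sol$objective,
       fluxes = stats::setNames(sol$x, rids))
}

#' Classify a pairwise ecological relationship from growth effects
#'
#' The effect of co-culture on each member is `g_pair - g_alone`; its sign is
#' 0 when the change is inside a neutral band (`max(tol_abs,
#' tol_rel * g_alone)`), otherwise its strict sign.  The unordered sign pair
#' maps to the six classical relationship types: (+,+) mutualism, (+,0)
#' commensalism, (+,-) exploitation, (0,0) neutralism, (0,-) amensalism,
#' (-,-) competition.
#'
#' @param g_alone1,g_alone2 mono-culture growth rates (>= 0).
#' @param g_pair1,g_pair2 co-culture growth rates (>= 0).
#' @param tol_rel,tol_abs neutral-band tolerances separating LP noise from
#'   real effects.
#' @return Relationship name (character scalar).
#' @export
classify_pair <- function(g_alone1, g_alone2, g_pair1, g_pair2,
                          tol_rel = 1e-6, tol_abs = 1e-9) {
  if (any(c(g_alone1, g_alone2, g_pair1, g_pair2) < 0))
    stop("growth rates must be non-negative")
  eff_sign <- function(alone, pair) {
    d <- pair - alone
    if (abs(d) <= max(tol_abs, tol_rel * alone)) 0L else as.integer(sign(d))
  }
  s <- sort(c(eff_sign(g_alone1, g_pair1), eff_sign(g_alone2, g_pair2)),
            decreasing = TRUE)
  key <- paste(s, collapse = ",")
  switch(key,
         "1,1"   = "mutualism",
         "1,0"   = "commensalism",
         "1,-1"  = "exploitation",
         "0,0"   = "neutralism",
         "0,-1"  = "amensalism",
         "-1,-1" = "competition",
         stop("unreachable sign pattern: ", key))
}

#' Classify all relationships of a model collection
#'
#' Runs the full chain (mono-culture FBA, pair building, co-growth, sign
#' classification) for every unordered model pair on a shared medium.
#'
#' @param models list of [metabolic_model()] objects.
#' @param medium shared medium (named lower bounds, `EX_<metabolite>`).
#' @param protocol passed to [pair_growth()].
#' @param tol_rel,tol_abs passed to [classify_pair()].
#' @return data.frame with one row per pair: ids, mono- and co-culture
#'   growths, relationship.
#' @export
classify_all_pairs <- function(models, medium = NULL, protocol = "joint_fva",
                               tol_rel = 1e-6, tol_abs = 1e-9) {
  ids <- vapply(models, `[[`, "", "id")
  names(models) <- ids
  g_alone <- vapply(models, function(m) {
    med <- medium[names(medium) %in% m$exchanges]
    if (!length(med)) med <- NULL
    fba(m, medium = med)$growth
  }, 0)
  pairs <- utils::combn(ids, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    comm <- build_pair(models[[i]], models[[j]], medium = medium)
    pg <- pair_growth(comm, protocol = protocol)
    rel <- classify_pair(g_alone[[i]], g_alone[[j]],
                         pg$g_pair[[i]], pg$g_pair[[j]],
                         tol_rel = tol_rel, tol_abs = tol_abs)
    out[[k]] <- data.frame(model1 = i, model2 = j,
                           g_alone1 = g_alone[[i]], g_alone2 = g_alone[[j]],
                           g_pair1 = pg$g_pair[[i]], g_pair2 = pg$g_pair[[j]],
                           relationship = rel)
  }
  do.call(rbind, out)
}

RELATIONSHIP_TYPES <- c("mutualism", "commensalism", "exploitation",
                        "neutralism", "amensalism", "competition")

#' Per-sample frequencies of ecological relationship types
#'
#' For each sample, the members detected above a relative-abundance threshold
#' are paired, each pair is looked up in the pair classification, and the
#' relationship types are tallied as counts and frequencies.
#'
#' @param pair_labels data.frame with `model1`, `model2`, `relationship`
#'   (e.g. from [classify_all_pairs()]).
#' @param abundance samples x models relative-abundance matrix (columns must
#'   be model ids).
#' @param detection_threshold members with relative abundance strictly above
#'   this are considered present.
#' @param weighted if `TRUE`, each pair is weighted by the product of the two
#'   members' relative abundances instead of counting 1.
#' @return data.frame, one row per sample, with `n_pairs` and one frequency
#'   column per relationship type; samples with < 2 detected members get
#'   `n_pairs = 0` and `NA` frequencies.
#' @export
community_frequencies <- function(pair_labels, abundance,
                                  detection_threshold = 0, weighted = FALSE) {
  ids <- colnames(abundance)
  lut <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(pair_labels))) {
    key <- paste(sort(c(pair_labels$model1[k], pair_labels$model2[k])),
                 collapse = "|")
    assign(key, pair_labels$relationship[k], envir = lut)
  }
  res <- matrix(NA_real_, nrow(abundance), length(RELATIONSHIP_TYPES),
                dimnames = list(rownames(abundance), RELATIONSHIP_TYPES))
  n_pairs <- integer(nrow(abundance))
  for (s in seq_len(nrow(abundance))) {
    present <- ids[abundance[s, ] > detection_threshold]
    if (length(present) < 2) next
    pr <- utils::combn(present, 2)
    w <- numeric(length(RELATIONSHIP_TYPES))
    names(w) <- RELATIONSHIP_TYPES
    for (k in seq_len(ncol(pr))) {
      key <- paste(sort(pr[, k]), collapse = "|")
      if (!exists(key, envir = lut))
        stop("no relationship label for pair ", key)
      wt <- if (weighted) abundance[s, pr[1, k]] * abundance[s, pr[2, k]] else 1
      rel <- get(key, envir = lut)
      w[rel] <- w[rel] + wt
    }
    n_pairs[s] <- ncol(pr)
    res[s, ] <- w / sum(w)
  }
  data.frame(sample_id = rownames(abundance), n_pairs = n_pairs, res,
             row.names = NULL)
}

#' Compare a relationship type's frequency between groups
#'
#' Mann-Whitney test on the per-sample frequency of one relationship type (or
#' of a pooled set, e.g. the antagonistic types competition, amensalism and
#' exploitation — any pattern with a negative effect on a member).
#'
#' @param profiles output of [community_frequencies()].
#' @param groups group label per profile row (two levels).
#' @param relationship character vector of relationship types to pool.
#' @return list with `U`, `p` and the per-group mean frequency.
#' @export
compare_relationship_groups <- function(profiles, groups,
                                        relationship = c("competition",
                                                         "amensalism",
                                                         "exploitation")) {
  stopifnot(all(relationship %in% RELATIONSHIP_TYPES))
  freq <- rowSums(profiles[, relationship, drop = FALSE])
  ok <- !is.na(freq)
  freq <- freq[ok]; groups <- groups[ok]
  gs <- unique(groups)
  if (length(gs) != 2 || min(table(groups)) < 2)
    stop("need two groups with >= 2 samples each")
  mw <- mann_whitney(freq[groups == gs[1]], freq[groups == gs[2]],
                     mode = "asymptotic")
  list(U = mw$U, p = mw$p,
       group_means = tapply(freq, groups, mean))
}

#' Write / read a metabolic model as JSON
#'
#' Plain-text schema: `id`, `metabolites` (id, compartment), `reactions`
#' (id, stoich map, lb, ub), `biomass`.
#'
#' @param model a [metabolic_model()].
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  rx <- lapply(names(model$reactions), function(rid) {
    r <- model$reactions[[rid]]
    list(id = rid, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub)
  })
  jsonlite::write_json(
    list(id = model$id,
         metabolites = model$metabolites,
         reactions = rx,
         biomass = model$biomass),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment)))
  rx <- list()
  for (r in j$reactions)
    rx[[r$id]] <- list(stoich = unlist(r$stoich), lb = r$lb, ub = r$ub)
  metabolic_model(j$id, mets, rx, j$biomass)
}
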