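#' Derive the analysis layers of a landscape bundle
#'
#' One-time preparation of everything the problem catalog consumes:
#' degraded/intact classification, the cover-based omnidirectional
#' connectivity surface, contemporary and historic lek-connectivity
#' surfaces (lek buffers zeroed) and their loss layer, per-species
#' ecological-potential layers (zonal imputation over management clusters),
#' and the conservation-area cell mask.
#'
#' @param bundle A `landscape_bundle` from [synth_landscape()].
#' @param connectivity A [window_config()] for the connectivity solves. The
#'   default scales the moving window to the desk-scale landscape (900 m on
#'   a 3 km grid) with stride 5.
#' @param lek_buffer_radius Lek protection buffer radius in metres.
#' @return The bundle with a `derived` element added.
#' @export
prepare_bundle <- function(bundle,
                           connectivity = window_config(radius = 900,
                                                        source_threshold = 15,
                                                        stride = 5L),
                           lek_buffer_radius = 1000) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  degraded <- classify_degraded(bundle$historic_cover, bundle$potential_cover,
                                bundle$current_cover)
  intact <- classify_intact(bundle$current_cover, degraded, threshold = 15)

  sage_cm <- omnidirectional_current(bundle$current_cover, connectivity)
  lek_cfg <- connectivity; lek_cfg$source_mode <- "point_based"
  lek_now <- mask_lek_buffers(
    lek_connectivity(bundle$current_cover, bundle$leks, lek_cfg),
    bundle$leks, lek_buffer_radius)
  lek_then <- mask_lek_buffers(
    lek_connectivity(bundle$historic_cover, bundle$leks, lek_cfg),
    bundle$leks, lek_buffer_radius)
  lek_loss <- connectivity_change(lek_now, lek_then)

  pot_names <- setdiff(names(bundle$features), "grouse_abundance")
  potentials <- lapply(bundle$features[pot_names], ecological_potential,
                       intact = intact, clusters = bundle$cluster_zones,
                       degraded = degraded)

  scd_mask <- matrix(FALSE, nrow(degraded), ncol(degraded))
  for (p in bundle$conservation_areas$polygons)
    scd_mask <- scd_mask | cells_in_polygon(p, bundle$current_cover)

  bundle$derived <- list(degraded = degraded, intact = intact,
                         sage_connectivity = sage_cm$values,
                         lek_connectivity = lek_now$values,
                         lek_loss = lek_loss,
                         potentials = potentials,
                         scd_mask = scd_mask,
                         connectivity_config = connectivity,
                         lek_buffer_radius = lek_buffer_radius)
  bundle
}

#' The default problem catalog
#'
#' Frozen configurations for the nine standard problem structures:
#' protection problems over intact habitat with varying cost layers
#' (uniform; transposed sagebrush connectivity; transposed future cover;
#' untransposed soil moisture with optional future-cover masks), the
#' restoration problems over degraded habitat (transposed soil moisture
#' cost, ecological-potential features, intact locked in; plus the
#' uncertainty variant), and the conservation-design set restricted to
#' designated core/growth areas (transposed lek connectivity; resilience
#' and connectivity-loss restoration chained onto the protection
#' solution). Boundary penalties carry the standard defaults: a nominal
#' 1e-5 anti-fragmentation penalty where the problem is otherwise
#' unconstrained, 0.1 for the all-species restoration problem, 2.5 and 1.5
#' for the chained restoration problems; relative targets are 0.2
#' throughout with an edge factor of 0.5 and a gap allowance of 0.01.
#'
#' @return Named list of catalog entries.
#' @export
problem_catalog <- function() {
  entry <- function(id, pu_source, cost_recipe, feature_recipe,
                    locked_recipe = "none", boundary_penalty = 0,
                    conservation_mask = FALSE, future_threshold = NULL,
                    uncertainty = FALSE) {
    list(id = id, pu_source = pu_source, cost_recipe = cost_recipe,
         feature_recipe = feature_recipe, locked_recipe = locked_recipe,
         boundary_penalty = boundary_penalty,
         conservation_mask = conservation_mask,
         future_threshold = future_threshold,
         uncertainty = uncertainty, target = 0.2, edge_factor = 0.5,
         gap = 0.01)
  }
  list(
    `1a` = entry("1a", "intact", "uniform", "direct",
                 boundary_penalty = 1e-5),
    `1b` = entry("1b", "intact", "transposed_connectivity", "direct"),
    `1c` = entry("1c", "intact", "transposed_future_cover", "direct"),
    `1d` = entry("1d", "intact", "soil_moisture", "direct",
                 boundary_penalty = 1e-5, future_threshold = NULL),
    `2a` = entry("2a", "merged", "transposed_soil_moisture",
                 "ecological_potential", locked_recipe = "intact",
                 boundary_penalty = 0.1),
    `2b` = entry("2b", "degraded", "transposed_soil_moisture",
                 "ecological_potential", uncertainty = TRUE),
    `3a` = entry("3a", "intact", "transposed_lek_connectivity", "direct",
                 conservation_mask = TRUE),
    `3b` = entry("3b", "degraded", "transposed_soil_moisture",
                 "ecological_potential", locked_recipe = "prior_solution",
                 boundary_penalty = 2.5, conservation_mask = TRUE),
    `3c` = entry("3c", "degraded", "shifted_connectivity_loss",
                 "ecological_potential", locked_recipe = "prior_solution",
                 boundary_penalty = 1.5, conservation_mask = TRUE)
  )
}

# feature sets by problem family
protection_feature_names <- function(bundle)
  setdiff(names(bundle$features), "grouse_abundance")

restoration_feature_names <- function(bundle)
  c(setdiff(names(bundle$features), c("grouse_abundance", "grouse_persistence_prob")),
    "grouse_abundance")

# per-unit feature matrix for an entry; features are rescaled to [0, 1]
# study-wide before extraction
entry_features <- function(entry, bundle, units) {
  nms <- if (entry$feature_recipe == "direct") protection_feature_names(bundle)
  else restoration_feature_names(bundle)
  out <- lapply(nms, function(nm) {
    g <- if (entry$feature_recipe == "direct") bundle$features[[nm]]
    else if (nm == "grouse_abundance") bundle$features[[nm]]
    else bundle$derived$potentials[[nm]]
    unit_values(units, rescale01(g))
  })
  names(out) <- nms
  out
}

entry_cost <- function(entry, bundle, units) {
  d <- bundle$derived
  switch(entry$cost_recipe,
         uniform = rep(1, units$n),
         soil_moisture = unit_values(units, bundle$soil_moisture),
         transposed_soil_moisture =
           transpose_max(unit_values(units, bundle$soil_moisture)),
         transposed_connectivity =
           transpose_max(unit_values(units, d$sage_connectivity)),
         transposed_future_cover =
           transpose_max(unit_values(units, bundle$future_cover)),
         transposed_lek_connectivity =
           transpose_max(unit_values(units, d$lek_connectivity)),
         shifted_connectivity_loss =
           shift_positive(unit_values(units, d$lek_loss)),
         stop("unknown cost recipe: ", entry$cost_recipe, call. = FALSE))
}

entry_units <- function(entry, bundle, prior_cells = NULL) {
  d <- bundle$derived
  base <- switch(entry$pu_source,
                 intact = d$intact,
                 degraded = d$degraded,
                 merged = d$intact | d$degraded,
                 stop("unknown planning-unit source: ", entry$pu_source,
                      call. = FALSE))
  if (isTRUE(entry$conservation_mask)) base <- base & d$scd_mask
  if (!is.null(prior_cells)) base <- base | prior_cells
  cs <- bundle$current_cover$cell_size
  units <- units_from_mask(base, cs, bundle$current_cover$origin)
  mask_by_future_cover(units, bundle$future_cover, entry$future_threshold)
}

entry_locked <- function(entry, bundle, units, prior_cells = NULL) {
  d <- bundle$derived
  cells <- switch(entry$locked_recipe,
                  none = return(integer(0)),
                  intact = which(d$intact),
                  prior_solution = {
                    if (is.null(prior_cells))
                      stop("entry ", entry$id,
                           " locks in a prior solution; supply `prior_cells`",
                           call. = FALSE)
                    which(prior_cells)
                  },
                  stop("unknown locked-in recipe: ", entry$locked_recipe,
                       call. = FALSE))
  which(units$cell_index %in% cells)
}

#' Run one catalog problem
#'
#' Assembles the [problem_spec()] a catalog entry describes against a
#' prepared bundle (planning-unit pool, masks, cost and feature recipes,
#' locked-in set, boundary penalty), solves it, and returns the solution
#' with its summary. Single-species iterations set that species' relative
#' target to 0.2 and all other targets to 0. An empty planning-unit pool
#' (e.g. after an aggressive future-cover mask) is reported as an
#' infeasible run naming the mask, not an error.
#'
#' @param entry A catalog entry from [problem_catalog()] (or its id).
#' @param bundle A prepared `landscape_bundle` (see [prepare_bundle()];
#'   preparation is run on the fly if missing).
#' @param species `"all"` or the name of a single focal feature.
#' @param prior_cells Logical cell matrix locked in when the entry's
#'   locked-in recipe is `"prior_solution"`.
#' @param backend Solver backend.
#' @param ... Passed on to [solve_minset()] (e.g. `time_limit`).
#' @return A `catalog_run`: entry, units, solution, summary.
#' @export
run_catalog_problem <- function(entry, bundle, species = "all",
                                prior_cells = NULL, backend = "milp", ...) {
  if (is.character(entry)) entry <- problem_catalog()[[entry]]
  if (is.null(entry)) stop("unknown catalog entry", call. = FALSE)
  if (is.null(bundle$derived)) bundle <- prepare_bundle(bundle)
  units <- entry_units(entry, bundle, prior_cells)
  if (units$n == 0L) {
    res <- list(entry = entry, units = units, solution = NULL,
                status = "infeasible",
                reason = paste0("no available sites after masking (",
                                if (!is.null(entry$future_threshold))
                                  paste0("future cover >= ",
                                         entry$future_threshold, "%")
                                else "planning-unit masks", ")"),
                summary = NULL)
    class(res) <- "catalog_run"
    return(res)
  }
  feats <- entry_features(entry, bundle, units)
  targets <- rep(entry$target, length(feats))
  names(targets) <- names(feats)
  if (!identical(species, "all")) {
    if (!species %in% names(feats))
      stop("unknown focal species: ", species, call. = FALSE)
    targets[] <- 0
    targets[species] <- entry$target
  }
  spec <- problem_spec(units, entry_cost(entry, bundle, units), feats,
                       targets = targets,
                       boundary_penalty = entry$boundary_penalty,
                       edge_factor = entry$edge_factor,
                       locked_in = entry_locked(entry, bundle, units, prior_cells),
                       gap = entry$gap)
  sol <- solve_minset(spec, backend, ...)
  layers <- c(list(cost = spec$cost), feats)
  res <- list(entry = entry, units = units, solution = sol,
              status = sol$status,
              summary = if (sol$status != "infeasible")
                summarize_solution(sol, layers, units$cell_size) else NULL)
  class(res) <- "catalog_run"
  res
}

#' @export
print.catalog_run <- function(x, ...) {
  cat(sprintf("<catalog_run> problem %s: %s\n", x$entry$id, x$status))
  if (!is.null(x$solution) && x$status != "infeasible") {
    cat(sprintf("  %d / %d unit(s) selected (%.4g ha)\n",
                sum(x$solution$selected), x$units$n, x$summary$area_ha))
  } else if (!is.null(x$reason)) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Solution as a binary raster
#'
#' @param units The `planning_units` of the solved problem.
#' @param selected Logical selection vector (or a `minset_solution`).
#' @return A [raster_grid()]: 1 selected, 0 available-unselected, nodata
#'   outside the planning-unit pool.
#' @export
solution_raster <- function(units, selected) {
  if (inherits(selected, "minset_solution")) selected <- selected$selected
  m <- matrix(NA_real_, units$shape[1], units$shape[2])
  m[units$cell_index] <- 0
  m[units$cell_index[selected]] <- 1
  raster_grid(m, units$cell_size, units$origin, semantic_tag = "solution (binary)")
}

#' Summary statistics of a solution
#'
#' Median, first and third quartiles, minimum, and maximum of each supplied
#' layer over the selected units; selected area in hectares; capture
#' proportions for all features. An empty selection returns the `NA`
#' sentinel statistics.
#'
#' @param solution A `minset_solution` (or logical selection vector).
#' @param layers Named list of per-unit value vectors.
#' @param cell_size Cell side in metres.
#' @return List: `n_selected`, `area_ha`, `stats` (one row per layer),
#'   `capture` (from [capture_report()], when the solution carries its
#'   spec).
#' @export
summarize_solution <- function(solution, layers, cell_size = 30) {
  selected <- if (inherits(solution, "minset_solution")) solution$selected else solution
  n_sel <- sum(selected)
  stats_df <- do.call(rbind, lapply(names(layers), function(nm) {
    v <- layers[[nm]][selected]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      data.frame(layer = nm, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                 min = NA_real_, max = NA_real_)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(layer = nm, median = q[2], q1 = q[1], q3 = q[3],
                 min = min(v), max = max(v))
    }
  }))
  list(n_selected = n_sel, area_ha = n_sel * cell_size^2 / 1e4,
       stats = stats_df,
       capture = if (inherits(solution, "minset_solution"))
         solution$captured else NULL)
}

#' Percent overlap of a solution with a polygon set
#'
#' @param solution A `minset_solution` or logical selection vector.
#' @param units The `planning_units` of the problem.
#' @param polygons A [polygon_layer()].
#' @param template An aligned [raster_grid()] supplying cell geometry.
#' @return Percent (0-100) of selected cells whose centers fall inside the
#'   polygon set.
#' @export
overlap_report <- function(solution, units, polygons, template) {
  selected <- if (inherits(solution, "minset_solution")) solution$selected else solution
  if (sum(selected) == 0L) return(NA_real_)
  inside <- matrix(FALSE, units$shape[1], units$shape[2])
  for (p in polygons$polygons) inside <- inside | cells_in_polygon(p, template)
  100 * mean(inside[units$cell_index[selected]])
}

#' Umbrella-species cross-capture matrix
#'
#' Runs the baseline protection problem once per focal species (that
#' species' target 0.2, all others 0) plus the all-species iteration, and
#' reports the proportion of every species' total captured by every run:
#' rows are solutions, columns species. Diagonal entries of feasible
#' single-species runs are at least the target by construction; the
#' off-diagonal entries measure how well each species umbrellas the others.
#'
#' @param bundle A prepared `landscape_bundle`.
#' @param species Character vector of feature names (default: all
#'   protection features).
#' @param entry Catalog entry to iterate (default `"1a"`).
#' @param backend Solver backend.
#' @return Numeric matrix of capture proportions, rows named by run.
#' @export
umbrella_matrix <- function(bundle, species = NULL, entry = "1a",
                            backend = "milp", ...) {
  if (is.null(bundle$derived)) bundle <- prepare_bundle(bundle)
  if (is.null(species)) species <- protection_feature_names(bundle)
  runs <- c(as.list(species), list("all"))
  names(runs) <- c(species, "all_species")
  out <- matrix(NA_real_, length(runs), length(species),
                dimnames = list(names(runs), species))
  for (i in seq_along(runs)) {
    r <- run_catalog_problem(entry, bundle, species = runs[[i]],
                             backend = backend, ...)
    if (r$status == "infeasible") next
    cap <- r$solution$captured
    out[i, ] <- cap$proportion[match(species, cap$feature)]
  }
  out
}

#' Chained conservation-design problems
#'
#' Runs the conservation-design protection problem, then injects its
#' selected sites as locked-in units for the resilience-focused and
#' connectivity-loss restoration problems, so restoration clusters around
#' the protected core.
#'
#' @param bundle A prepared `landscape_bundle`.
#' @param backend Solver backend.
#' @return List of three `catalog_run`s named `3a`, `3b`, `3c`.
#' @export
scd_chain <- function(bundle, backend = "milp", ...) {
  if (is.null(bundle$derived)) bundle <- prepare_bundle(bundle)
  r3a <- run_catalog_problem("3a", bundle, backend = backend, ...)
  if (r3a$status == "infeasible")
    stop("protection problem 3a infeasible; cannot chain", call. = FALSE)
  prior <- matrix(FALSE, r3a$units$shape[1], r3a$units$shape[2])
  prior[r3a$units$cell_index[r3a$solution$selected]] <- TRUE
  r3b <- run_catalog_problem("3b", bundle, prior_cells = prior,
                             backend = backend, ...)
  r3c <- run_catalog_problem("3c", bundle, prior_cells = prior,
                             backend = backend, ...)
  list(`3a` = r3a, `3b` = r3b, `3c` = r3c)
}

# ---- uncertainty sweep -----------------------------------------------------

#' Classify per-unit selection counts into sensitivity classes
#'
#' Units selected in at least 7 of the iterations are robust to
#' uncertainty ("low" sensitivity), 4-6 "medium", 1-3 "high"; units never
#' selected form their own "never" class (the classification compares
#' selected sites only).
#'
#' @param counts Integer vector of selection counts.
#' @return Factor with levels `low`, `medium`, `high`, `never`.
#' @export
classify_sensitivity <- function(counts) {
  cls <- ifelse(counts >= 7, "low",
                ifelse(counts >= 4, "medium",
                       ifelse(counts >= 1, "high", "never")))
  factor(cls, levels = c("low", "medium", "high", "never"))
}

#' Uncertainty sweep over coefficient-of-variation penalty weights
#'
#' The robustness analysis of the restoration problem: absolute targets are
#' frozen from the unpenalized layers (`t_k = target * sum(f_k)`), then for
#' each penalty weight `w` the cost layer is inflated by `w` times its CV
#' and every feature deflated by `w` times its CV (clamped at zero), the
#' problem is re-solved without boundary penalties or locked-in units, and
#' per-unit selection counts are accumulated. Features lacking a CV layer
#' are excluded. Because penalized features never exceed the originals,
#' any feasible iteration's selection also meets the frozen targets on the
#' original features; this dominance is asserted on every run. Infeasible
#' iterations are recorded, flagged, and excluded from the counts.
#'
#' @param bundle A prepared `landscape_bundle`.
#' @param weights Penalty weights (default 0.0-0.8 in steps of 0.1: nine
#'   iterations).
#' @param target Relative target frozen into absolute targets (default 0.2).
#' @param entry Catalog entry providing the base recipes (default `"2b"`).
#' @param backend Solver backend.
#' @return A `sensitivity_map`: per-unit `counts`, `class`, the `units`,
#'   per-iteration `solutions`, `feasible` flags, frozen `targets_abs`, and
#'   the weight schedule.
#' @export
uncertainty_sweep <- function(bundle, weights = seq(0, 0.8, by = 0.1),
                              target = 0.2, entry = "2b", backend = "milp",
                              ...) {
  if (is.character(entry)) entry <- problem_catalog()[[entry]]
  if (is.null(bundle$derived)) bundle <- prepare_bundle(bundle)
  units <- entry_units(entry, bundle)
  if (units$n == 0L) stop("no planning units for the uncertainty sweep",
                          call. = FALSE)
  feats_all <- entry_features(entry, bundle, units)
  has_cv <- vapply(names(feats_all), function(nm)
    !is.null(bundle$feature_cv[[nm]]), logical(1))
  feats <- feats_all[has_cv]
  if (length(feats) == 0L) stop("no feature carries a CV layer", call. = FALSE)
  fcv <- lapply(names(feats), function(nm) {
    v <- unit_values(units, bundle$feature_cv[[nm]])
    v[is.na(v)] <- 0
    v
  })
  names(fcv) <- names(feats)
  cost <- entry_cost(entry, bundle, units)
  cost_cv <- unit_values(units, bundle$soil_moisture_cv)
  cost_cv[is.na(cost_cv)] <- 0

  fmat <- vapply(feats, function(f) { f[is.na(f)] <- 0; f }, numeric(units$n))
  t_abs <- target * colSums(fmat)
  names(t_abs) <- names(feats)

  counts <- integer(units$n)
  feasible <- logical(length(weights))
  solutions <- vector("list", length(weights))
  for (i in seq_along(weights)) {
    w <- weights[i]
    fw <- lapply(names(feats), function(nm)
      utility_feature(fmat[, nm], fcv[[nm]], w))
    names(fw) <- names(feats)
    tw <- lapply(t_abs, function(t) list(kind = "absolute", value = t))
    spw <- problem_spec(units, utility_cost(cost, cost_cv, w), fw,
                        targets = tw, boundary_penalty = 0,
                        locked_in = integer(0), gap = entry$gap)
    sol <- solve_minset(spw, backend, ...)
    solutions[[i]] <- sol
    feasible[i] <- sol$status != "infeasible"
    if (feasible[i]) {
      # dominance: the selection must meet the frozen targets on the
      # ORIGINAL features (penalized utilities never exceed them)
      orig_cap <- colSums(fmat[sol$selected, , drop = FALSE])
      stopifnot(all(orig_cap >= t_abs - 1e-6))
      counts <- counts + sol$selected
    }
  }
  structure(list(counts = counts, class = classify_sensitivity(counts),
                 units = units, solutions = solutions, feasible = feasible,
                 n_iterations = length(weights), n_feasible = sum(feasible),
                 targets_abs = t_abs, weights = weights),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %d iteration(s), %d feasible\n",
              x$n_iterations, x$n_feasible))
  print(table(x$class))
  invisible(x)
}
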