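test_that("the problem catalog ships the frozen default configurations", {
  cat_ <- problem_catalog()
  expect_setequal(names(cat_), c("1a", "1b", "1c", "1d", "2a", "2b",
                                 "3a", "3b", "3c"))
  b_defaults <- vapply(cat_, `[[`, numeric(1), "boundary_penalty")
  expect_equal(unname(b_defaults[c("1a", "1d")]), c(1e-5, 1e-5))
  expect_equal(unname(b_defaults[c("1b", "1c", "2b", "3a")]), rep(0, 4))
  expect_equal(unname(b_defaults[c("2a", "3b", "3c")]), c(0.1, 2.5, 1.5))
  for (e in cat_) {
    expect_equal(e$target, 0.2)
    expect_equal(e$edge_factor, 0.5)
    expect_equal(e$gap, 0.01)
  }
  expect_equal(cat_[["1d"]]$cost_recipe, "soil_moisture")       # untransposed
  expect_equal(cat_[["2a"]]$cost_recipe, "transposed_soil_moisture")
  expect_equal(cat_[["3c"]]$cost_recipe, "shifted_connectivity_loss")
  expect_equal(cat_[["2a"]]$locked_recipe, "intact")
  expect_true(all(vapply(cat_[c("3a", "3b", "3c")], `[[`, logical(1),
                         "conservation_mask")))
})

test_that("restoration runs lock in every intact unit and shift costs above 1", {
  b <- small_bundle()
  r2a <- run_catalog_problem("2a", b, time_limit = 5)
  expect_false(r2a$status == "infeasible")
  intact_units <- which(r2a$units$cell_index %in% which(b$derived$intact))
  expect_true(all(r2a$solution$selected[intact_units]))
  expect_true(all(r2a$solution$captured$proportion[
    r2a$solution$captured$total > 0] >= 0.2 - 1e-9))

  ch <- scd_chain(b, time_limit = 5)
  expect_gte(min(ch[["3c"]]$solution$spec$cost), 1)   # shift contract
  sel3a <- ch[["3a"]]$units$cell_index[ch[["3a"]]$solution$selected]
  sel3b <- ch[["3b"]]$units$cell_index[ch[["3b"]]$solution$selected]
  sel3c <- ch[["3c"]]$units$cell_index[ch[["3c"]]$solution$selected]
  expect_true(all(sel3a %in% sel3b))
  expect_true(all(sel3a %in% sel3c))
  # all chained selections stay inside the conservation-area pool
  pool_b <- ch[["3b"]]$units$cell_index
  expect_true(all(sel3b %in% pool_b))
  scd_or_prior <- b$derived$scd_mask
  scd_or_prior[sel3a] <- TRUE
  expect_true(all(scd_or_prior[sel3c]))
})

test_that("an exhausted planning-unit pool is reported infeasible, not an error", {
  b <- small_bundle()
  entry <- problem_catalog()[["1d"]]
  entry$future_threshold <- 15
  capped <- b
  capped$future_cover <- raster_grid(pmin(b$future_cover$values, 12),
                                     b$future_cover$cell_size,
                                     b$future_cover$origin)
  r <- run_catalog_problem(entry, capped, time_limit = 5)
  expect_identical(r$status, "infeasible")
  expect_match(r$reason, "future cover >= 15")
})

test_that("solution summaries report order statistics, hectares, and captures", {
  u <- mk_units(matrix(TRUE, 10, 10))
  sel <- rep(FALSE, 100); sel[1:5] <- TRUE
  sm <- summarize_solution(sel, list(v = c(1, 2, 3, 4, 5, rep(99, 95))),
                           cell_size = 30)
  expect_equal(sm$stats$median, 3)
  expect_equal(sm$stats$q1, 2)
  expect_equal(sm$stats$q3, 4)
  expect_equal(sm$stats$min, 1)
  expect_equal(sm$stats$max, 5)
  expect_equal(sm$area_ha, 5 * 0.09)
  expect_equal(summarize_solution(rep(TRUE, 100), list(), 30)$area_ha, 9)
  empty <- summarize_solution(rep(FALSE, 100), list(v = 1:100), 30)
  expect_true(is.na(empty$stats$median))
  expect_equal(empty$area_ha, 0)
})

test_that("overlap percentages follow cell-center containment", {
  tpl <- grid_of(matrix(0, 10, 10))
  u <- mk_units(matrix(TRUE, 10, 10))
  whole <- polygon_layer(list(all = cbind(c(0, 300, 300, 0), c(0, 0, 300, 300))))
  expect_equal(overlap_report(rep(TRUE, 100), u, whole, tpl), 100)
  outside <- polygon_layer(list(x = cbind(c(500, 600, 600, 500), c(0, 0, 100, 100))))
  expect_equal(overlap_report(rep(TRUE, 100), u, outside, tpl), 0)
  half <- polygon_layer(list(west = cbind(c(0, 150, 150, 0), c(0, 0, 300, 300))))
  expect_equal(overlap_report(rep(TRUE, 100), u, half, tpl), 50)
  expect_true(is.na(overlap_report(rep(FALSE, 100), u, whole, tpl)))
})

test_that("a generalist whose habitat contains a specialist's umbrellas it", {
  # generalist twice as dense inside region A (which also holds all of the
  # specialist); minimum-set selection for the generalist therefore sits in
  # A and must capture at least its own target share of the specialist
  u <- mk_units(matrix(TRUE, 4, 4))
  in_A <- rep(c(TRUE, FALSE), each = 8)
  generalist <- ifelse(in_A, 2, 1)
  specialist <- ifelse(in_A, 1, 0)
  sp <- problem_spec(u, cost = rep(1, 16),
                     features = list(gen = generalist, spec_ = specialist),
                     targets = c(0.2, 0), gap = 0)
  s <- solve_minset(sp, "exhaustive")
  cap <- capture_report(s, list(gen = generalist, spec_ = specialist))
  expect_gte(cap$proportion[1], 0.2)
  expect_gte(cap$proportion[2], 0.2)
})

test_that("sensitivity classes partition counts at the documented breaks", {
  counts <- c(0, 1, 3, 4, 6, 7, 9)
  cls <- classify_sensitivity(counts)
  expect_equal(as.character(cls),
               c("never", "high", "high", "medium", "medium", "low", "low"))
  expect_true(all(table(cls) == c(2, 2, 2, 1)))
})

test_that("the uncertainty sweep freezes targets and collapses without CV", {
  b <- small_bundle()
  # all-zero CV layers: every iteration identical, every selected unit low
  b0 <- b
  zero <- function(g) raster_grid(g$values * 0, g$cell_size, g$origin,
                                  g$nodata_mask)
  b0$feature_cv <- lapply(b$feature_cv, function(g) if (is.null(g)) NULL else zero(g))
  b0$soil_moisture_cv <- zero(b$soil_moisture_cv)
  sw0 <- uncertainty_sweep(b0, time_limit = 5)
  expect_equal(sw0$n_iterations, 9)
  expect_equal(sw0$n_feasible, 9)
  sels <- vapply(sw0$solutions, function(s) paste(which(s$selected), collapse = ","),
                 character(1))
  expect_equal(length(unique(sels)), 1L)
  expect_true(all(sw0$counts[sw0$solutions[[1]]$selected] == 9))
  expect_true(all(sw0$class[sw0$counts > 0] == "low"))

  # positive CVs: selections meet the frozen absolute targets on the
  # original (unpenalized) features in every feasible iteration
  sw <- uncertainty_sweep(b, time_limit = 5)
  expect_equal(sw$n_iterations, 9)
  entry <- problem_catalog()[["2b"]]
  units <- sagescape:::entry_units(entry, b)
  feats <- sagescape:::entry_features(entry, b, units)
  has_cv <- vapply(names(feats), function(nm) !is.null(b$feature_cv[[nm]]),
                   logical(1))
  fmat <- vapply(feats[has_cv], function(f) { f[is.na(f)] <- 0; f },
                 numeric(units$n))
  for (i in which(sw$feasible)) {
    cap <- colSums(fmat[sw$solutions[[i]]$selected, , drop = FALSE])
    expect_true(all(cap >= sw$targets_abs - 1e-6))
  }
  # counts only accumulate over feasible iterations
  expect_lte(max(sw$counts), sw$n_feasible)
})

test_that("umbrella matrices hold their diagonal at the target", {
  b <- small_bundle()
  um <- umbrella_matrix(b, species = c("brewers_sparrow_density",
                                       "sagebrush_sparrow_density"),
                        time_limit = 5)
  expect_equal(dim(um), c(3L, 2L))
  expect_gte(um["brewers_sparrow_density", "brewers_sparrow_density"], 0.2 - 1e-9)
  expect_gte(um["sagebrush_sparrow_density", "sagebrush_sparrow_density"],
             0.2 - 1e-9)
  expect_true(all(um["all_species", ] >= 0.2 - 1e-9))
})

test_that("solution rasters recover the selection", {
  b <- small_bundle()
  r <- run_catalog_problem("1b", b, time_limit = 5)
  sr <- solution_raster(r$units, r$solution)
  expect_equal(sum(sr$values == 1, na.rm = TRUE), sum(r$solution$selected))
  expect_equal(sum(!is.na(sr$values)), r$units$n)
})
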