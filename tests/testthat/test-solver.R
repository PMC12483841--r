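test_that("formulation exposes the boundary accounting exactly", {
  u <- mk_units(matrix(TRUE, 1, 2))
  sp <- problem_spec(u, cost = c(1, 1), features = list(f = c(1, 1)),
                     targets = 0, boundary_penalty = 1, edge_factor = 0.5)
  form <- formulate(sp)
  # p* = shared (30) + 0.5 * study edge (90) = 75 per unit; both selected:
  # 2 * 75 - 2 * 30 = 90 of penalized exposed boundary
  expect_equal(form$pstar, c(75, 75))
  expect_equal(boundary_length(u, c(TRUE, TRUE), 0.5), 90)
  expect_equal(solve_minset(
    problem_spec(u, c(1, 1), list(f = c(1, 1)), targets = 1,
                 boundary_penalty = 1, edge_factor = 0.5, gap = 0),
    "exhaustive")$objective, 2 + 90)
  # b = 0 reduces the objective to the pure cost sum
  sp0 <- problem_spec(u, c(2, 3), list(f = c(1, 1)), targets = 0)
  expect_equal(formulate(sp0)$linear_cost, c(2, 3))
  # zero relative target is vacuous
  s0 <- solve_minset(sp0, "exhaustive")
  expect_equal(sum(s0$selected), 0)
  expect_equal(s0$objective, 0)
})

test_that("tiny instances solve to the enumerated optimum on all backends", {
  m <- matrix(FALSE, 1, 5); m[1, c(1, 3, 5)] <- TRUE
  u <- mk_units(m)
  sp <- problem_spec(u, cost = c(3, 1, 2), features = list(f = c(10, 5, 5)),
                     targets = 0.2, gap = 0)   # need >= 4: unit 2 alone suffices
  for (bk in c("exhaustive", "milp")) {
    s <- solve_minset(sp, bk)
    expect_identical(which(s$selected), 2L)
    expect_equal(s$objective, 1)
  }
  sg <- solve_minset(sp, "greedy")
  expect_gte(sg$objective, 1)
  expect_true(all(sg$captured$proportion >= 0.2))
})

test_that("locked-in units stay selected even when unnecessary", {
  m <- matrix(FALSE, 1, 3); m[1, c(1, 3)] <- TRUE
  u <- mk_units(m)
  sp <- problem_spec(u, cost = c(5, 1), features = list(f = c(0, 10)),
                     targets = 0.2, locked_in = 1L, gap = 0)
  for (bk in c("exhaustive", "milp", "greedy")) {
    s <- solve_minset(sp, bk)
    expect_true(s$selected[1], label = bk)
    expect_true(s$selected[2], label = bk)
  }
})

test_that("a zero-total feature with a positive relative target is vacuous", {
  u <- mk_units(matrix(TRUE, 1, 2))
  sp <- problem_spec(u, cost = c(1, 2),
                     features = list(empty = c(0, 0), real = c(4, 1)),
                     targets = 0.2, gap = 0)
  expect_warning(t_abs <- sagescape:::absolute_targets(sp), "vacuous")
  expect_equal(unname(t_abs), c(0, 1))
  s <- suppressWarnings(solve_minset(sp, "exhaustive"))
  expect_false(s$status == "infeasible")
  expect_identical(which(s$selected), 1L)
})

test_that("infeasible problems name the violated features on every backend", {
  u <- mk_units(matrix(TRUE, 1, 3))
  sp <- problem_spec(u, cost = rep(1, 3),
                     features = list(ok = c(5, 5, 5), short = c(1, 1, 1)),
                     targets = list(ok = list(kind = "relative", value = 0.2),
                                    short = list(kind = "absolute", value = 10)))
  for (bk in c("exhaustive", "milp", "greedy")) {
    s <- solve_minset(sp, bk)
    expect_identical(s$status, "infeasible", label = bk)
    expect_identical(s$violated_features, "short", label = bk)
  }
})

test_that("milp matches exhaustive enumeration on a randomized battery", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:40) {
    sp <- random_instance()
    a <- solve_minset(sp, "exhaustive")
    m <- solve_minset(sp, "milp")
    expect_identical(a$status == "infeasible", m$status == "infeasible")
    if (a$status == "infeasible") next
    n_checked <- n_checked + 1
    expect_lt(abs(a$objective - m$objective), 1e-9)
    t_abs <- suppressWarnings(sagescape:::absolute_targets(sp))
    for (s in list(a, m)) {
      expect_true(all(colSums(sp$features[s$selected, , drop = FALSE]) >=
                        t_abs - 1e-9))
      # the boundary component bit-matches the geometric recomputation
      expect_equal(s$boundary_component,
                   sp$boundary_penalty *
                     boundary_length(sp$units, s$selected, sp$edge_factor))
    }
    g <- solve_minset(sp, "greedy")
    expect_gte(g$objective, a$objective - 1e-9)
  }
  expect_gt(n_checked, 15)
})

test_that("raising a target never decreases the optimal objective", {
  set.seed(55)
  u <- mk_units(matrix(runif(12) > 0.2, 3, 4))
  feats <- list(f1 = runif(u$n, 0, 2), f2 = runif(u$n, 0, 2))
  prev <- -Inf
  for (tv in c(0, 0.2, 0.4, 0.6, 0.9)) {
    s <- solve_minset(problem_spec(u, runif(u$n, 0.5, 2), feats,
                                   targets = c(tv, 0.3), gap = 0,
                                   boundary_penalty = 0.1), "exhaustive")
    expect_gte(s$objective, prev - 1e-12)
    prev <- s$objective
  }
})

test_that("with uniform costs and b = 0 the optimum is a minimum-cardinality cover", {
  set.seed(77)
  m <- matrix(TRUE, 3, 4)
  u <- mk_units(m)
  feats <- list(f1 = runif(u$n), f2 = runif(u$n))
  sp <- problem_spec(u, rep(1, u$n), feats, targets = 0.35, gap = 0)
  s <- solve_minset(sp, "exhaustive")
  # enumerate minimum cardinality by brute force over subset sizes
  t_abs <- sagescape:::absolute_targets(sp)
  fmat <- sp$features
  min_card <- NA
  for (k in 0:u$n) {
    combs <- utils::combn(u$n, k)
    ok <- apply(combs, 2, function(ix)
      all(colSums(fmat[ix, , drop = FALSE]) >= t_abs - 1e-9))
    if (any(ok)) { min_card <- k; break }
  }
  expect_equal(sum(s$selected), min_card)
})

test_that("capture reports are exact proportions of feature totals", {
  u <- mk_units(matrix(TRUE, 2, 2))
  feats <- list(a = c(1, 2, 3, 4), b = c(0, 0, 5, 5))
  all_sel <- capture_report(rep(TRUE, 4), feats)
  expect_equal(all_sel$proportion, c(1, 1))
  none <- capture_report(rep(FALSE, 4), feats)
  expect_equal(none$proportion, c(0, 0))
  some <- capture_report(c(TRUE, FALSE, TRUE, FALSE), feats)
  expect_equal(some$captured, c(4, 5))
  expect_equal(some$proportion, c(0.4, 0.5))
})

test_that("boundary-penalty calibration reports the clustering trade-off", {
  # four scattered high-value cells tie a 2x2 clump at b = 0 (lexicographic
  # tie-break picks the scattered set); any positive penalty consolidates
  # the selection, so exposed boundary is non-increasing in b
  u <- mk_units(matrix(TRUE, 3, 5))
  f <- rep(0.01, u$n)
  f[c(1, 6, 9, 13)] <- 1.05                 # scattered, pairwise non-adjacent
  f[c(11, 12, 14, 15)] <- 1.0               # 2x2 clump in the far corner
  sp <- problem_spec(u, cost = rep(1, u$n), features = list(f = f),
                     targets = 0.45, gap = 0)
  cal <- calibrate_boundary_penalty(sp, candidates = c(0, 0.002, 0.02),
                                    inflation_tolerance = 0.5,
                                    backend = "exhaustive")
  expect_true(all(diff(cal$report$exposed_boundary) <= 1e-9))
  expect_lt(cal$report$exposed_boundary[3], cal$report$exposed_boundary[1])
  expect_true(all(diff(cal$report$n_clumps) <= 0))
  expect_equal(cal$chosen_b, 0.02)   # tolerance 0.5 admits every candidate here
  # degenerate sweep
  cal0 <- calibrate_boundary_penalty(sp, candidates = 0, backend = "exhaustive")
  expect_equal(cal0$chosen_b, 0)
  # infinite tolerance returns the maximum candidate
  cal_inf <- calibrate_boundary_penalty(sp, candidates = c(0, 0.01),
                                        inflation_tolerance = Inf,
                                        backend = "exhaustive")
  expect_equal(cal_inf$chosen_b, 0.01)
})
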