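# Constructed cover series with a known change distribution: 100 cells with
# historic-minus-current of 10 on cells 1-5 (extreme loss), 4 on cells 21 and
# 31 (in the one-to-two-sd band), and potential-minus-current of 10 on cells
# 11-13 plus 3 on cell 21 (its own band). Hand application of the rule marks
# cells 1-5 (historic rule), 11-13 (potential rule), and 21 (joint band);
# cell 31 sits in the historic band but below the potential band and stays
# intact-eligible.
degradation_fixture <- function() {
  dh <- matrix(0, 10, 10); dh[1:5] <- 10; dh[21] <- 4; dh[31] <- 4
  dp <- matrix(0, 10, 10); dp[11:13] <- 10; dp[21] <- 3
  current <- matrix(30, 10, 10)
  list(historic = grid_of(current + dh), potential = grid_of(current + dp),
       current = grid_of(current), dh = dh, dp = dp)
}

test_that("degradation classification applies the two-sd and joint-band rules", {
  fx <- degradation_fixture()
  deg <- classify_degraded(fx$historic, fx$potential, fx$current)
  expect_identical(which(deg), c(1:5, 11:13, 21L))
  expect_equal(sum(deg), 9)
  expect_true(deg[21])     # joint one-to-two-sd band on both changes
  expect_false(deg[31])    # historic band alone is not enough
  # closed-form oracle over every cell
  mh <- mean(fx$dh); sh <- sd(fx$dh); mp <- mean(fx$dp); sp <- sd(fx$dp)
  oracle <- (fx$dh >= mh + 2 * sh) | (fx$dp >= mp + 2 * sp) |
    (fx$dh >= mh + sh & fx$dh < mh + 2 * sh &
       fx$dp >= mp + sp & fx$dp < mp + 2 * sp)
  expect_identical(deg, oracle)
  # zero variance in both change fields is not classifiable
  flat <- grid_of(matrix(30, 5, 5))
  expect_error(classify_degraded(flat, flat, flat), "zero variance")
})

test_that("intact excludes degraded cells and applies the inclusive threshold", {
  fx <- degradation_fixture()
  deg <- classify_degraded(fx$historic, fx$potential, fx$current)
  cur <- fx$current$values
  cur[50] <- 15.0; cur[51] <- 14.9; cur[1] <- 40   # cell 1 is degraded
  cur_g <- grid_of(cur)
  intact <- classify_intact(cur_g, deg, threshold = 15)
  expect_true(intact[50])
  expect_false(intact[51])
  expect_false(intact[1])
  expect_false(any(intact & deg))
})

test_that("the order-reversing transposition maps the maximum to exactly 1", {
  expect_equal(transpose_max(c(0.2, 0.5, 1.0)), c(1.8, 1.5, 1.0))
  set.seed(2)
  v <- runif(50) * 10
  tv <- transpose_max(v)
  expect_equal(tv[which.max(v)], 1)
  expect_equal(order(tv), rev(order(v)))
  expect_equal(rank(-v, ties.method = "average"), rank(tv, ties.method = "average"))
  # ties remain ties
  expect_equal(transpose_max(c(2, 2, 1)), c(1, 1, 2))
})

test_that("the positive shift maps the minimum to exactly 1 and keeps order", {
  expect_equal(shift_positive(c(-3, -1, 0, 2)), c(1, 3, 4, 6))
  expect_equal(shift_positive(c(2, 5)), c(5, 8))   # |min| added verbatim
  set.seed(3)
  v <- rnorm(40)
  sv <- shift_positive(v)
  expect_equal(min(sv), 1)
  expect_equal(order(sv), order(v))
})

test_that("utility transforms penalize uncertainty monotonically and clamp at zero", {
  expect_equal(utility_cost(2.0, 0.5, 0.4), 2.2)
  expect_equal(utility_feature(0.3, 1.0, 0.5), 0)
  v <- c(1, 2, 0.1); cv <- c(0.5, 0, 2)
  expect_identical(utility_cost(v, cv, 0), v)
  expect_identical(utility_feature(v, cv, 0), v)
  ws <- seq(0, 0.8, by = 0.1)
  for (i in seq_along(ws)[-1]) {
    expect_true(all(utility_feature(v, cv, ws[i]) <= utility_feature(v, cv, ws[i - 1])))
    expect_true(all(utility_cost(v, cv, ws[i]) >= utility_cost(v, cv, ws[i - 1])))
  }
  expect_error(utility_cost(1, -0.1, 0.5), ">= 0")
})

test_that("ecological potential imputes cluster-wise intact means onto degraded cells", {
  vals <- matrix(0, 4, 4)
  vals[, 1:2] <- c(0.2, 0.4)               # left cluster intact values
  vals[, 3:4] <- 9                         # right cluster (never intact)
  g <- grid_of(vals)
  intact <- matrix(FALSE, 4, 4); intact[, 1] <- TRUE
  degraded <- matrix(FALSE, 4, 4); degraded[, 2] <- TRUE; degraded[, 4] <- TRUE
  clusters <- polygon_layer(list(
    west = cbind(c(0, 60, 60, 0), c(0, 0, 120, 120)),
    east = cbind(c(60, 120, 120, 60), c(0, 0, 120, 120))))
  ep <- ecological_potential(g, intact, clusters, degraded)
  expect_equal(ep$values[, 2], rep(0.3, 4))        # zonal mean of {0.2, 0.4}
  expect_true(all(is.na(ep$values[, 4])))          # no intact cells: undefined
  expect_true(all(is.na(ep$values[, c(1, 3)])))    # only degraded cells receive
  # two clusters with disjoint means give a step-constant surface
  intact2 <- matrix(FALSE, 4, 4); intact2[, 1] <- TRUE; intact2[, 3] <- TRUE
  ep2 <- ecological_potential(g, intact2, clusters, degraded)
  expect_equal(ep2$values[, 2], rep(0.3, 4))
  expect_equal(ep2$values[, 4], rep(9, 4))
})

test_that("planning-unit bookkeeping satisfies the perimeter identity", {
  iso <- mk_units(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(nrow(iso$adjacency), 0)
  expect_equal(iso$study_edge, 120)
  dom <- mk_units(matrix(TRUE, 1, 2))
  expect_equal(nrow(dom$adjacency), 1)
  expect_equal(dom$study_edge, c(90, 90))
  full <- mk_units(matrix(TRUE, 3, 3))
  expect_equal(nrow(full$adjacency), 12)   # enumeration of rook edges in 3x3
  expect_true(all(full$adjacency[, 1] < full$adjacency[, 2]))
  set.seed(6)
  for (i in 1:5) {
    m <- matrix(runif(48) > 0.4, 6, 8)
    if (!any(m)) next
    u <- mk_units(m)
    deg <- tabulate(c(u$adjacency), u$n)
    expect_equal(u$perimeter, deg * u$shared_edge_length + u$study_edge)
  }
  expect_error(build_units(matrix(FALSE, 2, 2)), "empty")
})

test_that("future-cover masking keeps exactly the qualifying cells", {
  set.seed(7)
  fut <- grid_of(matrix(runif(100, 0, 20), 10, 10))
  u <- mk_units(matrix(TRUE, 10, 10))
  expect_identical(mask_by_future_cover(u, fut, NULL), u)
  expect_identical(mask_by_future_cover(u, fut, "none"), u)
  m10 <- mask_by_future_cover(u, fut, 10)
  expect_equal(m10$n, sum(fut$values >= 10))
  expect_identical(m10$cell_index, which(fut$values >= 10))
  capped <- grid_of(matrix(pmin(fut$values, 12), 10, 10))
  m15 <- mask_by_future_cover(u, capped, 15)
  expect_equal(m15$n, 0)
})
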