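# shared fixtures, built in code at test time

# planning units straight from a logical mask (origin at top-left (0, n*cs))
mk_units <- function(mask, cs = 30) {
  sagescape:::units_from_mask(mask, cs, c(0, nrow(mask) * cs))
}

grid_of <- function(m, cs = 30) raster_grid(m, cs, c(0, nrow(m) * cs))

sample_skewness <- function(v) {
  v <- v[!is.na(v)]
  mean((v - mean(v))^3) / stats::sd(v)^3
}

# memoized bundles so expensive preparation happens once per test run
.fixture_cache <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    b <- synth_landscape(seed = 11, shape = c(40L, 40L))
    .fixture_cache$small <- prepare_bundle(
      b, window_config(radius = 360, source_threshold = 15, stride = 4L))
  }
  .fixture_cache$small
}

# the default study bundle: generator defaults, fixed seed
default_bundle <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- prepare_bundle(synth_landscape(seed = 1))
  }
  .fixture_cache$default
}

# random small solvable instance for solver batteries
random_instance <- function(b_values = c(0, 0.1, 1), max_units = 12L) {
  repeat {
    nr <- sample(2:4, 1L); nc <- sample(2:3, 1L)
    mask <- matrix(stats::runif(nr * nc) > 0.35, nr, nc)
    if (!any(mask)) next
    u <- mk_units(mask)
    if (u$n <= max_units) break
  }
  K <- sample(2:3, 1L)
  feats <- lapply(seq_len(K), function(k) stats::runif(u$n) * sample(1:5, 1L))
  names(feats) <- paste0("f", seq_len(K))
  lock <- if (stats::runif(1) < 0.3 && u$n > 1L) sample(u$n, 1L) else integer(0)
  problem_spec(u, cost = stats::runif(u$n, 0.5, 3), features = feats,
               targets = stats::runif(K, 0, 0.5),
               boundary_penalty = sample(b_values, 1L),
               locked_in = lock, gap = 0)
}
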