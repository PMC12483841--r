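test_that("raster round-trip through ASCII grid files is bit-exact", {
  g <- raster_grid(matrix(c(1, 2, NA, 4.123456789012345, 5, 6), 2, 3),
                   cell_size = 30, origin = c(1234.5, 6789.25),
                   semantic_tag = "percent cover")
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  g2 <- read_raster(path, semantic_tag = "percent cover")
  expect_identical(g2$values, g$values)
  expect_identical(g2$nodata_mask, g$nodata_mask)
  expect_identical(g2$cell_size, g$cell_size)
  expect_identical(g2$origin, g$origin)
  expect_equal(sum(g2$nodata_mask), 1L)

  ones <- raster_grid(matrix(1, 3, 3), 30, c(0, 90))
  write_raster(ones, path)
  expect_identical(read_raster(path)$values, ones$values)
})

test_that("raster reader fails loudly on malformed or misaligned input", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "1 2 3 4"), path)   # no georeferencing
  expect_error(read_raster(path), "georeferencing")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "1 2 3 4 5 6"), path)       # extra band of values
  expect_error(read_raster(path), "malformed")
  expect_error(read_raster(file.path(tempdir(), "does-not-exist.asc")),
               "unreadable")
  a <- raster_grid(matrix(0, 2, 2), 30, c(0, 60))
  b <- raster_grid(matrix(0, 2, 2), 30, c(30, 60))
  expect_error(check_aligned(a, b), "alignment")
  d <- raster_grid(matrix(0, 3, 2), 30, c(0, 90))
  expect_error(check_aligned(a, d), "alignment")
})

test_that("vector layers round-trip through GeoJSON", {
  pl <- polygon_layer(list(z1 = cbind(c(0, 60, 60, 0), c(0, 0, 60, 60)),
                           z2 = cbind(c(60, 120, 120, 60), c(0, 0, 60, 60))),
                      role_tag = "conservation_area")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_vector(pl, path)
  pl2 <- read_vector(path)
  expect_identical(pl2$polygons, pl$polygons)
  expect_identical(pl2$role_tag, "conservation_area")

  pt <- point_layer(cbind(c(15, 45.5), c(15, 44.25)), weight = c(1, 2.5))
  write_vector(pt, path)
  pt2 <- read_vector(path)
  expect_identical(pt2$points, pt$points)
  expect_identical(pt2$weight, pt$weight)
  expect_error(point_layer(cbind(1, 1), weight = 0), "positive")
})

test_that("zonal means follow the cell-center/eligibility contract", {
  vals <- matrix(c(0.2, 0.4, 1, 3), 2, 2)   # col 1: 0.2, 0.4; col 2: 1, 3
  g <- grid_of(vals)
  zones <- polygon_layer(list(left = cbind(c(0, 30, 30, 0), c(0, 0, 60, 60)),
                              right = cbind(c(30, 60, 60, 30), c(0, 0, 60, 60))))
  zm <- zonal_mean(g, zones)
  expect_equal(zm[["left"]], 0.3)
  expect_equal(zm[["right"]], 2)
  # masked-out zone is undefined, not zero
  zm2 <- zonal_mean(g, zones, within_mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(zm2[["left"]], 0.3)
  expect_true(is.na(zm2[["right"]]))
  # constant field: both zones report the constant
  zc <- zonal_mean(grid_of(matrix(5, 4, 4)),
                   polygon_layer(list(a = cbind(c(0, 60, 60, 0), c(0, 0, 120, 120)),
                                      b = cbind(c(60, 120, 120, 60), c(0, 0, 120, 120)))))
  expect_equal(unname(zc), c(5, 5))
})

test_that("zonal means over a partition conserve the global mean", {
  set.seed(4)
  g <- grid_of(matrix(runif(12 * 10), 12, 10))
  zones <- polygon_layer(list(a = cbind(c(0, 150, 150, 0), c(0, 0, 360, 360)),
                              b = cbind(c(150, 300, 300, 150), c(0, 0, 360, 360))))
  counts <- vapply(zones$polygons, function(p) sum(cells_in_polygon(p, g)),
                   numeric(1))
  zm <- zonal_mean(g, zones)
  expect_equal(sum(zm * counts) / sum(counts), mean(g$values))
})

test_that("buffer masks equal the brute-force center-distance rule", {
  tpl <- grid_of(matrix(0, 40, 40))
  pt <- point_layer(cbind(615, 585))
  bm <- buffer_mask(pt, 1000, tpl)
  cc <- cell_centers(tpl)
  brute <- sqrt((cc$x - 615)^2 + (cc$y - 585)^2) <= 1000
  expect_identical(bm, brute)
  # degenerate radius: exactly the one cell whose center is hit
  bm0 <- buffer_mask(point_layer(cbind(45, 45)), 0, grid_of(matrix(0, 2, 2)))
  expect_equal(sum(bm0), 1)
  expect_true(bm0[1, 2])
  # point far outside the grid contributes nothing
  expect_false(any(buffer_mask(point_layer(cbind(1e6, 1e6)), 500, tpl)))
})

test_that("rescale01 maps to [0, 1] with the constant-layer convention", {
  g <- grid_of(matrix(c(0, 5, 10, NA), 2, 2))
  r <- rescale01(g)
  expect_equal(sort(as.vector(r$values[!r$nodata_mask])), c(0, 0.5, 1))
  expect_true(r$nodata_mask[2, 2])
  rc <- rescale01(grid_of(matrix(7, 2, 2)))
  expect_true(all(rc$values == 0))
  set.seed(1)
  rr <- rescale01(grid_of(matrix(rnorm(25), 5, 5)))
  expect_equal(range(rr$values), c(0, 1))
  expect_error(rescale01(grid_of(matrix(NA_real_, 2, 2))), "all-nodata")
})

test_that("coefficient of variation follows sd/mean with nodata at mean <= 0", {
  m <- grid_of(matrix(c(4, 3, 0, -1), 2, 2))
  s <- grid_of(matrix(c(2, 0, 1, 1), 2, 2))
  cv <- coefficient_of_variation(m, s)
  expect_equal(cv$values[1, 1], 0.5)
  expect_equal(cv$values[2, 1], 0)
  expect_true(cv$nodata_mask[1, 2])    # mean 0
  expect_true(cv$nodata_mask[2, 2])    # mean negative
  expect_error(coefficient_of_variation(m, grid_of(matrix(-1, 2, 2))), ">= 0")
})
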