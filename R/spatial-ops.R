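#' Which cell centers fall inside a polygon
#'
#' Membership of a cell in a polygon is decided by containment of the cell
#' center (the cheap, unambiguous rule used throughout the toolkit).
#'
#' @param polygon Two-column vertex matrix (open ring).
#' @param template A [raster_grid()] supplying the cell geometry.
#' @return Logical matrix, `TRUE` where the cell center lies inside.
#' @export
cells_in_polygon <- function(polygon, template) {
  cc <- cell_centers(template)
  pts <- cbind(as.vector(cc$x), as.vector(cc$y))
  bnd <- rbind(polygon, polygon[1L, , drop = FALSE])
  inside <- mgcv::in.out(bnd, pts)
  matrix(inside, nrow(template$values), ncol(template$values))
}

#' Zonal mean of a raster over polygons
#'
#' Arithmetic mean of `value_grid` per zone, over cells whose centers fall
#' in the zone, are `TRUE` in `within_mask`, and are not nodata. A zone with
#' no eligible cell maps to `NA` ("undefined"), never to zero.
#'
#' @param value_grid A [raster_grid()].
#' @param zones A [polygon_layer()].
#' @param within_mask Optional logical matrix restricting eligibility
#'   (e.g. the intact mask); defaults to all cells.
#' @return Named numeric vector, one mean (or `NA`) per zone id.
#' @export
zonal_mean <- function(value_grid, zones, within_mask = NULL) {
  stopifnot(is_raster_grid(value_grid), inherits(zones, "polygon_layer"))
  if (is.null(within_mask)) within_mask <- !value_grid$nodata_mask
  stopifnot(identical(dim(within_mask), dim(value_grid$values)))
  eligible <- within_mask & !value_grid$nodata_mask
  out <- vapply(zones$polygons, function(p) {
    sel <- cells_in_polygon(p, value_grid) & eligible
    if (!any(sel)) NA_real_ else mean(value_grid$values[sel])
  }, numeric(1))
  names(out) <- names(zones$polygons)
  out
}

#' Boolean buffer mask around points
#'
#' A cell is `TRUE` iff its center lies within `radius` (Euclidean, map
#' units) of any point. Points outside the grid extent simply contribute no
#' cells.
#'
#' @param points A [point_layer()].
#' @param radius Buffer radius in map units (metres); must be `>= 0`.
#' @param template A [raster_grid()] supplying the cell geometry.
#' @return Logical matrix of the template's shape.
#' @export
buffer_mask <- function(points, radius, template) {
  stopifnot(inherits(points, "point_layer"), radius >= 0,
            is_raster_grid(template))
  cc <- cell_centers(template)
  out <- matrix(FALSE, nrow(template$values), ncol(template$values))
  r2 <- radius^2
  for (i in seq_len(nrow(points$points))) {
    dx <- cc$x - points$points[i, 1L]
    dy <- cc$y - points$points[i, 2L]
    out <- out | (dx * dx + dy * dy <= r2)
  }
  out
}

#' Rescale a raster linearly to [0, 1]
#'
#' `(v - min) / (max - min)` over non-nodata cells; nodata is preserved. A
#' constant layer maps to all zeros (the declared convention: it keeps the
#' layer usable downstream without dividing by zero).
#'
#' @param grid A [raster_grid()] with at least one data cell.
#' @return A [raster_grid()] on `[0, 1]`.
#' @export
rescale01 <- function(grid) {
  stopifnot(is_raster_grid(grid))
  if (all(grid$nodata_mask)) stop("cannot rescale an all-nodata grid", call. = FALSE)
  rng <- range(grid$values, na.rm = TRUE)
  v <- if (rng[2] > rng[1]) (grid$values - rng[1]) / (rng[2] - rng[1]) else
    grid$values * 0
  raster_grid(v, grid$cell_size, grid$origin, grid$nodata_mask,
              paste0(grid$semantic_tag, " (rescaled 0-1)"))
}

#' Coefficient of variation of paired mean/sd rasters
#'
#' Per-cell `sd / mean`. Cells whose mean is not strictly positive become
#' nodata (the CV is undefined there); downstream stages treat nodata as
#' ineligible.
#'
#' @param mean_grid,sd_grid Aligned [raster_grid()]s; `sd_grid >= 0`.
#' @return A [raster_grid()] of CV values.
#' @export
coefficient_of_variation <- function(mean_grid, sd_grid) {
  check_aligned(mean_grid, sd_grid)
  if (any(sd_grid$values < 0, na.rm = TRUE))
    stop("standard deviations must be >= 0", call. = FALSE)
  bad <- mean_grid$nodata_mask | sd_grid$nodata_mask |
    (!is.na(mean_grid$values) & mean_grid$values <= 0)
  v <- sd_grid$values / mean_grid$values
  v[bad] <- NA_real_
  raster_grid(v, mean_grid$cell_size, mean_grid$origin, bad,
              "coefficient of variation")
}

# ---- kernel machinery (FFT convolution) ------------------------------------

# 2-D convolution of `m` with kernel `k` via FFT, zero-padded at the study
# edge. Used for random-field smoothing and focal means; `k` must have odd
# dimensions.
convolve2d <- function(m, k) {
  dm <- dim(m); dk <- dim(k)
  stopifnot(all(dk %% 2L == 1L))
  n1 <- dm[1] + dk[1] - 1L
  n2 <- dm[2] + dk[2] - 1L
  M <- matrix(0, n1, n2); M[seq_len(dm[1]), seq_len(dm[2])] <- m
  K <- matrix(0, n1, n2); K[seq_len(dk[1]), seq_len(dk[2])] <- k
  full <- Re(fft(fft(M) * fft(K), inverse = TRUE)) / (n1 * n2)
  off1 <- (dk[1] - 1L) %/% 2L
  off2 <- (dk[2] - 1L) %/% 2L
  full[off1 + seq_len(dm[1]), off2 + seq_len(dm[2])]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

disk_kernel <- function(radius_cells) {
  r <- max(0L, floor(radius_cells))
  d <- outer(seq(-r, r)^2, seq(-r, r)^2, "+")
  (d <= radius_cells^2) * 1
}

# Gaussian smoothing of a matrix, edge-normalised so the study boundary is
# not darkened by the zero padding.
smooth_gaussian <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  convolve2d(m, k) / convolve2d(matrix(1, nrow(m), ncol(m)), k)
}

#' Focal (moving-window) mean over a circular window
#'
#' Mean of the data cells within `radius` of each cell center; nodata cells
#' neither contribute nor receive values.
#'
#' @param grid A [raster_grid()].
#' @param radius Window radius in map units.
#' @return A [raster_grid()] of focal means.
#' @export
focal_mean <- function(grid, radius) {
  stopifnot(is_raster_grid(grid), radius > 0)
  k <- disk_kernel(radius / grid$cell_size)
  v <- grid$values
  ok <- !grid$nodata_mask
  v[!ok] <- 0
  num <- convolve2d(v, k)
  den <- convolve2d(ok * 1, k)
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  raster_grid(out, grid$cell_size, grid$origin,
              semantic_tag = paste0(grid$semantic_tag, " (focal mean)"))
}
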