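#' Classify degraded cells from a cover time series
#'
#' A cell is degraded when its cover loss is extreme relative to the
#' study-wide distribution of change. Let `dh = historic - current` and
#' `dp = potential - current` per cell, with mean and standard deviation of
#' each computed over all non-nodata cells. A cell is degraded iff
#' `dh >= mean_h + 2 sd_h`, or `dp >= mean_p + 2 sd_p`, or both changes fall
#' in their own one-to-two-standard-deviation band. Change is signed: cover
#' gains are negative losses and enter the statistics.
#'
#' @param historic,potential,current Aligned percent-cover [raster_grid()]s.
#' @return Logical matrix; nodata cells are `FALSE`.
#' @export
classify_degraded <- function(historic, potential, current) {
  check_aligned(historic, potential, current)
  bad <- historic$nodata_mask | potential$nodata_mask | current$nodata_mask
  dh <- historic$values - current$values
  dp <- potential$values - current$values
  mh <- mean(dh[!bad]); sh <- stats::sd(dh[!bad])
  mp <- mean(dp[!bad]); sp <- stats::sd(dp[!bad])
  if ((is.na(sh) || sh == 0) && (is.na(sp) || sp == 0)) {
    stop("both change fields have zero variance; no degradation classification possible",
         call. = FALSE)
  }
  deg <- (dh >= mh + 2 * sh) | (dp >= mp + 2 * sp) |
    (dh >= mh + sh & dh < mh + 2 * sh & dp >= mp + sp & dp < mp + 2 * sp)
  deg[bad] <- FALSE
  deg[is.na(deg)] <- FALSE
  deg
}

#' Classify intact cells
#'
#' Intact iff not degraded, current cover at or above `threshold`
#' (inclusive), and not nodata. Intact and degraded are disjoint by
#' construction.
#'
#' @param current Current percent-cover [raster_grid()].
#' @param degraded Logical matrix from [classify_degraded()].
#' @param threshold Minimum percent cover (default 15, the conventional
#'   floor for usable sagebrush habitat).
#' @return Logical matrix.
#' @export
classify_intact <- function(current, degraded, threshold = 15) {
  stopifnot(identical(dim(degraded), dim(current$values)))
  intact <- !degraded & !current$nodata_mask & current$values >= threshold
  intact[is.na(intact)] <- FALSE
  intact
}

#' Transpose a layer so high values become low costs
#'
#' `v' = -v + max(v) + 1`, with the maximum taken over the supplied
#' (eligible) values. Order-reversing; the former maximum maps to exactly 1,
#' so all outputs are `>= 1`. Used to turn "more is better" surfaces
#' (connectivity, future cover, soil moisture) into minimizable costs.
#'
#' @param values Finite numeric vector (`NA` passes through).
#' @return Transposed values.
#' @export
transpose_max <- function(values) {
  if (all(is.na(values))) stop("no finite values to transpose", call. = FALSE)
  -values + max(values, na.rm = TRUE) + 1
}

#' Shift a layer to be positive
#'
#' `v' = v + |min(v)| + 1`; order-preserving, and the minimum maps to
#' exactly 1. Applied verbatim even to all-positive inputs (reproducibility
#' of the stated rule over cleverness). Used for signed layers such as
#' connectivity loss, whose negative values would otherwise break the
#' optimizer.
#'
#' @param values Finite numeric vector (`NA` passes through).
#' @return Shifted values, minimum exactly 1.
#' @export
shift_positive <- function(values) {
  if (all(is.na(values))) stop("no finite values to shift", call. = FALSE)
  values + abs(min(values, na.rm = TRUE)) + 1
}

#' Uncertainty-weighted utility layers
#'
#' The risk-averse transforms of the uncertainty sweep: a cost layer is
#' penalized upward by `w` times its coefficient of variation,
#' `cost' = cost + w * cv`; a feature layer is discounted,
#' `feature' = max(0, feature - w * cv)` (negative utilities are clamped to
#' zero). `w = 0` is the identity for both.
#'
#' @param cost,feature Numeric vectors of layer values.
#' @param cv Matching CV values (`>= 0`).
#' @param w Penalty weight (`>= 0`).
#' @return Transformed values.
#' @export
utility_cost <- function(cost, cv, w) {
  stopifnot(w >= 0, all(cv >= 0, na.rm = TRUE))
  cost + w * cv
}

#' @rdname utility_cost
#' @export
utility_feature <- function(feature, cv, w) {
  stopifnot(w >= 0, all(cv >= 0, na.rm = TRUE))
  pmax(0, feature - w * cv)
}

#' Ecological potential of degraded cells by zonal imputation
#'
#' Degraded cells carry depressed present-day feature values, so restoration
#' problems use the value a cell could attain if restored: the mean of the
#' feature over *intact* cells within the cell's management cluster, painted
#' onto every degraded cell of that cluster. Degraded cells in clusters with
#' no intact cell stay `NA` (undefined) and are excluded from that feature's
#' totals downstream.
#'
#' @param feature A [raster_grid()] of present-day feature values.
#' @param intact Logical matrix of intact cells.
#' @param clusters A [polygon_layer()] of management cluster zones.
#' @param degraded Logical matrix of degraded cells.
#' @return A [raster_grid()]: imputed values on degraded cells, `NA`
#'   elsewhere.
#' @export
ecological_potential <- function(feature, intact, clusters, degraded) {
  stopifnot(is_raster_grid(feature),
            identical(dim(intact), dim(feature$values)),
            identical(dim(degraded), dim(feature$values)))
  zm <- zonal_mean(feature, clusters, within_mask = intact)
  out <- matrix(NA_real_, nrow(feature$values), ncol(feature$values))
  for (id in names(clusters$polygons)) {
    if (is.na(zm[[id]])) next
    sel <- cells_in_polygon(clusters$polygons[[id]], feature) & degraded
    out[sel] <- zm[[id]]
  }
  raster_grid(out, feature$cell_size, feature$origin,
              semantic_tag = paste(feature$semantic_tag, "(ecological potential)"))
}

# ---- planning units --------------------------------------------------------

#' Build a planning-unit set from an eligibility grid
#'
#' Planning units are the eligible cells, with the bookkeeping that boundary
#' penalties need: rook (4-neighbour) adjacency with shared-edge length
#' equal to the cell size, per-unit perimeter `4 * cell_size`, and the
#' study-edge length of each unit (edges bordering ineligible or
#' outside-grid cells), so that for every unit
#' `perimeter = sum(shared edges) + study_edge`.
#'
#' @param eligible Logical matrix of eligible cells (at least one `TRUE`).
#' @param cell_size Cell side in metres.
#' @param origin Map coordinates of the grid's top-left corner (used when
#'   writing solutions back to rasters).
#' @return A `planning_units` object: `cell_index` (column-major cell index
#'   per unit), `adjacency` (two-column matrix of unit index pairs, i < j),
#'   `shared_edge_length`, `perimeter`, `study_edge` (per unit), `area_ha`,
#'   plus the grid geometry.
#' @export
build_units <- function(eligible, cell_size = 30,
                        origin = c(0, nrow(eligible) * cell_size)) {
  stopifnot(is.logical(eligible), is.matrix(eligible))
  if (!any(eligible)) stop("empty eligibility grid: no planning units", call. = FALSE)
  units_from_mask(eligible, cell_size, origin)
}

# Internal constructor: tolerates an empty mask (used by masking steps, for
# which an empty pool is a legal, reportable outcome).
units_from_mask <- function(eligible, cell_size, origin) {
  d <- dim(eligible)
  rank <- matrix(0L, d[1], d[2])
  rank[eligible] <- seq_len(sum(eligible))
  # rook neighbour pairs among eligible cells
  hor <- which(eligible[, -d[2], drop = FALSE] & eligible[, -1L, drop = FALSE])
  ver <- which(eligible[-d[1], , drop = FALSE] & eligible[-1L, , drop = FALSE])
  adj <- rbind(
    if (length(hor)) {
      rc <- arrayInd(hor, c(d[1], d[2] - 1L))
      cbind(rank[cbind(rc[, 1L], rc[, 2L])], rank[cbind(rc[, 1L], rc[, 2L] + 1L)])
    },
    if (length(ver)) {
      rc <- arrayInd(ver, c(d[1] - 1L, d[2]))
      cbind(rank[cbind(rc[, 1L], rc[, 2L])], rank[cbind(rc[, 1L] + 1L, rc[, 2L])]
      )
    }
  )
  if (is.null(adj)) adj <- matrix(integer(0), 0L, 2L)
  adj <- t(apply(adj, 1L, sort))
  if (length(adj) == 0L) adj <- matrix(integer(0), 0L, 2L)
  n <- sum(eligible)
  deg <- tabulate(c(adj[, 1L], adj[, 2L]), nbins = n)
  structure(
    list(cell_index = which(eligible), n = n, shape = d,
         cell_size = cell_size, origin = as.numeric(origin),
         eligible = eligible,
         adjacency = adj, shared_edge_length = cell_size,
         perimeter = rep(4 * cell_size, n),
         study_edge = cell_size * (4 - deg),
         area_ha = cell_size^2 / 1e4),
    class = "planning_units")
}

#' @export
print.planning_units <- function(x, ...) {
  cat(sprintf("<planning_units> %d unit(s) on a %d x %d grid @ %g m (%g ha total)\n",
              x$n, x$shape[1], x$shape[2], x$cell_size, x$n * x$area_ha))
  cat(sprintf("  %d rook adjacency pair(s)\n", nrow(x$adjacency)))
  invisible(x)
}

#' Extract per-unit values from a raster layer
#'
#' @param units A `planning_units` object.
#' @param grid An aligned [raster_grid()] (or plain matrix of the grid's
#'   shape).
#' @return Numeric vector, one value per unit (`NA` where the raster has
#'   nodata).
#' @export
unit_values <- function(units, grid) {
  m <- if (is_raster_grid(grid)) grid$values else grid
  stopifnot(identical(dim(m), units$shape))
  m[units$cell_index]
}

#' Restrict a planning-unit set by a future-cover threshold
#'
#' Keeps units whose projected future cover is at or above `threshold`
#' percent; `threshold = NULL` (or `"none"`) leaves the set unchanged. An
#' empty result is legal — downstream problem assembly reports it as
#' infeasible (no available sites) rather than erroring here.
#'
#' @param units A `planning_units` object.
#' @param future_cover Aligned future percent-cover [raster_grid()].
#' @param threshold Percent-cover threshold, or `NULL`/`"none"`.
#' @return A (possibly empty) `planning_units` object.
#' @export
mask_by_future_cover <- function(units, future_cover, threshold = NULL) {
  if (is.null(threshold) || identical(threshold, "none")) return(units)
  stopifnot(identical(dim(future_cover$values), units$shape))
  keep <- units$eligible &
    !future_cover$nodata_mask & future_cover$values >= threshold
  keep[is.na(keep)] <- FALSE
  units_from_mask(keep, units$cell_size, units$origin)
}

#' Restrict a planning-unit set to cells inside polygons
#'
#' @param units A `planning_units` object.
#' @param polygons A [polygon_layer()] (e.g. conservation areas).
#' @param template An aligned [raster_grid()] supplying cell geometry.
#' @return A (possibly empty) `planning_units` object.
#' @export
mask_by_polygons <- function(units, polygons, template) {
  inside <- matrix(FALSE, units$shape[1], units$shape[2])
  for (p in polygons$polygons) inside <- inside | cells_in_polygon(p, template)
  units_from_mask(units$eligible & inside, units$cell_size, units$origin)
}
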