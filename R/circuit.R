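#' Moving-window configuration for circuit connectivity
#'
#' @param radius Window radius in map units (default 30 km, the scale of an
#'   annual sage-grouse home range).
#' @param source_threshold Percent cover at or above which a cell is a
#'   source in `cover_based` mode (default 15, matching the intact-cover
#'   floor).
#' @param stride Cells between visited window centers (window-center
#'   thinning for desk-scale tractability; `1` is the dense scheme).
#' @param source_mode `"cover_based"` (sources from the conductance/cover
#'   surface) or `"point_based"` (sources at supplied points, e.g. leks).
#' @param equal_source_strength If `TRUE` every source injects unit
#'   current; if `FALSE`, point weights scale the injection.
#' @return A `window_config` list.
#' @export
window_config <- function(radius = 30000, source_threshold = 15, stride = 1L,
                          source_mode = c("cover_based", "point_based"),
                          equal_source_strength = TRUE) {
  stopifnot(radius > 0, stride >= 1L)
  structure(list(radius = radius, source_threshold = source_threshold,
                 stride = as.integer(stride),
                 source_mode = match.arg(source_mode),
                 equal_source_strength = isTRUE(equal_source_strength)),
            class = "window_config")
}

# rook-neighbour pairs among TRUE cells of a mask; returns 1-based node
# ranks (column-major over TRUE cells) and the rank matrix
rook_pairs <- function(mask) {
  d <- dim(mask)
  rank <- matrix(0L, d[1], d[2])
  rank[mask] <- seq_len(sum(mask))
  hor <- which(mask[, -d[2], drop = FALSE] & mask[, -1L, drop = FALSE])
  ver <- which(mask[-d[1], , drop = FALSE] & mask[-1L, , drop = FALSE])
  pairs <- rbind(
    if (length(hor)) {
      rc <- arrayInd(hor, c(d[1], d[2] - 1L))
      cbind(rank[cbind(rc[, 1L], rc[, 2L])], rank[cbind(rc[, 1L], rc[, 2L] + 1L)])
    },
    if (length(ver)) {
      rc <- arrayInd(ver, c(d[1] - 1L, d[2]))
      cbind(rank[cbind(rc[, 1L], rc[, 2L])], rank[cbind(rc[, 1L] + 1L, rc[, 2L])])
    })
  if (is.null(pairs)) pairs <- matrix(integer(0), 0L, 2L)
  list(rank = rank, pairs = pairs)
}

#' Solve one circuit window
#'
#' Builds a resistor network on the rook-neighbour graph of the
#' positive-conductance cells of a patch (edge conductance = arithmetic mean
#' of the two cells' conductances), injects current at the source cell,
#' grounds the ground cells (voltage 0), solves the Kirchhoff node
#' equations with a sparse Cholesky factorization, and returns the per-cell
#' throughflow current (half the summed absolute edge currents plus half
#' the absolute injection/extraction at focal cells).
#'
#' If no positive-conductance path joins the source to any ground, the
#' window carries zero current (not an error).
#'
#' @param conductance_patch Numeric matrix of conductances (`>= 0`; `NA`
#'   treated as 0).
#' @param source_cell Column-major cell index of the source in the patch.
#' @param ground_cells Column-major cell indices of the grounds (distinct
#'   from the source).
#' @param injection Current injected at the source (default 1).
#' @return List: `current` (matrix of per-cell throughflow), `injected`,
#'   `grounded` (total current extracted at grounds; equals `injected` up
#'   to solver tolerance when a path exists).
#' @export
solve_window <- function(conductance_patch, source_cell, ground_cells,
                         injection = 1) {
  cond <- conductance_patch
  cond[is.na(cond)] <- 0
  if (any(cond < 0)) stop("conductance must be >= 0", call. = FALSE)
  stopifnot(length(source_cell) == 1L, !source_cell %in% ground_cells)
  d <- dim(cond)
  zero <- list(current = matrix(0, d[1], d[2]), injected = injection, grounded = 0)
  pos <- cond > 0
  if (!pos[source_cell] || length(ground_cells) == 0L) return(zero)
  rp <- rook_pairs(pos)
  n <- sum(pos)
  src <- rp$rank[source_cell]
  grounds <- rp$rank[ground_cells]
  grounds <- grounds[grounds > 0L]
  if (length(grounds) == 0L) return(zero)
  if (nrow(rp$pairs) == 0L) return(zero)
  g <- igraph::graph_from_edgelist(rp$pairs, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  grounds <- grounds[comp[grounds] == comp[src]]
  if (length(grounds) == 0L) return(zero)

  keep <- which(comp == comp[src])
  sub <- match(seq_len(n), keep)            # node rank -> component rank
  m <- length(keep)
  pr <- sub[rp$pairs[, 1L]]; pc <- sub[rp$pairs[, 2L]]
  esel <- !is.na(pr) & !is.na(pc)
  pr <- pr[esel]; pc <- pc[esel]
  cvals <- cond[pos]
  w <- (cvals[rp$pairs[esel, 1L]] + cvals[rp$pairs[esel, 2L]]) / 2
  lap <- Matrix::sparseMatrix(i = c(pr, pc, seq_len(m)),
                              j = c(pc, pr, seq_len(m)),
                              x = c(-w, -w, numeric(m)),
                              dims = c(m, m), symmetric = FALSE)
  Matrix::diag(lap) <- -Matrix::rowSums(lap)
  gr <- sub[grounds]
  free <- setdiff(seq_len(m), gr)
  b <- numeric(m); b[sub[src]] <- injection
  v <- numeric(m)
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(lap[free, free, drop = FALSE]),
                             b[free])),
    error = function(e) NULL)
  if (is.null(sol)) return(zero)            # singular: no effective path
  v[free] <- sol
  edge_i <- w * (v[pr] - v[pc])
  flow <- numeric(m)
  ae <- abs(edge_i)
  acc <- tapply(c(ae, ae), c(pr, pc), sum)
  flow[as.integer(names(acc))] <- acc
  extraction <- numeric(m)
  extraction[gr] <- -as.numeric(lap[gr, , drop = FALSE] %*% v)
  inj <- numeric(m); inj[sub[src]] <- injection
  node_current <- 0.5 * (flow + abs(inj) + abs(extraction))
  out <- matrix(0, d[1], d[2])
  cells <- which(pos)[keep]
  out[cells] <- node_current
  list(current = out, injected = injection, grounded = sum(extraction[gr]))
}

#' Omnidirectional cumulative current map
#'
#' For each source location visited at the configured stride, solves a
#' circular window of the configured radius with that source injecting
#' current against the other sources inside the window as grounds, and
#' accumulates the per-cell current across windows. This produces the
#' cumulative omnidirectional connectivity surface: high current marks
#' cells many random walks between habitat sources must pass through.
#'
#' @param conductance A [raster_grid()] of conductances (e.g. percent
#'   cover); nodata is treated as zero conductance.
#' @param config A [window_config()].
#' @param sources For `cover_based` mode an optional logical matrix of
#'   source cells (defaults to `conductance >= source_threshold`); for
#'   `point_based` mode a [point_layer()].
#' @return A `current_map`: list with `values` (a [raster_grid()], `>= 0`,
#'   zero wherever conductance is zero) and `provenance` (config plus
#'   conductance description).
#' @export
omnidirectional_current <- function(conductance, config = window_config(),
                                    sources = NULL) {
  stopifnot(is_raster_grid(conductance), inherits(config, "window_config"))
  cond <- conductance$values
  cond[conductance$nodata_mask | is.na(cond)] <- 0
  cond[cond < 0] <- 0
  d <- dim(cond)
  cs <- conductance$cell_size
  rad_cells <- config$radius / cs

  if (config$source_mode == "cover_based") {
    src_mask <- if (is.null(sources)) cond >= config$source_threshold else sources
    stopifnot(is.logical(src_mask), identical(dim(src_mask), d))
    src_mask <- src_mask & cond > 0
    src_cells <- which(src_mask)
    rc <- arrayInd(src_cells, d)
    visit <- src_cells[(rc[, 1L] - 1L) %% config$stride == 0L &
                         (rc[, 2L] - 1L) %% config$stride == 0L]
    weights <- rep(1, length(visit))
  } else {
    stopifnot(inherits(sources, "point_layer"))
    rcix <- points_to_cells(sources, conductance)
    inside <- !is.na(rcix)
    src_cells <- unique(rcix[inside])
    src_mask <- matrix(FALSE, d[1], d[2]); src_mask[src_cells] <- TRUE
    visit <- src_cells
    weights <- if (config$equal_source_strength || is.null(sources$weight))
      rep(1, length(visit)) else sources$weight[inside][match(visit, rcix[inside])]
  }
  acc <- matrix(0, d[1], d[2])
  if (length(visit) == 0L) {
    warning("no sources: returning an all-zero current map")
  } else {
    for (k in seq_along(visit)) {
      sc <- visit[k]
      rc0 <- arrayInd(sc, d)
      r0 <- rc0[1L]; c0 <- rc0[2L]
      rr <- max(1L, r0 - floor(rad_cells)):min(d[1], r0 + floor(rad_cells))
      cc <- max(1L, c0 - floor(rad_cells)):min(d[2], c0 + floor(rad_cells))
      patch <- cond[rr, cc, drop = FALSE]
      dist2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      patch[dist2 > rad_cells^2] <- 0     # circular window, truncated at edges
      psrc_mask <- src_mask[rr, cc, drop = FALSE] & dist2 <= rad_cells^2
      local_src <- (match(c0, cc) - 1L) * length(rr) + match(r0, rr)
      grounds <- setdiff(which(psrc_mask), local_src)
      if (length(grounds) == 0L) next
      sol <- solve_window(patch, local_src, grounds, injection = weights[k])
      acc[rr, cc] <- acc[rr, cc] + sol$current
    }
  }
  vals <- raster_grid(acc, cs, conductance$origin,
                      semantic_tag = "cumulative current")
  structure(list(values = vals,
                 provenance = list(config = config,
                                   conductance = conductance$semantic_tag)),
            class = "current_map")
}

#' @export
print.current_map <- function(x, ...) {
  cat("<current_map> ", x$provenance$config$source_mode, " sources, radius ",
      x$provenance$config$radius, " m\n", sep = "")
  print(x$values)
  invisible(x)
}

# nearest-containing-cell index for each point (NA if outside the grid)
points_to_cells <- function(points, template) {
  d <- dim(template$values); cs <- template$cell_size
  col <- floor((points$points[, 1L] - template$origin[1]) / cs) + 1L
  row <- floor((template$origin[2] - points$points[, 2L]) / cs) + 1L
  ok <- row >= 1L & row <= d[1] & col >= 1L & col <= d[2]
  ifelse(ok, (col - 1L) * d[1] + row, NA_integer_)
}

#' Lek-to-lek connectivity surface
#'
#' Point-based omnidirectional current with lek locations as sources
#' (every other lek in the window grounds the injection), followed by a
#' focal mean over the window radius, so the final surface represents mean
#' current over the moving window.
#'
#' @param conductance A [raster_grid()] (e.g. percent cover).
#' @param leks A [point_layer()] with at least two leks.
#' @param config A [window_config()]; its `source_mode` is forced to
#'   `point_based`.
#' @return A `current_map`.
#' @export
lek_connectivity <- function(conductance, leks, config = window_config()) {
  stopifnot(inherits(leks, "point_layer"))
  if (nrow(leks$points) < 2L)
    stop("lek connectivity needs at least 2 leks (pairwise sources)", call. = FALSE)
  config$source_mode <- "point_based"
  cm <- omnidirectional_current(conductance, config, sources = leks)
  sm <- focal_mean(cm$values, config$radius)
  v <- sm$values
  v[is.na(v)] <- 0
  cm$values <- raster_grid(v, sm$cell_size, sm$origin,
                           semantic_tag = "lek connectivity (window mean current)")
  cm$provenance$smoothed <- TRUE
  cm
}

#' Zero a current map inside lek protection buffers
#'
#' Cells within `radius` of any lek are set to exactly zero (such cells are
#' assumed already protected and are removed from prioritization).
#'
#' @param current A `current_map`.
#' @param leks A [point_layer()].
#' @param radius Buffer radius in map units (default 1 km).
#' @return The masked `current_map`.
#' @export
mask_lek_buffers <- function(current, leks, radius = 1000) {
  stopifnot(inherits(current, "current_map"))
  buf <- buffer_mask(leks, radius, current$values)
  v <- current$values$values
  v[buf] <- 0
  current$values <- raster_grid(v, current$values$cell_size,
                                current$values$origin,
                                current$values$nodata_mask,
                                current$values$semantic_tag)
  current$provenance$lek_buffer_radius <- radius
  current
}

#' Connectivity change (loss-only) layer
#'
#' `now - then`, with gains (positive change, often an artefact of current
#' redirection rather than real improvement) clamped to zero, so the output
#' reflects only predicted loss and is `<= 0` everywhere. The two maps must
#' come from identically configured runs.
#'
#' @param current_now,current_then `current_map`s from runs with identical
#'   configuration.
#' @return A [raster_grid()] of non-positive loss values.
#' @export
connectivity_change <- function(current_now, current_then) {
  stopifnot(inherits(current_now, "current_map"),
            inherits(current_then, "current_map"))
  cfg_n <- current_now$provenance$config
  cfg_t <- current_then$provenance$config
  if (!identical(unclass(cfg_n), unclass(cfg_t)))
    stop("connectivity change requires identically configured runs", call. = FALSE)
  check_aligned(current_now$values, current_then$values)
  delta <- current_now$values$values - current_then$values$values
  delta[delta > 0] <- 0
  raster_grid(delta, current_now$values$cell_size, current_now$values$origin,
              semantic_tag = "connectivity loss")
}
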