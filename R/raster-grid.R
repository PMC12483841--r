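#' Raster grid container
#'
#' A `raster_grid` is a single-band, north-up raster on a square-cell grid:
#' a numeric matrix (`values`, row 1 = northernmost row), a logical
#' `nodata_mask` of the same shape, the cell size in map units (metres), and
#' the map coordinates of the top-left (north-west) corner of the grid
#' (`origin`). All grids taking part in one analysis must share shape, cell
#' size, and origin; [check_aligned()] enforces this before any multi-layer
#' operation.
#'
#' @param values Numeric matrix, row-major, north-up (row 1 at the top).
#' @param cell_size Cell side length in map units (metres); must be positive.
#' @param origin Length-2 numeric, map coordinates `(x, y)` of the top-left
#'   corner of cell `[1, 1]`.
#' @param nodata_mask Logical matrix, same shape as `values`; `TRUE` marks
#'   cells with no data. Defaults to `is.na(values)`.
#' @param semantic_tag Free-text description of what the values mean
#'   (e.g. `"percent cover"`, `"density"`).
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        nodata_mask = NULL, semantic_tag = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("`origin` must be two finite map coordinates (x, y)", call. = FALSE)
  }
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values))) {
    stop("`nodata_mask` must be a logical matrix with the shape of `values`",
         call. = FALSE)
  }
  nodata_mask <- nodata_mask | is.na(values)
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata_mask = nodata_mask,
         semantic_tag = as.character(semantic_tag)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g)%s\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$semantic_tag)) paste0(" [", x$semantic_tag, "]") else ""))
  cat(sprintf("  nodata: %d cells; range of data: %s\n", sum(x$nodata_mask),
              if (all(x$nodata_mask)) "none" else
                paste(signif(range(x$values, na.rm = TRUE), 6), collapse = " .. ")))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Check that rasters share one grid
#'
#' All grids in one analysis must share shape, cell size, and origin.
#' Mismatches are errors, not repaired: the toolkit enforces alignment
#' rather than resampling.
#'
#' @param ... Two or more `raster_grid` objects.
#' @return Invisibly `TRUE`; errors on any mismatch, naming the defect.
#' @export
check_aligned <- function(...) {
  grids <- list(...)
  grids <- grids[vapply(grids, is_raster_grid, logical(1))]
  if (length(grids) < 2L) return(invisible(TRUE))
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(dim(g$values), dim(ref$values)))
      stop("raster alignment error: shapes differ (",
           paste(dim(ref$values), collapse = "x"), " vs ",
           paste(dim(g$values), collapse = "x"), ")", call. = FALSE)
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size)))
      stop("raster alignment error: cell sizes differ (", ref$cell_size,
           " vs ", g$cell_size, ")", call. = FALSE)
    if (!isTRUE(all.equal(g$origin, ref$origin)))
      stop("raster alignment error: origins differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param grid A `raster_grid`.
#' @return A list with matrices `x` and `y` giving the map coordinates of
#'   every cell center (same shape as the grid).
#' @export
cell_centers <- function(grid) {
  d <- dim(grid$values)
  cs <- grid$cell_size
  x <- grid$origin[1] + (seq_len(d[2]) - 0.5) * cs
  y <- grid$origin[2] - (seq_len(d[1]) - 0.5) * cs
  list(x = matrix(x, d[1], d[2], byrow = TRUE),
       y = matrix(y, d[1], d[2], byrow = FALSE))
}

#' Read a raster from an ESRI ASCII grid file
#'
#' The native raster format of the toolkit is the ESRI ASCII grid (`.asc`):
#' a single-band, plain-text, georeferenced raster with a declared nodata
#' value. `read_raster()`/[write_raster()] round-trip values, mask, cell
#' size, and origin bit-exactly (values are written with 17 significant
#' digits).
#'
#' @param path Path to a `.asc` file.
#' @param semantic_tag Optional tag attached to the returned grid.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, semantic_tag = "") {
  if (!file.exists(path)) stop("unreadable raster file: ", path, call. = FALSE)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0L) {
    stop("raster file ", path, " lacks georeferencing header field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("raster file ", path, " is malformed: expected ", nr * nc,
         " cell values, found ", length(vals),
         " (multi-band or truncated input?)", call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- matrix(FALSE, nr, nc)
  if (!is.null(hdr$nodata_value)) mask <- m == hdr$nodata_value
  m[mask] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  raster_grid(m, cell_size = hdr$cellsize, origin = origin,
              nodata_mask = mask, semantic_tag = semantic_tag)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param grid A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata_value Value standing in for nodata cells in the file.
#' @return Invisibly `path`.
#' @rdname read_raster
#' @export
write_raster <- function(grid, path, nodata_value = -9999) {
  stopifnot(is_raster_grid(grid))
  d <- dim(grid$values)
  vals <- grid$values
  if (any(!grid$nodata_mask & vals == nodata_value, na.rm = TRUE)) {
    stop("nodata_value ", nodata_value, " collides with a data value; choose another",
         call. = FALSE)
  }
  vals[grid$nodata_mask] <- nodata_value
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    paste("xllcorner", sprintf("%.17g", grid$origin[1])),
    paste("yllcorner", sprintf("%.17g", grid$origin[2] - d[1] * grid$cell_size)),
    paste("cellsize", sprintf("%.17g", grid$cell_size)),
    paste("NODATA_value", sprintf("%.17g", nodata_value))
  ), con)
  writeLines(apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

# ---- vector layers ---------------------------------------------------------

#' Polygon layer
#'
#' A set of simple (non-self-intersecting) polygons with unique string ids,
#' tagged by their role in the workflow: `cluster_zone` for management
#' cluster polygons used in zonal imputation, `conservation_area` for
#' designated core/growth-opportunity areas used as planning-unit masks.
#'
#' @param polygons Named list of two-column matrices (x, y vertex
#'   coordinates, open or closed rings both accepted).
#' @param role_tag `"cluster_zone"` or `"conservation_area"`.
#' @return An object of class `polygon_layer`.
#' @export
polygon_layer <- function(polygons, role_tag = c("cluster_zone", "conservation_area")) {
  role_tag <- match.arg(role_tag)
  if (is.null(names(polygons)) || anyDuplicated(names(polygons)) ||
      any(!nzchar(names(polygons)))) {
    stop("polygons must carry unique, non-empty string ids", call. = FALSE)
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon needs >= 3 (x, y) vertices", call. = FALSE)
    # drop an explicit closing vertex; rings are stored open
    if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  structure(list(polygons = polygons, role_tag = role_tag),
            class = "polygon_layer")
}

#' Point layer
#'
#' Point locations in map coordinates with optional strictly positive
#' per-point weights (e.g. lek locations with source strengths).
#'
#' @param xy Two-column matrix of map coordinates.
#' @param weight Optional numeric vector of strictly positive weights.
#' @return An object of class `point_layer`.
#' @export
point_layer <- function(xy, weight = NULL) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("`xy` must have two columns (x, y)", call. = FALSE)
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  if (!is.null(weight)) {
    if (length(weight) != nrow(xy) || any(!is.finite(weight)) || any(weight <= 0))
      stop("weights must be finite, strictly positive, one per point", call. = FALSE)
    weight <- as.numeric(weight)
  }
  structure(list(points = xy, weight = weight), class = "point_layer")
}

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("<polygon_layer> %d polygon(s), role '%s'\n",
              length(x$polygons), x$role_tag))
  invisible(x)
}

#' @export
print.point_layer <- function(x, ...) {
  cat(sprintf("<point_layer> %d point(s)%s\n", nrow(x$points),
              if (is.null(x$weight)) "" else ", weighted"))
  invisible(x)
}

#' Read and write vector layers as GeoJSON
#'
#' Polygon layers are stored as a GeoJSON `FeatureCollection` of `Polygon`
#' features with `id` and `role` properties; point layers as `Point`
#' features with an optional `weight` property.
#'
#' @param layer A [polygon_layer()] or [point_layer()].
#' @param path File path (`.geojson`).
#' @return `write_vector()` returns `path` invisibly; `read_vector()` the
#'   reconstructed layer.
#' @export
write_vector <- function(layer, path) {
  if (inherits(layer, "polygon_layer")) {
    feats <- mapply(function(id, p) {
      ring <- rbind(p, p[1L, , drop = FALSE])
      list(type = "Feature",
           properties = list(id = id, role = layer$role_tag),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) as.numeric(ring[i, ])))))
    }, names(layer$polygons), layer$polygons, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else if (inherits(layer, "point_layer")) {
    feats <- lapply(seq_len(nrow(layer$points)), function(i) {
      props <- if (is.null(layer$weight)) structure(list(), names = character()) else
        list(weight = layer$weight[i])
      list(type = "Feature", properties = props,
           geometry = list(type = "Point",
                           coordinates = as.numeric(layer$points[i, ])))
    })
  } else stop("unsupported layer type", call. = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  types <- vapply(gj$features, function(f) f$geometry$type, character(1))
  if (all(types == "Polygon")) {
    polys <- lapply(gj$features, function(f) {
      ring <- f$geometry$coordinates[[1L]]
      do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    })
    names(polys) <- vapply(gj$features, function(f) as.character(f$properties$id),
                           character(1))
    role <- gj$features[[1L]]$properties$role
    polygon_layer(polys, role_tag = if (is.null(role)) "cluster_zone" else role)
  } else if (all(types == "Point")) {
    xy <- do.call(rbind, lapply(gj$features, function(f)
      as.numeric(unlist(f$geometry$coordinates))))
    w <- vapply(gj$features, function(f) {
      if (is.null(f$properties$weight)) NA_real_ else as.numeric(f$properties$weight)
    }, numeric(1))
    point_layer(xy, weight = if (all(is.na(w))) NULL else w)
  } else stop("mixed or unsupported geometry types in ", path, call. = FALSE)
}
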