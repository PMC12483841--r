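#' @title Seeded synthetic landscapes
#' @description Generators for synthetic sagebrush-like landscapes with the
#'   statistical structure the prioritization workflow assumes: spatially
#'   autocorrelated percent-cover time series with patchy degradation,
#'   species feature layers with contrasting distribution shapes
#'   (right-skewed density-like vs. left-skewed bounded-probability-like),
#'   coefficient-of-variation layers, management cluster zones, designated
#'   conservation areas, and lek points placed preferentially in high-cover
#'   cells. Every generator is bit-reproducible from `(seed, config)`.
#' @name synth
NULL

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage sub-seeds below 2^31.
stage_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Smoothed standard-normal random field.
random_field <- function(shape, scale) {
  z <- smooth_gaussian(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]), scale)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic percent-cover time series
#'
#' Produces four aligned cover grids: `historic` (a smoothed positive random
#' field), `potential` (historic plus a small positive offset, the cover
#' expected under undisturbed conditions), `current` (historic minus patchy
#' losses over about `degrade_fraction` of the cells at a depth of about
#' `degrade_depth` percentage points), and `future` (current attenuated by a
#' smooth spatial trend, so that cover thresholds such as 5/10/15 percent
#' partition the map nontrivially).
#'
#' @param seed Integer seed; the series is bit-reproducible from
#'   `(seed, arguments)`.
#' @param shape `c(nrow, ncol)` in cells; at least 8 x 8.
#' @param cell_size Cell side in metres (default 30).
#' @param autocorr_scale Gaussian smoothing scale of the random fields, in
#'   cells.
#' @param degrade_fraction Fraction of cells receiving cover loss, in
#'   `[0, 1]`.
#' @param degrade_depth Typical loss depth in cover percentage points.
#' @param origin Map coordinates of the top-left corner.
#' @return Named list of four [raster_grid()]s
#'   (`historic`, `potential`, `current`, `future`), percent cover in
#'   `[0, 100]`.
#' @export
generate_cover_series <- function(seed, shape = c(100L, 100L), cell_size = 30,
                                  autocorr_scale = 4, degrade_fraction = 0.2,
                                  degrade_depth = 15, origin = c(0, shape[1] * cell_size)) {
  if (any(shape < 8L)) stop("degenerate shape: need at least 8 x 8 cells", call. = FALSE)
  if (degrade_fraction < 0 || degrade_fraction > 1)
    stop("`degrade_fraction` must lie in [0, 1]", call. = FALSE)
  ss <- stage_seeds(seed, 4L)
  clamp <- function(m) matrix(pmin(100, pmax(0, m)), shape[1], shape[2])

  historic <- with_seed(ss[1L], clamp(30 + 15 * random_field(shape, autocorr_scale)))
  potential <- with_seed(ss[2L], {
    offset <- 3 + 5 * stats::pnorm(random_field(shape, autocorr_scale * 2))
    clamp(historic + offset)
  })
  current <- if (degrade_fraction == 0) historic else with_seed(ss[3L], {
    d <- random_field(shape, autocorr_scale * 1.5)
    thr <- stats::quantile(d, 1 - degrade_fraction)
    intensity <- pmax(0, (d - thr) / max(max(d) - thr, .Machine$double.eps))
    loss <- (d > thr) * degrade_depth * (0.6 + 0.8 * intensity)
    clamp(historic - loss)
  })
  future <- with_seed(ss[4L], {
    grad <- matrix(seq(0, 1, length.out = shape[2]), shape[1], shape[2], byrow = TRUE)
    atten <- 0.15 + 0.75 * (0.5 * grad +
                              0.5 * stats::pnorm(random_field(shape, autocorr_scale * 2)))
    clamp(current * atten)
  })
  g <- function(m, tag) raster_grid(m, cell_size, origin, semantic_tag = tag)
  list(historic = g(historic, "percent cover (historic)"),
       potential = g(potential, "percent cover (ecological potential)"),
       current = g(current, "percent cover (current)"),
       future = g(future, "percent cover (projected future)"))
}

#' Species specification for the feature generator
#'
#' @param name Species/layer name.
#' @param family `"skewed_density"` (non-negative, right-skewed, e.g. bird
#'   density) or `"bounded_probability"` (in `[0, 1]`, left-skewed, e.g.
#'   persistence or presence probability).
#' @param response Response of habitat value to percent cover:
#'   `"increasing"`, `"decreasing"` (an open-shrubland analogue that avoids
#'   dense cover), or `"hump"` (peaked at intermediate cover).
#' @param has_cv Whether a coefficient-of-variation layer accompanies the
#'   feature (one default species lacks it, emulating a layer with no
#'   published uncertainty surface).
#' @param cv_range Range of the generated CV values.
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, family = c("skewed_density", "bounded_probability"),
                         response = c("increasing", "decreasing", "hump"),
                         has_cv = TRUE, cv_range = c(0.1, 0.5)) {
  family <- match.arg(family)
  response <- match.arg(response)
  structure(list(name = name, family = family, response = response,
                 has_cv = has_cv, cv_range = cv_range), class = "species_spec")
}

#' Default focal-species set
#'
#' Four density-like songbird analogues (one responding negatively to dense
#' cover, as sagebrush sparrows do), a left-skewed persistence-probability
#' layer, and a presence-probability layer that carries no uncertainty
#' surface and is therefore excluded from the uncertainty sweep.
#'
#' @return List of [species_spec()]s.
#' @export
default_species_specs <- function() {
  list(
    species_spec("brewers_sparrow_density", "skewed_density", "increasing"),
    species_spec("sagebrush_sparrow_density", "skewed_density", "decreasing"),
    species_spec("sage_thrasher_density", "skewed_density", "increasing"),
    species_spec("towhee_density", "skewed_density", "hump"),
    species_spec("grouse_persistence_prob", "bounded_probability", "increasing"),
    species_spec("rabbit_presence_prob", "bounded_probability", "hump",
                 has_cv = FALSE)
  )
}

cover_response <- function(cover_pct, response) {
  c01 <- cover_pct / 100
  switch(response,
         increasing = c01,
         decreasing = 1 - c01,
         hump = exp(-((cover_pct - 25)^2) / (2 * 10^2)),
         stop("unknown response keyword: ", response, call. = FALSE))
}

#' Generate species feature layers (and CV layers) from cover
#'
#' Density-family layers are gamma draws whose mean follows the declared
#' cover response (non-negative and right-skewed); probability-family layers
#' are beta draws with mass pushed toward 1 (bounded in `[0, 1]` and
#' left-skewed overall). CV layers are smooth positive fields within each
#' species' declared range.
#'
#' @param seed Integer seed.
#' @param cover_grids Output of [generate_cover_series()] (the `current`
#'   grid drives the response).
#' @param species_specs List of [species_spec()]s.
#' @return List with named lists `features` and `cv` of [raster_grid()]s
#'   (`cv` entries are `NULL` where `has_cv` is `FALSE`).
#' @export
generate_features <- function(seed, cover_grids, species_specs = default_species_specs()) {
  cur <- cover_grids$current
  shape <- dim(cur$values)
  n <- prod(shape)
  ss <- stage_seeds(seed, 2L * length(species_specs))
  features <- list(); cvs <- list()
  for (i in seq_along(species_specs)) {
    sp <- species_specs[[i]]
    r <- cover_response(cur$values, sp$response)
    vals <- with_seed(ss[2L * i - 1L], {
      if (sp$family == "skewed_density") {
        mu <- 0.3 + 4 * r
        matrix(stats::rgamma(n, shape = 2, scale = mu / 2), shape[1], shape[2])
      } else {
        a <- 1.5 + 6 * r
        matrix(stats::rbeta(n, a, 1.3), shape[1], shape[2])
      }
    })
    features[[sp$name]] <- raster_grid(vals, cur$cell_size, cur$origin,
                                       semantic_tag = paste(sp$name, "(synthetic)"))
    cvs[[sp$name]] <- if (isTRUE(sp$has_cv)) with_seed(ss[2L * i], {
      z <- stats::pnorm(random_field(shape, 6))
      cv <- sp$cv_range[1] + diff(sp$cv_range) * z
      raster_grid(cv, cur$cell_size, cur$origin,
                  semantic_tag = paste(sp$name, "CV (synthetic)"))
    }) else NULL
  }
  list(features = features, cv = cvs)
}

#' Generate cluster zones, conservation areas, and lek points
#'
#' Cluster zones are rectangles that tile the grid (boundaries snapped to
#' cell edges so no cell center is ambiguous); conservation areas are a
#' small set of rectangles covering roughly `conservation_fraction` of the
#' grid; leks are placed preferentially in high-cover cells (sampling
#' probability proportional to squared cover), so their mean underlying
#' cover exceeds the grid mean.
#'
#' @param seed Integer seed.
#' @param template A [raster_grid()] supplying grid geometry.
#' @param cover Cover grid steering lek placement (defaults to `template`).
#' @param n_clusters Number of cluster zones (>= 1).
#' @param n_leks Number of lek points.
#' @param conservation_fraction Approximate fraction of the grid covered by
#'   conservation areas.
#' @return List with `cluster_zones` and `conservation_areas`
#'   ([polygon_layer()]s) and `leks` (a [point_layer()]).
#' @export
generate_zones_and_leks <- function(seed, template, cover = template,
                                    n_clusters = 4L, n_leks = 12L,
                                    conservation_fraction = 0.35) {
  stopifnot(n_clusters >= 1L)
  d <- dim(template$values); cs <- template$cell_size
  x0 <- template$origin[1]; y0 <- template$origin[2]
  rect <- function(c0, c1, r0, r1) {
    # cell-index bounds [c0, c1) x [r0, r1) -> map-coordinate rectangle
    cbind(x = x0 + cs * c(c0, c1, c1, c0), y = y0 - cs * c(r0, r0, r1, r1))
  }
  nr_t <- max(vapply(seq_len(floor(sqrt(n_clusters))), function(k)
    if (n_clusters %% k == 0L) k else 0L, integer(1)))
  nc_t <- n_clusters %/% nr_t
  rb <- round(seq(0, d[1], length.out = nr_t + 1L))
  cb <- round(seq(0, d[2], length.out = nc_t + 1L))
  polys <- list()
  for (i in seq_len(nr_t)) for (j in seq_len(nc_t)) {
    polys[[sprintf("cluster_%02d", (i - 1L) * nc_t + j)]] <-
      rect(cb[j], cb[j + 1L], rb[i], rb[i + 1L])
  }
  cluster_zones <- polygon_layer(polys, "cluster_zone")

  ss <- stage_seeds(seed, 2L)
  conservation_areas <- with_seed(ss[1L], {
    covered <- matrix(FALSE, d[1], d[2])
    boxes <- list(); k <- 0L
    while (mean(covered) < conservation_fraction && k < 8L) {
      k <- k + 1L
      h <- sample(seq(round(d[1] * 0.25), round(d[1] * 0.5)), 1L)
      w <- sample(seq(round(d[2] * 0.25), round(d[2] * 0.5)), 1L)
      r0 <- sample.int(d[1] - h + 1L, 1L) - 1L
      c0 <- sample.int(d[2] - w + 1L, 1L) - 1L
      covered[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
      boxes[[sprintf("csa_%02d", k)]] <- rect(c0, c0 + w, r0, r0 + h)
    }
    polygon_layer(boxes, "conservation_area")
  })

  leks <- with_seed(ss[2L], {
    prob <- as.vector(pmax(cover$values, 0))^2 + 1e-9
    idx <- sample.int(length(prob), n_leks, prob = prob)
    rc <- arrayInd(idx, d)
    point_layer(cbind(x0 + cs * (rc[, 2L] - 0.5), y0 - cs * (rc[, 1L] - 0.5)))
  })
  list(cluster_zones = cluster_zones, conservation_areas = conservation_areas,
       leks = leks)
}

#' Generate a complete synthetic landscape bundle
#'
#' The one-call generator for a study-ready input stack: cover time series,
#' species feature and CV layers, a cluster-level abundance layer (constant
#' within each management cluster, as lek-trend estimates aggregated to
#' cluster polygons are), spring-soil-moisture mean and CV surfaces, cluster
#' zones, conservation areas, and lek points. Bit-reproducible from
#' `(seed, config)`.
#'
#' @param seed Integer seed.
#' @param shape Grid shape in cells.
#' @param cell_size Cell side in metres.
#' @param autocorr_scale,degrade_fraction,degrade_depth Passed to
#'   [generate_cover_series()].
#' @param species_specs Passed to [generate_features()].
#' @param n_clusters,n_leks,conservation_fraction Passed to
#'   [generate_zones_and_leks()].
#' @return A `landscape_bundle` list.
#' @export
synth_landscape <- function(seed = 1L, shape = c(100L, 100L), cell_size = 30,
                            autocorr_scale = 4, degrade_fraction = 0.2,
                            degrade_depth = 15,
                            species_specs = default_species_specs(),
                            n_clusters = 4L, n_leks = 12L,
                            conservation_fraction = 0.35) {
  config <- list(shape = as.integer(shape), cell_size = cell_size,
                 autocorr_scale = autocorr_scale,
                 degrade_fraction = degrade_fraction,
                 degrade_depth = degrade_depth,
                 n_clusters = as.integer(n_clusters), n_leks = as.integer(n_leks),
                 conservation_fraction = conservation_fraction)
  ss <- stage_seeds(seed, 5L)
  cover <- generate_cover_series(ss[1L], shape, cell_size, autocorr_scale,
                                 degrade_fraction, degrade_depth)
  feats <- generate_features(ss[2L], cover, species_specs)
  zl <- generate_zones_and_leks(ss[3L], cover$current, cover$current,
                                n_clusters, n_leks, conservation_fraction)

  soil <- with_seed(ss[4L], {
    mean_v <- 40 + 25 * stats::pnorm(random_field(shape, autocorr_scale * 2))
    sd_v <- mean_v * (0.1 + 0.3 * stats::pnorm(random_field(shape, autocorr_scale * 2)))
    m <- raster_grid(mean_v, cell_size, cover$current$origin,
                     semantic_tag = "spring soil moisture (mean)")
    s <- raster_grid(sd_v, cell_size, cover$current$origin,
                     semantic_tag = "spring soil moisture (sd)")
    list(mean = m, cv = coefficient_of_variation(m, s))
  })

  abundance <- with_seed(ss[5L], {
    zones <- zl$cluster_zones$polygons
    ab <- stats::rlnorm(length(zones), meanlog = log(50), sdlog = 0.6)
    cv <- stats::runif(length(zones), 0.15, 0.45)
    vals <- matrix(NA_real_, shape[1], shape[2])
    cvv <- matrix(NA_real_, shape[1], shape[2])
    for (i in seq_along(zones)) {
      sel <- cells_in_polygon(zones[[i]], cover$current)
      vals[sel] <- ab[i]; cvv[sel] <- cv[i]
    }
    list(values = raster_grid(vals, cell_size, cover$current$origin,
                              semantic_tag = "grouse lek abundance (cluster mean)"),
         cv = raster_grid(cvv, cell_size, cover$current$origin,
                          semantic_tag = "grouse lek abundance CV"))
  })
  feats$features$grouse_abundance <- abundance$values
  feats$cv$grouse_abundance <- abundance$cv

  structure(
    list(seed = as.integer(seed), config = config,
         historic_cover = cover$historic, potential_cover = cover$potential,
         current_cover = cover$current, future_cover = cover$future,
         features = feats$features, feature_cv = feats$cv,
         soil_moisture = soil$mean, soil_moisture_cv = soil$cv,
         cluster_zones = zl$cluster_zones,
         conservation_areas = zl$conservation_areas, leks = zl$leks),
    class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> seed %d, %d x %d cells @ %g m\n", x$seed,
              x$config$shape[1], x$config$shape[2], x$config$cell_size))
  cat("  features:", paste(names(x$features), collapse = ", "), "\n")
  cat(sprintf("  %d cluster zone(s), %d conservation area(s), %d lek(s)\n",
              length(x$cluster_zones$polygons),
              length(x$conservation_areas$polygons), nrow(x$leks$points)))
  invisible(x)
}

#' Write a landscape bundle to a directory
#'
#' Rasters go out as ESRI ASCII grids, vector layers as GeoJSON, and the
#' generator configuration (including the seed) as JSON.
#'
#' @param bundle A `landscape_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(g, nm) if (!is.null(g)) write_raster(g, file.path(dir, paste0(nm, ".asc")))
  w(bundle$historic_cover, "historic_cover")
  w(bundle$potential_cover, "potential_cover")
  w(bundle$current_cover, "current_cover")
  w(bundle$future_cover, "future_cover")
  w(bundle$soil_moisture, "soil_moisture")
  w(bundle$soil_moisture_cv, "soil_moisture_cv")
  for (nm in names(bundle$features)) {
    w(bundle$features[[nm]], paste0("feature_", nm))
    w(bundle$feature_cv[[nm]], paste0("feature_cv_", nm))
  }
  write_vector(bundle$cluster_zones, file.path(dir, "cluster_zones.geojson"))
  write_vector(bundle$conservation_areas, file.path(dir, "conservation_areas.geojson"))
  write_vector(bundle$leks, file.path(dir, "leks.geojson"))
  jsonlite::write_json(c(list(seed = bundle$seed), bundle$config),
                       file.path(dir, "bundle_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a landscape bundle from a directory written by [write_bundle()]
#'
#' @param dir Directory holding the bundle layers.
#' @return A `landscape_bundle`.
#' @export
read_bundle <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "bundle_config.json"))
  rd <- function(nm, tag = nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    if (file.exists(p)) read_raster(p, semantic_tag = tag) else NULL
  }
  feat_files <- list.files(dir, pattern = "^feature_.*\\.asc$")
  feat_files <- feat_files[!grepl("^feature_cv_", feat_files)]
  feat_names <- sub("\\.asc$", "", sub("^feature_", "", feat_files))
  features <- lapply(feat_names, function(nm) rd(paste0("feature_", nm), nm))
  names(features) <- feat_names
  feature_cv <- lapply(feat_names, function(nm) rd(paste0("feature_cv_", nm)))
  names(feature_cv) <- feat_names
  structure(
    list(seed = as.integer(cfg$seed), config = cfg[setdiff(names(cfg), "seed")],
         historic_cover = rd("historic_cover", "percent cover (historic)"),
         potential_cover = rd("potential_cover", "percent cover (ecological potential)"),
         current_cover = rd("current_cover", "percent cover (current)"),
         future_cover = rd("future_cover", "percent cover (projected future)"),
         features = features, feature_cv = feature_cv,
         soil_moisture = rd("soil_moisture", "spring soil moisture (mean)"),
         soil_moisture_cv = rd("soil_moisture_cv"),
         cluster_zones = read_vector(file.path(dir, "cluster_zones.geojson")),
         conservation_areas = read_vector(file.path(dir, "conservation_areas.geojson")),
         leks = read_vector(file.path(dir, "leks.geojson"))),
    class = "landscape_bundle")
}
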