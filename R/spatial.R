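#' Whale-count-weighted mean location
#'
#' Arithmetic mean of latitude and longitude weighted by each observation
#' unit's whale-count contribution, tracking the centre of foraging effort.
#'
#' @param observations tibble with `lat`, `lon` and a weight column
#'   `count_contribution` (missing weights default to 1).
#' @return one-row tibble `lat`, `lon`, `total_weight`.
#' @export
weighted_mean_location <- function(observations) {
  stopifnot(all(c("lat", "lon") %in% names(observations)), nrow(observations) >= 1)
  w <- observations$count_contribution
  if (is.null(w)) w <- rep(1, nrow(observations))
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  tibble::tibble(
    lat = sum(observations$lat * w) / sum(w),
    lon = sum(observations$lon * w) / sum(w),
    total_weight = sum(w)
  )
}

#' Monthly heat grid of whale locations
#'
#' Bins whale counts into half-open grid cells `[lo, hi)` in both axes,
#' anchored at the bounding-box corner. Cell counts are conserved: their sum
#' equals the total whale count for the month. Observations falling outside
#' a supplied bounding box are retained in an overflow cell and flagged.
#'
#' @param observations tibble with `lat`, `lon`, `count_contribution`, and a
#'   `date` or `month` column.
#' @param cell_size cell edge in decimal degrees (> 0).
#' @param month calendar month (1-12) to select; NULL uses all rows.
#' @param bbox optional `c(lat_min, lat_max, lon_min, lon_max)`; defaults to
#'   the observation bounding box.
#' @return list of class `gw_heatgrid`: `cells` (tibble `lat_lo`, `lon_lo`,
#'   `lat_hi`, `lon_hi`, `count`), `overflow` (count outside bbox), `month`,
#'   `cell_size`, `weighted_mean`, `total`.
#' @export
monthly_heat_grid <- function(observations, cell_size, month = NULL, bbox = NULL) {
  stopifnot(cell_size > 0)
  obs <- observations
  if (!is.null(month)) {
    m <- if ("month" %in% names(obs)) obs$month else as.integer(format(obs$date, "%m"))
    obs <- obs[m == month, ]
  }
  if (nrow(obs) == 0) {
    return(structure(
      list(
        cells = tibble::tibble(
          lat_lo = numeric(0), lon_lo = numeric(0),
          lat_hi = numeric(0), lon_hi = numeric(0), count = numeric(0)
        ),
        overflow = 0, month = month, cell_size = cell_size,
        weighted_mean = NULL, total = 0
      ),
      class = "gw_heatgrid"
    ))
  }
  w <- obs$count_contribution
  if (is.null(w)) w <- rep(1, nrow(obs))
  if (is.null(bbox)) {
    bbox <- c(min(obs$lat), max(obs$lat), min(obs$lon), max(obs$lon))
  }
  inside <- obs$lat >= bbox[1] & obs$lat <= bbox[2] + cell_size &
    obs$lon >= bbox[3] & obs$lon <= bbox[4] + cell_size
  overflow <- sum(w[!inside])
  obs_in <- obs[inside, ]
  w_in <- w[inside]
  # half-open cells: a point exactly on a boundary belongs to the higher
  # cell (the epsilon guards against floating-point shortfall at boundaries)
  i_lat <- floor((obs_in$lat - bbox[1]) / cell_size + 1e-9)
  i_lon <- floor((obs_in$lon - bbox[3]) / cell_size + 1e-9)
  cells <- tibble::tibble(
    lat_lo = bbox[1] + i_lat * cell_size,
    lon_lo = bbox[3] + i_lon * cell_size,
    count = w_in
  ) |>
    dplyr::summarise(count = sum(.data$count), .by = c("lat_lo", "lon_lo")) |>
    dplyr::mutate(lat_hi = .data$lat_lo + cell_size, lon_hi = .data$lon_lo + cell_size) |>
    dplyr::select("lat_lo", "lon_lo", "lat_hi", "lon_hi", "count") |>
    dplyr::arrange(.data$lat_lo, .data$lon_lo)
  structure(
    list(
      cells = cells, overflow = overflow, month = month, cell_size = cell_size,
      weighted_mean = weighted_mean_location(obs), total = sum(w)
    ),
    class = "gw_heatgrid"
  )
}

#' @export
print.gw_heatgrid <- function(x, ...) {
  cat(sprintf(
    "<gw_heatgrid> month %s: %d cells, %g whales (cell %g deg)\n",
    ifelse(is.null(x$month), "all", x$month), nrow(x$cells), x$total, x$cell_size
  ))
  invisible(x)
}

#' Write a heat grid as GeoJSON polygons
#'
#' One polygon feature per cell with a `count` property, suitable for any
#' GIS. Coordinates follow the GeoJSON convention (longitude first).
#'
#' @param grid a `gw_heatgrid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
heat_grid_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "gw_heatgrid"))
  features <- lapply(seq_len(nrow(grid$cells)), function(i) {
    c <- grid$cells[i, ]
    list(
      type = "Feature",
      properties = list(count = c$count, month = grid$month),
      geometry = list(
        type = "Polygon",
        coordinates = list(list(
          c(c$lon_lo, c$lat_lo), c(c$lon_hi, c$lat_lo),
          c(c$lon_hi, c$lat_hi), c(c$lon_lo, c$lat_hi),
          c(c$lon_lo, c$lat_lo)
        ))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Social context of a transect: nearest-neighbour distance structure
#'
#' Builds the inter-individual distance matrix between foraging units
#' (individuals, groups and cow-calf pairs each count as one unit; grouped
#' whales share one location) using great-circle (haversine) distances in
#' metres -- at bay scale this matches planar straight-line distance to
#' well under 0.1%. Each unit's nearest-neighbour distance is the smallest
#' off-diagonal entry of its row; the snapshot mean is taken over units and
#' is undefined (NA) when fewer than two units are present, matching the
#' convention that a single whale in the bay has no inter-individual
#' distance. Duplicate coordinates are allowed (distance 0, same patch).
#'
#' @param units tibble of observation units with `lat`, `lon`, `unit_type`,
#'   `count_contribution` (may have zero rows).
#' @return list of class `gw_snapshot`: `n_units`, `n_whales`, `n_groups`,
#'   `n_pairs`, `distance_matrix` (m), `nn_distances`, `mean_nn_distance`.
#' @export
social_context <- function(units) {
  n <- nrow(units)
  if (n == 0) {
    return(structure(
      list(
        n_units = 0L, n_whales = 0L, n_groups = 0L, n_pairs = 0L,
        distance_matrix = matrix(numeric(0), 0, 0),
        nn_distances = numeric(0), mean_nn_distance = NA_real_
      ),
      class = "gw_snapshot"
    ))
  }
  stopifnot(all(c("lat", "lon") %in% names(units)))
  w <- units$count_contribution
  if (is.null(w)) w <- rep(1L, n)
  pts <- cbind(units$lon, units$lat)
  dm <- geosphere::distm(pts, fun = geosphere::distHaversine)
  dimnames(dm) <- NULL
  nn <- if (n >= 2) {
    apply(dm + diag(Inf, n), 1, min)
  } else {
    numeric(0)
  }
  structure(
    list(
      n_units = n,
      n_whales = as.integer(sum(w)),
      n_groups = sum(units$unit_type == "group"),
      n_pairs = sum(units$unit_type == "cow_calf"),
      distance_matrix = dm,
      nn_distances = nn,
      mean_nn_distance = if (n >= 2) mean(nn) else NA_real_
    ),
    class = "gw_snapshot"
  )
}

#' @export
print.gw_snapshot <- function(x, ...) {
  cat(sprintf(
    "<gw_snapshot> %d units (%d whales, %d groups, %d pairs); mean NN %.0f m\n",
    x$n_units, x$n_whales, x$n_groups, x$n_pairs, x$mean_nn_distance
  ))
  invisible(x)
}

#' Monthly weighted mean locations across years
#'
#' @param units observation-unit tibble with `date`, `lat`, `lon`,
#'   `count_contribution`.
#' @return tibble `year`, `month`, `lat`, `lon`, `total_weight`.
#' @export
monthly_weighted_means <- function(units) {
  units |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::group_modify(~ weighted_mean_location(.x)) |>
    dplyr::ungroup()
}
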