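# Small fixtures built in code, shared across test files.

# a fast small-study config: fewer seasons, same per-season density
small_config <- function(seed = 1L, n_years = 8L, ...) {
  simulation_config(seed = seed, n_years = n_years, ...)
}

# transect tibble from explicit counts/days within one season
transects_from_counts <- function(counts, days, year = 2000) {
  open <- as.Date(sprintf("%d-05-24", year))
  tibble::tibble(
    transect_id = sprintf("T%d_%02d", year, seq_along(counts)),
    year = year,
    date = open + days,
    day = as.integer(days),
    completed = TRUE,
    n_whales = as.integer(counts)
  )
}

# brute-force biased autocorrelation, independent of stats::acf
acf_brute <- function(x, k) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  sum(d[1:(n - k)] * d[(k + 1):n]) / sum(d^2)
}

# brute-force PACF: solve the Yule-Walker system on the biased ACF directly
# (last element of R_k^{-1} r_k), independent of the Durbin-Levinson
# recursion used by stats::pacf
pacf_brute <- function(x, max_lag) {
  r <- vapply(seq_len(max_lag), function(k) acf_brute(x, k), numeric(1))
  vapply(seq_len(max_lag), function(k) {
    if (k == 1) return(r[1])
    R <- stats::toeplitz(c(1, r[seq_len(k - 1)]))
    solve(R, r[seq_len(k)])[k]
  }, numeric(1))
}

# observation-unit tibble from explicit coordinates
units_at <- function(lat, lon, type = "individual", weight = 1, year = 2015,
                     date = as.Date(sprintf("%d-07-01", year))) {
  n <- length(lat)
  tibble::tibble(
    transect_id = "T1", year = year, date = date,
    timestamp = as.POSIXct(paste(date, "12:00:00"), tz = "UTC"),
    unit_id = sprintf("U%d", seq_len(n)),
    unit_type = rep_len(type, n),
    group_size = rep_len(as.integer(pmax(weight, 1)), n),
    count_contribution = rep_len(as.integer(weight), n),
    lat = lat, lon = lon
  )
}

# minimal snapshot for acoustic joins
snapshot_at <- function(ts, n_whales, mean_nn = 300, n_pairs = 0,
                        transect_total = NA_real_) {
  structure(
    list(
      timestamp = as.POSIXct(ts, tz = "UTC"),
      n_units = n_whales, n_whales = n_whales, n_groups = 0L,
      n_pairs = n_pairs, distance_matrix = NULL,
      nn_distances = NULL, mean_nn_distance = mean_nn,
      transect_total_whales = transect_total
    ),
    class = "gw_snapshot"
  )
}

calls_at <- function(ts, classes, deployment = "AMAR2015") {
  tibble::tibble(
    timestamp = as.POSIXct(ts, tz = "UTC"),
    call_class = classes,
    deployment_id = deployment
  )
}
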