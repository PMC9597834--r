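#' Summarise one season of transect counts
#'
#' Per-season foraging-intensity statistics: mean and maximum whales per
#' transect (zero-whale transects included in the denominator, since
#' whales/survey is reported over all completed surveys), the peak date
#' expressed as days elapsed from the season opening (ties broken to the
#' earliest date), and the adjusted Fisher-Pearson sample skewness and
#' excess kurtosis of the count series. Skewness locates foraging pressure
#' early or late in the summer; kurtosis describes whether the peak is
#' sharp or sustained. With fewer than three transects, or fewer than two
#' distinct counts, the shape statistics are undefined and returned as NA
#' rather than zero-divided.
#'
#' @param transects a tibble with at least `date` (Date) and `n_whales`
#'   columns, all from one season.
#' @param season_start season opening `"mm-dd"`; day 0 of the peak-date
#'   scale.
#' @return a one-row tibble: `year`, `n_transects`, `mean_whales`,
#'   `max_whales`, `peak_date_days`, `skewness`, `excess_kurtosis`,
#'   `raw_kurtosis`.
#' @export
summarize_year <- function(transects, season_start = "05-24") {
  if (is.null(transects) || nrow(transects) == 0) {
    stop("cannot summarise an empty transect set", call. = FALSE)
  }
  counts <- transects$n_whales
  days <- season_day(transects$date, season_start)
  ord <- order(days)
  counts_o <- counts[ord]
  days_o <- days[ord]
  peak <- days_o[which.max(counts_o)] # which.max returns the first maximum
  shape_ok <- length(counts) >= 3 && length(unique(counts)) >= 2
  tibble::tibble(
    year = as.integer(format(transects$date[1], "%Y")),
    n_transects = length(counts),
    mean_whales = mean(counts),
    max_whales = max(counts),
    peak_date_days = as.integer(peak),
    skewness = if (shape_ok) e1071::skewness(counts, type = 2) else NA_real_,
    excess_kurtosis = if (shape_ok) e1071::kurtosis(counts, type = 2) else NA_real_,
    raw_kurtosis = if (shape_ok) e1071::kurtosis(counts, type = 2) + 3 else NA_real_
  )
}

#' Summarise every season of a transect table
#'
#' @param transects tibble with `year`, `date`, `n_whales`.
#' @inheritParams summarize_year
#' @return a tibble with one [summarize_year()] row per season, plus the
#'   high/low classification from [classify_years()].
#' @export
summarize_seasons <- function(transects, season_start = "05-24") {
  stopifnot(all(c("year", "date", "n_whales") %in% names(transects)))
  summaries <- transects |>
    dplyr::group_by(.data$year) |>
    dplyr::group_map(~ summarize_year(.x, season_start)) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$year)
  global_mean <- mean(transects$n_whales)
  classify_years(summaries, global_mean = global_mean)
}

#' Classify seasons as high or low foraging years
#'
#' A season is `"high"` when its mean whales-per-transect strictly exceeds
#' the global mean over all transects of all years, `"low"` otherwise
#' ("above the global mean" is read strictly, so a season exactly at the
#' global mean is low). The global mean is computed over transects, not as a
#' mean of yearly means, so seasons with more transects weigh more.
#'
#' @param summaries tibble of per-season rows with `mean_whales` and
#'   `n_transects`.
#' @param global_mean optional externally computed global mean
#'   whales-per-transect; when `NULL`, an existing `global_mean` column is
#'   reused, and failing that the threshold is reconstructed from the
#'   summaries as the transect-weighted mean of `mean_whales`.
#' @return `summaries` with `global_mean` and `classification` columns.
#'   Idempotent: reclassifying the result changes nothing.
#' @export
classify_years <- function(summaries, global_mean = NULL) {
  stopifnot(all(c("mean_whales", "n_transects") %in% names(summaries)))
  if (is.null(global_mean)) {
    global_mean <- if ("global_mean" %in% names(summaries)) {
      summaries$global_mean[1]
    } else {
      sum(summaries$mean_whales * summaries$n_transects) /
        sum(summaries$n_transects)
    }
  }
  summaries$global_mean <- global_mean
  summaries$classification <- ifelse(summaries$mean_whales > global_mean, "high", "low")
  summaries
}
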