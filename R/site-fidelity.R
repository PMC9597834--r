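#' Within-season residency from a sighting history
#'
#' Residency is the inclusive day span between a whale's first and last
#' sighting of the season: `last - first + 1`, so a whale sighted once has
#' residency 1 day (the span is inclusive precisely so the single-sighting
#' floor is one day, not zero).
#'
#' @param dates Date vector of one whale's sightings.
#' @param year season (calendar year) to evaluate; default: the only year
#'   present.
#' @return integer number of days, or NA if the whale has no sighting that
#'   year.
#' @export
compute_residency <- function(dates, year = NULL) {
  stopifnot(inherits(dates, "Date"), length(dates) >= 1)
  yrs <- as.integer(format(dates, "%Y"))
  if (is.null(year)) {
    year <- unique(yrs)
    if (length(year) > 1) stop("multiple years present; specify `year`", call. = FALSE)
  }
  d <- dates[yrs == year]
  if (length(d) == 0) {
    return(NA_integer_)
  }
  as.integer(max(d) - min(d)) + 1L
}

#' Per-whale, per-year residency table
#'
#' @param catalogue long tibble of sightings: `whale_id`, `date`.
#' @return tibble with `whale_id`, `year`, `n_sightings`, `residency_days`.
#' @export
residency_table <- function(catalogue) {
  stopifnot(all(c("whale_id", "date") %in% names(catalogue)))
  catalogue |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::summarise(
      n_sightings = dplyr::n(),
      residency_days = as.integer(max(.data$date) - min(.data$date)) + 1L,
      .by = c("whale_id", "year")
    )
}

#' Classify a photo-identification catalogue into return and single-visit whales
#'
#' A whale is a return whale when its sightings span two or more distinct
#' years, a single-visit whale otherwise. The category is assessed
#' retrospectively over the whole catalogue, not per year, so per-year
#' return proportions report how many of the individuals identified that
#' year are known (from any year) to be multi-year users. Duplicate
#' whale-date rows are merged before counting.
#'
#' @param catalogue long tibble of sightings: `whale_id`, `date`.
#' @return list of class `gw_fidelity`:
#'   * `per_whale`: `whale_id`, `first_year`, `n_years`, `n_return_years`,
#'     `category`;
#'   * `per_year`: `year`, `total_individuals`, `return_count`,
#'     `single_visit_count`, `return_proportion` (percent, retrospective),
#'     `resighted_count`/`resighted_proportion` (prospective: already known
#'     from an earlier season -- low in early catalogue years while the
#'     catalogue is being established);
#'   * `totals`: catalogue-wide counts and the single-visit percentage.
#' @export
classify_catalogue <- function(catalogue) {
  stopifnot(all(c("whale_id", "date") %in% names(catalogue)))
  catalogue <- dplyr::distinct(catalogue[, c("whale_id", "date")])
  sightings <- catalogue |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")))
  per_whale <- sightings |>
    dplyr::summarise(
      first_year = min(.data$year),
      n_years = dplyr::n_distinct(.data$year),
      .by = "whale_id"
    ) |>
    dplyr::mutate(
      n_return_years = .data$n_years - 1L,
      category = ifelse(.data$n_years >= 2, "return", "single_visit")
    )
  per_year <- sightings |>
    dplyr::distinct(.data$whale_id, .data$year) |>
    dplyr::left_join(per_whale[, c("whale_id", "category", "first_year")], by = "whale_id") |>
    dplyr::summarise(
      total_individuals = dplyr::n(),
      return_count = sum(.data$category == "return"),
      single_visit_count = sum(.data$category == "single_visit"),
      resighted_count = sum(.data$first_year < .data$year),
      .by = "year"
    ) |>
    dplyr::mutate(
      return_proportion = 100 * .data$return_count / .data$total_individuals,
      # prospective companion measure: whales already known from an earlier
      # season; carries the catalogue-establishment bias of the early years
      resighted_proportion = 100 * .data$resighted_count / .data$total_individuals
    ) |>
    dplyr::arrange(.data$year)
  n_total <- nrow(per_whale)
  n_return <- sum(per_whale$category == "return")
  structure(
    list(
      per_whale = per_whale,
      per_year = per_year,
      totals = list(
        total_individuals = n_total,
        return_whales = n_return,
        single_visit_whales = n_total - n_return,
        single_visit_percent = 100 * (n_total - n_return) / n_total,
        return_percent = 100 * n_return / n_total
      )
    ),
    class = "gw_fidelity"
  )
}

#' @export
print.gw_fidelity <- function(x, ...) {
  t <- x$totals
  cat("<gw_fidelity>\n")
  cat(sprintf(
    "  %d individuals: %d return (%.1f%%), %d single-visit (%.2f%%)\n",
    t$total_individuals, t$return_whales, t$return_percent,
    t$single_visit_whales, t$single_visit_percent
  ))
  cat(sprintf("  %d catalogue years\n", nrow(x$per_year)))
  invisible(x)
}

#' Rank correlations between fidelity and foraging-intensity metrics
#'
#' Spearman rank correlations (two-sided) between yearly fidelity metrics
#' (mean residency, return proportion, total individuals) and yearly
#' foraging-intensity metrics (mean and maximum whales per transect),
#' the associations used to link site fidelity to foraging intensity.
#'
#' @param fidelity a `gw_fidelity` object from [classify_catalogue()].
#' @param annual per-season summary tibble from [summarize_seasons()].
#' @param residency optional per-whale/year residency from
#'   [residency_table()]; when supplied, mean annual residency enters the
#'   table. `include_single_sighting = FALSE` drops residency-1 whales from
#'   the yearly mean.
#' @param include_single_sighting keep whales sighted once (residency 1
#'   day) in the annual residency mean (default TRUE).
#' @return tibble with `metric_a`, `metric_b`, `rs`, `p_value`, `n_years`.
#' @export
fidelity_correlations <- function(fidelity, annual, residency = NULL,
                                  include_single_sighting = TRUE) {
  stopifnot(inherits(fidelity, "gw_fidelity"))
  tab <- dplyr::inner_join(fidelity$per_year, annual, by = "year")
  if (!is.null(residency)) {
    if (!include_single_sighting) {
      residency <- residency[residency$residency_days > 1, ]
    }
    res_year <- residency |>
      dplyr::summarise(mean_residency = mean(.data$residency_days), .by = "year")
    tab <- dplyr::left_join(tab, res_year, by = "year")
  }
  if (nrow(tab) < 4) {
    warning("fewer than 4 overlapping years; correlations not computed")
    return(tibble::tibble(
      metric_a = character(0), metric_b = character(0),
      rs = numeric(0), p_value = numeric(0), n_years = integer(0)
    ))
  }
  pairs <- list(
    c("return_proportion", "mean_whales"),
    c("return_proportion", "total_individuals"),
    c("total_individuals", "mean_whales"),
    c("return_count", "total_individuals"),
    c("single_visit_count", "total_individuals")
  )
  if ("mean_residency" %in% names(tab)) {
    pairs <- c(pairs, list(
      c("mean_residency", "mean_whales"),
      c("mean_residency", "return_proportion")
    ))
  }
  rows <- lapply(pairs, function(p) {
    ok <- stats::complete.cases(tab[[p[1]]], tab[[p[2]]])
    x <- tab[[p[1]]][ok]
    y <- tab[[p[2]]][ok]
    if (length(x) < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(
        metric_a = p[1], metric_b = p[2],
        rs = NA_real_, p_value = NA_real_, n_years = length(x)
      ))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    tibble::tibble(
      metric_a = p[1], metric_b = p[2],
      rs = unname(ct$estimate), p_value = ct$p.value, n_years = length(x)
    )
  })
  dplyr::bind_rows(rows)
}
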