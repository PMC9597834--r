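# Internal helpers shared across modules.

# Deterministic sub-seed derivation: each sub-generator (dynamics, catalogue,
# locations, calls, noise) gets its own stream so a module can be regenerated
# independently of the others. Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 97 + stream * 10007) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Convert calendar dates to season days
#'
#' Days elapsed from the season opening date (24 May unless configured
#' otherwise), so that 24 May is day 0. The season-day scale is the unit in
#' which peak foraging dates are reported.
#'
#' @param dates a `Date` vector.
#' @param season_start season opening as `"mm-dd"` (default `"05-24"`).
#' @return integer vector of days elapsed since the season opening of each
#'   date's own year.
#' @export
season_day <- function(dates, season_start = "05-24") {
  stopifnot(inherits(dates, "Date"))
  yr <- as.integer(format(dates, "%Y"))
  open <- as.Date(paste0(yr, "-", season_start))
  as.integer(dates - open)
}

season_dates <- function(year, season_start = "05-24", season_end = "09-06") {
  c(
    start = as.Date(paste0(year, "-", season_start)),
    end = as.Date(paste0(year, "-", season_end))
  )
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}
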