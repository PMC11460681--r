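#' Day length from latitude and day of year
#'
#' Closed-form CBM day-length model (Forsythe et al. 1995, Ecological
#' Modelling 80:87-95) with daylight defined sunrise-to-sunset at solar
#' center on the horizon (twilight coefficient p = 0). Uses a 365-day
#' no-leap calendar.
#'
#' @param latitude degrees, in `[-90, 90]` (vectorized).
#' @param day_of_year integer day 1..365 (vectorized, recycled).
#' @param p twilight coefficient in degrees below the horizon counted as
#'   daylight; 0 is astronomical sunrise/sunset.
#' @return hours of daylight in `[0, 24]`.
#' @export
day_length <- function(latitude, day_of_year, p = 0) {
  if (any(abs(latitude) > 90)) stop("latitude must lie in [-90, 90]")
  if (any(day_of_year < 1 | day_of_year >= 366)) {
    stop("day_of_year must lie in [1, 366)")
  }
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  phi <- asin(0.39795 * cos(theta))  # solar declination, radians
  lat_r <- latitude * pi / 180
  a <- (sin(p * pi / 180) + sin(lat_r) * sin(phi)) / (cos(lat_r) * cos(phi))
  a <- pmin(pmax(a, -1), 1)  # polar night / midnight sun
  24 - (24 / pi) * acos(a)
}

new_season_mask <- function(active) {
  stopifnot(is.matrix(active), ncol(active) == 365)
  structure(list(active = active, season_length = rowSums(active)),
            class = "season_mask")
}

#' @export
print.season_mask <- function(x, ...) {
  cat(sprintf("<season_mask> %d cells; season length %d..%d days\n",
              nrow(x$active), min(x$season_length), max(x$season_length)))
  invisible(x)
}

#' Photoperiod activity-season mask
#'
#' A day is in the activity season iff its day length is at least
#' `threshold_hours` (boundary inclusive: exactly 9 h counts as active).
#'
#' @param latitude per-cell latitudes (degrees).
#' @param threshold_hours daylight threshold, default 9 hours.
#' @return a `season_mask`: `active` (cells x 365 logical matrix) and
#'   `season_length` (days per cell).
#' @export
photoperiod_season_mask <- function(latitude, threshold_hours = 9) {
  dl <- outer(latitude, 1:365, day_length)
  new_season_mask(dl >= threshold_hours)
}

#' Precipitation activity-season mask
#'
#' A day `d` is in the activity season iff the trailing 30-day precipitation
#' total (days `d-29`..`d`, wrapping across the year boundary of the cyclic
#' average year) is at least `threshold_mm` (boundary inclusive).
#'
#' @param precip_daily cells x 365 matrix of daily precipitation (mm/day),
#'   nonnegative.
#' @param threshold_mm trailing-window total threshold, default 50 mm.
#' @param window_days trailing window, default 30 days.
#' @return a `season_mask`.
#' @export
precipitation_season_mask <- function(precip_daily, threshold_mm = 50,
                                      window_days = 30) {
  stopifnot(is.matrix(precip_daily), ncol(precip_daily) == 365)
  if (any(precip_daily < 0)) stop("precipitation must be nonnegative")
  padded <- cbind(precip_daily, precip_daily)  # cyclic year
  csum <- t(apply(padded, 1, cumsum))
  # trailing sum ending at day d (original index) = C[d+365] - C[d+365-window]
  d <- 1:365
  trail <- csum[, d + 365, drop = FALSE] - csum[, d + 365 - window_days, drop = FALSE]
  new_season_mask(trail >= threshold_mm)
}

#' A full-year (year-round) season mask
#'
#' @param n_cells number of cells.
#' @return a `season_mask` with all 365 days active.
#' @export
year_round_season_mask <- function(n_cells) {
  new_season_mask(matrix(TRUE, n_cells, 365))
}

#' In-season temperature mean and standard deviation
#'
#' Computes the mean and population standard deviation of the daily
#' temperature series over the active days of each cell's season. Cells
#' with a zero-length season get `NA` for both statistics.
#'
#' @param temp_daily cells x 365 matrix of daily temperature (degrees C).
#' @param mask a `season_mask` with matching cell count.
#' @param sd_type `"population"` (divisor n, the default: the mask defines
#'   the complete population of in-season days) or `"sample"` (divisor n-1).
#' @return data.frame with `mean`, `sd`, `season_length` per cell.
#' @export
season_temperature_stats <- function(temp_daily, mask,
                                     sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(temp_daily), ncol(temp_daily) == 365,
            inherits(mask, "season_mask"),
            nrow(temp_daily) == nrow(mask$active))
  n <- mask$season_length
  tm <- temp_daily
  tm[!mask$active] <- NA
  mu <- rowMeans(tm, na.rm = TRUE)
  ss <- rowSums((tm - mu)^2, na.rm = TRUE)
  denom <- if (sd_type == "population") n else pmax(n - 1, 0)
  sdv <- sqrt(ifelse(denom > 0, ss / denom, NA_real_))
  mu[n == 0] <- NA_real_
  sdv[n == 0] <- NA_real_
  data.frame(mean = mu, sd = sdv, season_length = n)
}
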