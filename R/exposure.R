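#' Nearest monitor to a point
#'
#' Returns the id of the monitor closest to `xy` in planar Euclidean
#' distance. Ties are broken deterministically by the lexicographically
#' lowest monitor id. Coordinates are planar (km): at the spatial scale of a
#' regional monitoring network the difference from a geodesic metric is
#' negligible, and the distance function is isolated here so a geodesic
#' variant can be swapped in.
#'
#' @param xy numeric length-2 vector (x, y).
#' @param monitors data.frame with columns `monitor_id`, `x`, `y`.
#' @return A single monitor id (character).
#' @export
nearest_monitor <- function(xy, monitors) {
  if (!is.numeric(xy) || length(xy) != 2L || any(!is.finite(xy)))
    stop_invalid("`xy` must be two finite coordinates")
  if (!is.data.frame(monitors) || nrow(monitors) == 0L)
    stop_invalid("`monitors` must be a non-empty data.frame")
  d2 <- (monitors$x - xy[1])^2 + (monitors$y - xy[2])^2
  ids <- as.character(monitors$monitor_id)
  best <- d2 == min(d2)
  sort(ids[best])[1L]
}

#' Grid-cell assignment on a regular lattice
#'
#' Maps a point to the index of the half-open cell `[low, high)` of a regular
#' axis-aligned grid. Points exactly on an interior boundary belong to the
#' higher-index cell.
#'
#' @param xy numeric length-2 point.
#' @param origin numeric length-2 lower-left corner of the grid.
#' @param pitch cell edge length (same units as `xy`), default 4 (km).
#' @param n_cells integer length-2 grid extent (cells per axis).
#' @return Integer vector `c(ix, iy)` of zero-based cell indices.
#' @export
assign_grid_cell <- function(xy, origin, pitch = 4, n_cells) {
  if (!is.numeric(xy) || length(xy) != 2L) stop_invalid("`xy` must be length 2")
  check_scalar_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  idx <- floor((xy - origin) / pitch)
  if (any(idx < 0) || any(idx >= n_cells))
    stop_invalid("point (%g, %g) lies outside the grid extent", xy[1], xy[2])
  as.integer(idx)
}

#' Apparent temperature from air temperature and relative humidity
#'
#' Computes the perceived-temperature covariate standard in air-pollution
#' epidemiology: the dew point is obtained from the Magnus approximation and
#' combined with air temperature as
#' `AT = -2.653 + 0.994 * t_air + 0.0153 * Td^2` (Steadman/Kalkstein form).
#'
#' @param t_air air temperature, deg C (vectorized).
#' @param rh relative humidity, percent in \[0, 100\].
#' @return Apparent temperature, deg C.
#' @export
apparent_temperature <- function(t_air, rh) {
  if (any(!is.finite(t_air)) || any(!is.finite(rh)))
    stop_invalid("`t_air` and `rh` must be finite")
  if (any(rh < 0 | rh > 100))
    stop_invalid("`rh` must lie in [0, 100]")
  td <- dew_point_magnus(t_air, rh)
  -2.653 + 0.994 * t_air + 0.0153 * td^2
}

# Magnus dew point; rh = 100 gives Td = t_air exactly.
dew_point_magnus <- function(t_air, rh) {
  a <- 17.625
  b <- 243.04
  rh <- pmax(rh, 1e-8) # log(0) guard; rh = 0 maps to a very low dew point
  alpha <- log(rh / 100) + a * t_air / (b + t_air)
  b * alpha / (a - alpha)
}

#' Per-subject lagged PM10 exposure assignment
#'
#' Assigns the 8-day lag vector (Day 0 through Day -7), long-term averages,
#' and the Day -1 apparent temperature for one subject. Day 0 (recruitment
#' day) uses the monitor nearest the clinic; Days -1..-7 and the long-term
#' windows use the monitor nearest the subject's residence. The 6-month and
#' yearly averages are means over the 182/365 days ending at Day -1, so no
#' long-term channel reads recruitment-day residence data. Any missing
#' monitor-day fails loudly rather than being imputed.
#'
#' @param subject one-row data.frame with `subject_id`, `res_x`, `res_y`,
#'   `enrollment_date` (Date).
#' @param series exposure series as returned by [generate_exposure()] or read
#'   from `exposure.csv`: list with `monitors` and `daily`.
#' @param clinic_xy numeric length-2 clinic coordinates.
#' @param longterm compute the 6-month/yearly averages (requires 182/365
#'   days of history before Day 0); with `FALSE` those columns are `NA`.
#' @return A one-row data.frame with `subject_id`, `pm10_lag0`..`pm10_lag7`,
#'   `pm10_6mo`, `pm10_1yr`, `app_temp_lag1`.
#' @export
assign_lags <- function(subject, series, clinic_xy, longterm = TRUE) {
  stopifnot(is.data.frame(subject), nrow(subject) == 1L)
  lookup <- exposure_lookup(series)
  row <- assign_lags_fast(
    subject_id = subject$subject_id,
    res_xy = c(subject$res_x, subject$res_y),
    enrollment_date = as.Date(subject$enrollment_date),
    lookup = lookup, clinic_xy = clinic_xy, longterm = longterm
  )
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Lagged exposure assignment for a whole cohort
#'
#' Vectorized driver over [assign_lags()] semantics; identical output,
#' one row per subject.
#'
#' @param cohort cohort data.frame (see [generate_cohort()]).
#' @param series exposure series.
#' @param clinic_xy clinic coordinates.
#' @return data.frame with one exposure row per subject.
#' @inheritParams assign_lags
#' @export
assign_exposure <- function(cohort, series, clinic_xy, longterm = TRUE) {
  lookup <- exposure_lookup(series)
  n <- nrow(cohort)
  out <- vector("list", n)
  dates <- as.Date(cohort$enrollment_date)
  for (i in seq_len(n)) {
    out[[i]] <- assign_lags_fast(
      subject_id = cohort$subject_id[i],
      res_xy = c(cohort$res_x[i], cohort$res_y[i]),
      enrollment_date = dates[i],
      lookup = lookup, clinic_xy = clinic_xy, longterm = longterm
    )
  }
  do.call(rbind.data.frame, c(out, list(stringsAsFactors = FALSE)))
}

# Precompute monitor-by-date matrices for O(1) window lookups.
exposure_lookup <- function(series) {
  daily <- series$daily
  monitors <- series$monitors
  ids <- as.character(monitors$monitor_id)
  dates <- sort(unique(as.Date(daily$date)))
  if (!all(diff(dates) == 1))
    stop_invalid("exposure series dates are not contiguous")
  nd <- length(dates)
  shape <- function(col) {
    m <- matrix(NA_real_, nrow = length(ids), ncol = nd,
                dimnames = list(ids, NULL))
    ri <- match(as.character(daily$monitor_id), ids)
    ci <- match(as.Date(daily$date), dates)
    m[cbind(ri, ci)] <- daily[[col]]
    m
  }
  pm <- shape("pm10")
  list(
    monitors = monitors, ids = ids, date0 = dates[1L], n_dates = nd,
    pm10 = pm, temperature = shape("temperature"), rh = shape("rh"),
    # cumulative sums along days (NA-free check happens at lookup time)
    pm10_cum = t(apply(pm, 1L, function(v) cumsum(ifelse(is.na(v), 0, v)))),
    pm10_na = t(apply(pm, 1L, function(v) cumsum(is.na(v))))
  )
}

assign_lags_fast <- function(subject_id, res_xy, enrollment_date, lookup,
                             clinic_xy, longterm = TRUE) {
  res_mon <- nearest_monitor(res_xy, lookup$monitors)
  clin_mon <- nearest_monitor(clinic_xy, lookup$monitors)
  day0 <- as.integer(enrollment_date - lookup$date0) + 1L
  need <- day0 - 0:7
  if (any(need < 1L) || day0 > lookup$n_dates)
    stop_invalid("subject %s: exposure series does not cover the lag window ending %s",
                 subject_id, format(enrollment_date))
  lag <- numeric(8L)
  lag[1L] <- lookup$pm10[clin_mon, day0]
  lag[2:8] <- lookup$pm10[res_mon, need[2:8]]
  miss <- which(!is.finite(lag))
  if (length(miss))
    stop_invalid("subject %s: missing PM10 on %s",
                 subject_id, format(enrollment_date - (miss[1L] - 1L)))
  win_mean <- function(len) {
    hi <- day0 - 1L
    lo <- hi - len + 1L
    if (lo < 1L)
      stop_invalid("subject %s: series does not cover the %d-day window ending %s",
                   subject_id, len, format(enrollment_date - 1))
    nas <- lookup$pm10_na[res_mon, hi] - if (lo > 1L) lookup$pm10_na[res_mon, lo - 1L] else 0
    if (nas > 0)
      stop_invalid("subject %s: %d missing PM10 days in the %d-day window",
                   subject_id, nas, len)
    s <- lookup$pm10_cum[res_mon, hi] - if (lo > 1L) lookup$pm10_cum[res_mon, lo - 1L] else 0
    s / len
  }
  t1 <- lookup$temperature[res_mon, day0 - 1L]
  rh1 <- lookup$rh[res_mon, day0 - 1L]
  if (!is.finite(t1) || !is.finite(rh1))
    stop_invalid("subject %s: missing meteorology on %s",
                 subject_id, format(enrollment_date - 1))
  list(
    subject_id = subject_id,
    pm10_lag0 = lag[1L], pm10_lag1 = lag[2L], pm10_lag2 = lag[3L],
    pm10_lag3 = lag[4L], pm10_lag4 = lag[5L], pm10_lag5 = lag[6L],
    pm10_lag6 = lag[7L], pm10_lag7 = lag[8L],
    pm10_6mo = if (longterm) win_mean(182L) else NA_real_,
    pm10_1yr = if (longterm) win_mean(365L) else NA_real_,
    app_temp_lag1 = apparent_temperature(t1, rh1)
  )
}
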