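#' Diurnal-curve parameters
#'
#' The three parameters of the diurnal temperature model: `a`, the lag (hours)
#' of the daily maximum after TST noon; `b`, the dimensionless night-time
#' decay coefficient; and `c`, the lag (hours) of the daily minimum after
#' sunrise. Defaults are the generic triple calibrated for the Swiss plateau;
#' [params_site_mean()] returns the mean of the site-specific calibrations,
#' the customary starting point for a new fit.
#'
#' @param a Hours; sanity bounds (-2, 6).
#' @param b Dimensionless, > 0.
#' @param c Hours; sanity bounds (-2, 4).
#' @return An object of class `model_params`.
#' @examples
#' model_params()              # generic calibration
#' model_params(2.5, 3.0, 0.9) # a custom triple
#' @export
model_params <- function(a = 2.71, b = 3.14, c = 0.75) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (b <= 0) stop("b (night-time decay) must be > 0")
  if (a <= -2 || a >= 6) stop("a out of sanity bounds (-2, 6): ", a)
  if (c <= -2 || c >= 4) stop("c out of sanity bounds (-2, 4): ", c)
  structure(list(a = a, b = b, c = c), class = "model_params")
}

#' @rdname model_params
#' @export
params_generic <- function() model_params(2.71, 3.14, 0.75)

#' @rdname model_params
#' @export
params_site_mean <- function() model_params(2.79, 3.16, 0.79)

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("diurnal model parameters: a = %.4g h, b = %.4g, c = %.4g h\n",
              x$a, x$b, x$c))
  invisible(x)
}

# Day-branch sine evaluated at hour h (vectorized). The denominator
# hs - hr + 2a - 2c stretches the half-period so the curve peaks at
# (hr + hs)/2 + a and passes through Tx there.
.day_branch <- function(h, a, c, tn, tx, hr, hs) {
  tn + (tx - tn) * sin(pi * (h - hr - c) / (hs - hr + 2 * a - 2 * c))
}

# Night branch: exponential relaxation from the sunset temperature ts towards
# the upcoming minimum tn, over corrected night length n, evaluated t hours
# after sunset. The factored form carries the (ts - tn) amplitude on both the
# exponential and the linear correction term, which pins T(t = n) = tn
# exactly; the literal form leaves the linear term unscaled.
.night_branch <- function(t, n, b, tn, ts, night_form) {
  if (night_form == "factored") {
    tn + (ts - tn) * (exp(-b * t / n) - (t / n) * exp(-b))
  } else {
    tn + (ts - tn) * exp(-b * t / n) - (t / n) * exp(-b)
  }
}

#' Temperature at sunset
#'
#' Evaluates the daytime sine branch at the sunset hour. The sunset
#' temperature anchors the nocturnal exponential decay of the same and the
#' following night.
#'
#' @param params A [model_params()].
#' @param tn,tx Daily minimum and maximum, degrees C (vectorized).
#' @param sunrise,sunset Hours in TST (vectorized).
#' @return Degrees C, within \[tn, tx\].
#' @export
sunset_temperature <- function(params, tn, tx, sunrise, sunset) {
  stopifnot(inherits(params, "model_params"))
  if (any(tn > tx, na.rm = TRUE)) stop("tn > tx")
  if (any(sunset - sunrise - params$c <= 0, na.rm = TRUE) ||
      any(sunset - sunrise + 2 * params$a - 2 * params$c <= 0, na.rm = TRUE))
    stop("degenerate daylength: sunset <= sunrise + c")
  .day_branch(sunset, params$a, params$c, tn, tx, sunrise, sunset)
}

#' Per-day forcing for the diurnal model
#'
#' Assembles, for each day of a contiguous daily series, the quantities the
#' three-branch model needs: the day's Tn/Tx and solar times plus the
#' neighbouring-day context (previous day's Tn/Tx and solar times, from which
#' the previous sunset temperature is computed; next day's Tn and sunrise).
#' At the first and last day of the series the missing neighbour is replaced
#' by the day's own values and the day is flagged `"edge"`; the same rule
#' covers interior days whose neighbour has missing Tn/Tx.
#'
#' @param daily A data.frame with columns `date` (Date), `tmin`, `tmax`
#'   (degrees C); dates must be contiguous.
#' @param geometry A [site_geometry()].
#' @return A data.frame, one row per day.
#' @export
build_forcing <- function(daily, geometry) {
  stopifnot(is.data.frame(daily), all(c("date", "tmin", "tmax") %in% names(daily)))
  if (nrow(daily) < 2) stop("daily series must have at least 2 days")
  daily <- daily[order(daily$date), , drop = FALSE]
  if (any(diff(as.integer(daily$date)) != 1L))
    stop("daily series has gaps; fill or split it first")
  bad <- which(daily$tmin > daily$tmax)
  if (length(bad))
    stop("tmin > tmax on ", daily$date[bad[1]])
  doy <- as.POSIXlt(daily$date)$yday + 1L
  st <- sunrise_sunset(geometry, doy)
  n <- nrow(daily)
  lag1 <- function(x, fill) c(fill, x[-n])
  lead1 <- function(x, fill) c(x[-1], fill)
  f <- data.frame(
    date = daily$date, day_of_year = doy,
    tn = daily$tmin, tx = daily$tmax,
    sunrise = st$sunrise, sunset = st$sunset,
    tn_prev = lag1(daily$tmin, daily$tmin[1]),
    tx_prev = lag1(daily$tmax, daily$tmax[1]),
    sunrise_prev = lag1(st$sunrise, st$sunrise[1]),
    sunset_prev = lag1(st$sunset, st$sunset[1]),
    tn_next = lead1(daily$tmin, daily$tmin[n]),
    sunrise_next = lead1(st$sunrise, st$sunrise[n]),
    flag = "ok", stringsAsFactors = FALSE)
  f$flag[c(1, n)] <- "edge"
  # interior neighbour gaps: fall back to same-day surrogates, as at edges
  prev_na <- is.na(f$tn_prev) | is.na(f$tx_prev)
  f$tn_prev[prev_na] <- f$tn[prev_na]
  f$tx_prev[prev_na] <- f$tx[prev_na]
  next_na <- is.na(f$tn_next)
  f$tn_next[next_na] <- f$tn[next_na]
  f$flag[(prev_na | next_na) & f$flag == "ok"] <- "edge"
  f$flag[is.na(f$tn) | is.na(f$tx)] <- "missing"
  f
}

# Core evaluator: all arguments equal-length vectors (h paired row-wise with
# the forcing fields). Returns degrees C.
.eval_model <- function(h, params, tn, tx, tn_next, ts, ts_prev,
                        sunrise, sunset, sunset_prev, sunrise_next,
                        night_form) {
  a <- params$a; b <- params$b; cc <- params$c
  if (any(h < 0 | h > 24, na.rm = TRUE)) stop("hour must be in [0, 24]")
  n1 <- sunrise - sunset_prev + cc + 24
  n2 <- sunrise_next - sunset + cc + 24
  if (any(n1 <= 0 | n2 <= 0, na.rm = TRUE))
    stop("non-positive corrected night length")
  if (any(sunset - sunrise - cc <= 0, na.rm = TRUE))
    stop("degenerate daylength: sunset <= sunrise + c")
  out <- rep(NA_real_, length(h))
  morning <- !is.na(h) & h < sunrise + cc
  day <- !is.na(h) & h >= sunrise + cc & h <= sunset
  evening <- !is.na(h) & h > sunset
  if (any(morning)) {
    t1 <- h[morning] - sunset_prev[morning] + 24
    out[morning] <- .night_branch(t1, n1[morning], b, tn[morning],
                                  ts_prev[morning], night_form)
  }
  if (any(day))
    out[day] <- .day_branch(h[day], a, cc, tn[day], tx[day],
                            sunrise[day], sunset[day])
  if (any(evening)) {
    t2 <- h[evening] - sunset[evening]
    out[evening] <- .night_branch(t2, n2[evening], b, tn_next[evening],
                                  ts[evening], night_form)
  }
  out
}

#' Hourly temperature for one day
#'
#' Evaluates the three-branch diurnal model at hours `h` (decimal TST) of the
#' day described by `forcing` (one row of [build_forcing()] output, or any
#' list with the same fields). Before sunrise + c the temperature relaxes
#' exponentially from the previous day's sunset temperature towards today's
#' minimum; between sunrise + c and sunset it follows a sine arc through
#' today's minimum and maximum; after sunset it decays from today's sunset
#' temperature towards tomorrow's minimum.
#'
#' @param params A [model_params()].
#' @param forcing One-row data.frame or list with fields `tn`, `tx`,
#'   `tn_next`, `tn_prev`, `tx_prev`, `sunrise`, `sunset`, `sunset_prev`,
#'   `sunrise_prev`, `sunrise_next`.
#' @param h Numeric vector of hours in \[0, 24\].
#' @param night_form `"factored"` (default; the additive night correction is
#'   scaled by the sunset-to-minimum amplitude, so the curve passes exactly
#'   through the minimum) or `"literal"` (unscaled correction term).
#' @return Degrees C, same length as `h`.
#' @export
hourly_temperature <- function(params, forcing, h,
                               night_form = c("factored", "literal")) {
  night_form <- match.arg(night_form)
  stopifnot(inherits(params, "model_params"))
  one <- function(x) rep(x, length(h))
  ts <- sunset_temperature(params, forcing$tn, forcing$tx,
                           forcing$sunrise, forcing$sunset)
  ts_prev <- sunset_temperature(params, forcing$tn_prev, forcing$tx_prev,
                                forcing$sunrise_prev, forcing$sunset_prev)
  .eval_model(h, params,
              one(forcing$tn), one(forcing$tx), one(forcing$tn_next),
              one(ts), one(ts_prev),
              one(forcing$sunrise), one(forcing$sunset),
              one(forcing$sunset_prev), one(forcing$sunrise_next),
              night_form)
}

#' Simulate an hourly temperature series from daily extremes
#'
#' Applies the diurnal model day by day over a contiguous daily Tn/Tx series,
#' carrying the previous day's sunset temperature and the next day's minimum
#' across midnight so the reconstructed series is continuous. The first and
#' last days use their own values as neighbour surrogates and are flagged
#' `"edge"`; days with missing Tn/Tx yield missing hours flagged `"missing"`.
#'
#' @inheritParams build_forcing
#' @param params A [model_params()].
#' @param hours Sampling grid within each day, decimal TST hours in (0, 24\];
#'   default on-the-hour `1:24` (hour 24 is the following midnight).
#' @param night_form See [hourly_temperature()].
#' @return A data.frame with columns `date`, `hour`, `temp`, `flag`.
#' @examples
#' daily <- data.frame(date = as.Date("2003-06-01") + 0:4,
#'                     tmin = c(10, 11, 9, 12, 10),
#'                     tmax = c(22, 24, 20, 25, 23))
#' sim <- simulate_series(params_generic(), daily, site_geometry(47))
#' head(sim)
#' @export
simulate_series <- function(params, daily, geometry, hours = 1:24,
                            night_form = c("factored", "literal")) {
  night_form <- match.arg(night_form)
  stopifnot(inherits(params, "model_params"), all(hours >= 0), all(hours <= 24))
  f <- build_forcing(daily, geometry)
  ok <- f$flag != "missing"
  ts <- rep(NA_real_, nrow(f))
  ts[ok] <- sunset_temperature(params, f$tn[ok], f$tx[ok],
                               f$sunrise[ok], f$sunset[ok])
  ts_prev <- rep(NA_real_, nrow(f))
  ts_prev[ok] <- sunset_temperature(params, f$tn_prev[ok], f$tx_prev[ok],
                                    f$sunrise_prev[ok], f$sunset_prev[ok])
  nh <- length(hours)
  idx <- rep(seq_len(nrow(f)), each = nh)
  h <- rep(hours, nrow(f))
  temp <- rep(NA_real_, length(h))
  use <- ok[idx]
  temp[use] <- .eval_model(
    h[use], params, f$tn[idx][use], f$tx[idx][use], f$tn_next[idx][use],
    ts[idx][use], ts_prev[idx][use], f$sunrise[idx][use], f$sunset[idx][use],
    f$sunset_prev[idx][use], f$sunrise_next[idx][use], night_form)
  data.frame(date = f$date[idx], hour = h, temp = temp,
             flag = f$flag[idx], stringsAsFactors = FALSE)
}

#' Daily extremes from an hourly series
#'
#' Extracts per-date minimum and maximum temperature, the standard way daily
#' Tn/Tx are derived from station records before feeding them back into the
#' diurnal model.
#'
#' @param hourly A data.frame with columns `date`, `hour`, `temp`.
#' @param min_hours Minimum number of non-missing hours for a day to be kept.
#' @return A data.frame with columns `date`, `tmin`, `tmax`, `n_hours`.
#' @export
daily_from_hourly <- function(hourly, min_hours = 24L) {
  stopifnot(all(c("date", "temp") %in% names(hourly)))
  sp <- split(hourly$temp, hourly$date)
  n <- vapply(sp, function(x) sum(!is.na(x)), integer(1))
  out <- data.frame(
    date = as.Date(names(sp)),
    tmin = vapply(sp, function(x) if (any(!is.na(x))) min(x, na.rm = TRUE) else NA_real_, numeric(1)),
    tmax = vapply(sp, function(x) if (any(!is.na(x))) max(x, na.rm = TRUE) else NA_real_, numeric(1)),
    n_hours = n, row.names = NULL)
  out$tmin[n < min_hours] <- NA_real_
  out$tmax[n < min_hours] <- NA_real_
  out
}
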