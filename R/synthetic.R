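#' Synthetic-weather configuration
#'
#' Parameters of the seeded fixture generator used to exercise the whole
#' pipeline without station data. The defaults emulate a mid-latitude
#' lowland station (Swiss plateau): annual mean 9 degrees C with a 9-degree
#' seasonal amplitude peaking around DOY 200, a mean diurnal range of 8
#' degrees modulated seasonally by +/- 3, AR(1) day-to-day weather noise,
#' independent Gaussian hourly noise, and a 30% fraction of overcast days on
#' which the diurnal cycle is flattened, the minimum typically drifts to the
#' afternoon, and the radiation ratio drops below the clear-sky threshold.
#'
#' @param true_params [model_params()] generating the diurnal curves.
#' @param sites List of [site_geometry()] objects.
#' @param years Number of calendar years, starting at `start_year`.
#' @param start_year First calendar year.
#' @param annual_mean,annual_amplitude Seasonal Tn/Tx midline, degrees C.
#' @param peak_doy DOY of the warmest day of the seasonal cycle.
#' @param diurnal_range,range_amplitude Mean daily Tx - Tn and its seasonal
#'   modulation, degrees C.
#' @param ar1_phi,daily_sd AR(1) coefficient and marginal SD of the
#'   day-to-day noise added independently to Tn and Tx.
#' @param hourly_noise_sd SD of i.i.d. Gaussian noise on each hourly value.
#' @param overcast_fraction Bernoulli probability that a day is overcast.
#' @param flattening Factor in (0, 1\] multiplying the diurnal amplitude on
#'   overcast days.
#' @param afternoon_tn_prob Probability that an overcast day's hourly
#'   profile is reversed in time, displacing the minimum to the afternoon.
#' @param clear_ratio_range,overcast_ratio_range Uniform ranges for the
#'   observed/potential radiation ratio on clear and overcast days.
#' @param transmissivity Clear-sky transmissivity for potential radiation.
#' @param seed Master seed; every stochastic element derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_params = params_generic(),
                             sites = list(site_geometry(47.0, 7.5,
                                                        standard_meridian = 15,
                                                        elevation = 450)),
                             years = 3, start_year = 2001,
                             annual_mean = 9, annual_amplitude = 9,
                             peak_doy = 200,
                             diurnal_range = 8, range_amplitude = 3,
                             ar1_phi = 0.6, daily_sd = 1.5,
                             hourly_noise_sd = 0.5,
                             overcast_fraction = 0.3, flattening = 0.4,
                             afternoon_tn_prob = 0.9,
                             clear_ratio_range = c(0.92, 1.00),
                             overcast_ratio_range = c(0.40, 0.85),
                             transmissivity = 0.75,
                             seed = 1L) {
  stopifnot(inherits(true_params, "model_params"),
            overcast_fraction >= 0, overcast_fraction <= 1,
            flattening > 0, flattening <= 1,
            daily_sd >= 0, hourly_noise_sd >= 0,
            abs(ar1_phi) < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# AR(1) series with marginal SD `sd` (innovation sd scaled accordingly).
.ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# Daily Tn/Tx plus overcast labels for one site. Assumes the RNG is already
# seeded by the caller.
.generate_daily <- function(cfg, geometry) {
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$start_year + cfg$years - 1L)),
               by = "day")
  doy <- as.POSIXlt(dates)$yday + 1L
  n <- length(dates)
  seas <- cfg$annual_mean +
    cfg$annual_amplitude * cos(2 * pi * (doy - cfg$peak_doy) / 365.25)
  rng <- pmax(1, cfg$diurnal_range +
                cfg$range_amplitude * cos(2 * pi * (doy - cfg$peak_doy) / 365.25))
  tn <- seas - rng / 2 + as.numeric(.ar1(n, cfg$ar1_phi, cfg$daily_sd))
  tx <- seas + rng / 2 + as.numeric(.ar1(n, cfg$ar1_phi, cfg$daily_sd))
  bad <- tx < tn + 0.5
  if (any(bad)) { # keep a minimal positive diurnal range
    mid <- (tn[bad] + tx[bad]) / 2
    tn[bad] <- mid - 0.25; tx[bad] <- mid + 0.25
  }
  overcast <- stats::runif(n) < cfg$overcast_fraction
  if (any(overcast)) { # flatten the diurnal cycle on overcast days
    mid <- (tn[overcast] + tx[overcast]) / 2
    half <- (tx[overcast] - tn[overcast]) / 2 * cfg$flattening
    tn[overcast] <- mid - half; tx[overcast] <- mid + half
  }
  list(daily = data.frame(date = dates, tmin = tn, tmax = tx),
       doy = doy, overcast = overcast)
}

#' Generate a synthetic station
#'
#' Draws a multi-year station record with known ground truth: daily Tn/Tx
#' from a seasonal sinusoid plus AR(1) noise, hourly temperatures from the
#' diurnal model at `true_params` plus i.i.d. Gaussian noise, and daily
#' radiation ratios that make clear days pass and overcast days fail the
#' clear-sky screen. Overcast days are flattened and (with probability
#' `afternoon_tn_prob`) time-reversed so their minimum falls in the
#' afternoon, emulating the irregular days real records contain.
#'
#' @param cfg A [synthetic_config()].
#' @param site Index into `cfg$sites`.
#' @return A [station()] with two extra fields: `labels` (data.frame
#'   `date`, `overcast`, `ratio`, `reversed`) and `true_params`.
#' @export
generate_station <- function(cfg, site = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"), site >= 1,
            site <= length(cfg$sites))
  geometry <- cfg$sites[[site]]
  .with_seed(cfg$seed + (site - 1L), {
    g <- .generate_daily(cfg, geometry)
    hourly <- simulate_series(cfg$true_params, g$daily, geometry)
    if (cfg$hourly_noise_sd > 0)
      hourly$temp <- hourly$temp +
        stats::rnorm(nrow(hourly), sd = cfg$hourly_noise_sd)
    reversed <- g$overcast & (stats::runif(length(g$overcast)) < cfg$afternoon_tn_prob)
    if (any(reversed)) {
      k <- hourly$date %in% g$daily$date[reversed]
      hourly$temp[k] <- as.vector(apply(
        matrix(hourly$temp[k], nrow = 24), 2, rev))
    }
    ratio <- ifelse(g$overcast,
                    stats::runif(length(g$overcast), cfg$overcast_ratio_range[1],
                                 cfg$overcast_ratio_range[2]),
                    stats::runif(length(g$overcast), cfg$clear_ratio_range[1],
                                 cfg$clear_ratio_range[2]))
    rad_pot <- potential_daily_radiation(geometry, g$doy, cfg$transmissivity)
    stn <- station(paste0("SYN", site), geometry, hourly, g$daily,
                   radiation = data.frame(date = g$daily$date,
                                          rad_obs = ratio * rad_pot,
                                          rad_pot = rad_pot))
    stn$labels <- data.frame(date = g$daily$date, overcast = g$overcast,
                             ratio = ratio, reversed = reversed)
    stn$true_params <- cfg$true_params
    stn
  })
}

#' Generate a gridded daily Tn/Tx field
#'
#' One seeded base daily series (as in [generate_station()], without hourly
#' noise) shifted per cell by a constant lapse rate times the cell's
#' elevation anomaly. The default elevation surface rises linearly from west
#' to east, giving a clean monotone structure for downstream checks;
#' `per_cell_sd` adds independent cell noise when non-zero.
#'
#' @param cfg A [synthetic_config()].
#' @param lat_range,lon_range Grid extent, degrees (cell centres).
#' @param resolution Cell size in degrees; default 0.02.
#' @param lapse_rate Degrees C per 100 m; default -0.65.
#' @param elevation Matrix (nlat x nlon) of metres a.s.l., or NULL for the
#'   default west-east ramp from 400 to 1600 m.
#' @param ref_elevation Elevation (m) at which the base series applies.
#' @param per_cell_sd SD of extra i.i.d. daily noise per cell; default 0
#'   (cells are exact lapse-shifted copies).
#' @return A `grid_field`: coordinate vectors, elevation matrix, `dates`,
#'   and `tmin`/`tmax` arrays of dimension (days, nlat, nlon).
#' @export
generate_grid <- function(cfg, lat_range = c(46.0, 46.2),
                          lon_range = c(7.0, 7.2), resolution = 0.02,
                          lapse_rate = -0.65, elevation = NULL,
                          ref_elevation = 450, per_cell_sd = 0) {
  stopifnot(inherits(cfg, "synthetic_config"), resolution > 0)
  lat <- seq(lat_range[1], lat_range[2], by = resolution)
  lon <- seq(lon_range[1], lon_range[2], by = resolution)
  if (!length(lat) || !length(lon)) stop("empty grid extent")
  if (is.null(elevation))
    elevation <- matrix(rep(seq(400, 1600, length.out = length(lon)),
                            each = length(lat)),
                        nrow = length(lat))
  stopifnot(nrow(elevation) == length(lat), ncol(elevation) == length(lon))
  base_geom <- site_geometry(mean(lat), mean(lon),
                             standard_meridian = cfg$sites[[1]]$standard_meridian,
                             elevation = ref_elevation)
  .with_seed(cfg$seed, {
    g <- .generate_daily(cfg, base_geom)
    nd <- nrow(g$daily)
    tmin <- array(NA_real_, c(nd, length(lat), length(lon)))
    tmax <- tmin
    for (i in seq_along(lat)) for (j in seq_along(lon)) {
      shift <- lapse_rate * (elevation[i, j] - ref_elevation) / 100
      eps <- if (per_cell_sd > 0) stats::rnorm(nd, sd = per_cell_sd) else 0
      tmin[, i, j] <- g$daily$tmin + shift + eps
      tmax[, i, j] <- g$daily$tmax + shift + eps
    }
    structure(list(lat = lat, lon = lon, elevation = elevation,
                   dates = g$daily$date, tmin = tmin, tmax = tmax,
                   ref_elevation = ref_elevation, lapse_rate = lapse_rate),
              class = "grid_field")
  })
}
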