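#' Clear-sky screening rules
#'
#' A day enters the calibration set only if its diurnal course is "regular":
#' the daily minimum occurs before TST noon and the observed/potential
#' global radiation ratio exceeds a threshold (default 0.9). Potential
#' radiation is extraterrestrial radiation scaled by a clear-sky
#' transmissivity (see [potential_daily_radiation()]).
#'
#' @param radiation_ratio_threshold Fraction in (0, 1\]; default 0.9.
#' @param require_tn_before_noon Logical; default TRUE.
#' @param transmissivity Clear-sky transmissivity used when potential
#'   radiation has to be computed; default 0.75.
#' @return An object of class `clear_sky_criteria`.
#' @export
clear_sky_criteria <- function(radiation_ratio_threshold = 0.9,
                               require_tn_before_noon = TRUE,
                               transmissivity = 0.75) {
  stopifnot(radiation_ratio_threshold > 0, radiation_ratio_threshold <= 1)
  structure(list(radiation_ratio_threshold = radiation_ratio_threshold,
                 require_tn_before_noon = require_tn_before_noon,
                 transmissivity = transmissivity),
            class = "clear_sky_criteria")
}

#' Classify one day as clear-sky
#'
#' @param temp,hour The day's hourly temperatures and their TST hours
#'   (expected 24 values on the 1..24 grid).
#' @param rad_obs,rad_pot Observed and potential daily global radiation,
#'   MJ m^-2 d^-1.
#' @param criteria A [clear_sky_criteria()].
#' @return TRUE/FALSE, or NA if the day is incomplete (missing hours).
#' @export
is_clear_sky_day <- function(temp, hour, rad_obs, rad_pot,
                             criteria = clear_sky_criteria()) {
  stopifnot(length(temp) == length(hour), rad_pot > 0)
  if (length(temp) < 24L || anyNA(temp) || is.na(rad_obs)) return(NA)
  ok <- rad_obs / rad_pot > criteria$radiation_ratio_threshold
  if (criteria$require_tn_before_noon)
    ok <- ok && hour[which.min(temp)] < 12
  ok
}

#' Clear-sky classification for a whole station record
#'
#' @param stn A [station()] carrying a `radiation` table.
#' @param criteria A [clear_sky_criteria()].
#' @return data.frame with columns `date` and `clear` (logical, NA when the
#'   day is incomplete or radiation is missing).
#' @export
clear_sky_days <- function(stn, criteria = clear_sky_criteria()) {
  stopifnot(inherits(stn, "tt_station"))
  if (is.null(stn$radiation))
    stop("station has no radiation table; cannot screen clear-sky days")
  rad <- stn$radiation
  sp <- split(stn$hourly[c("hour", "temp")], stn$hourly$date)
  dates <- as.Date(names(sp))
  i <- match(dates, rad$date)
  clear <- vapply(seq_along(sp), function(k) {
    if (is.na(i[k])) return(NA)
    is_clear_sky_day(sp[[k]]$temp, sp[[k]]$hour,
                     rad$rad_obs[i[k]], rad$rad_pot[i[k]], criteria)
  }, logical(1))
  data.frame(date = dates, clear = clear)
}

#' Select calibration days
#'
#' Draws `n_years` distinct calendar years uniformly at random (without
#' replacement, seeded) from the station record, then keeps every clear-sky
#' day within them.
#'
#' @inheritParams clear_sky_days
#' @param n_years Number of years to sample; if the record holds fewer, all
#'   years are used with a warning.
#' @param seed Integer seed; NULL uses the current RNG stream.
#' @return Date vector of selected clear-sky days, with the sampled years in
#'   attribute `"years"`.
#' @export
select_calibration_days <- function(stn, n_years = 25,
                                    criteria = clear_sky_criteria(),
                                    seed = NULL) {
  cs <- clear_sky_days(stn, criteria)
  yrs <- unique(format(cs$date, "%Y"))
  if (length(yrs) < n_years) {
    warning("only ", length(yrs), " years available; using all")
    pick <- yrs
  } else {
    pick <- .with_seed(seed, sample(yrs, n_years))
  }
  keep <- cs$date[!is.na(cs$clear) & cs$clear & format(cs$date, "%Y") %in% pick]
  structure(keep, years = sort(pick))
}

# Pooled frame linking each calibration day's forcing row to its observed
# hourly temperatures. `hidx` maps hourly rows to forcing rows.
.calibration_frame <- function(stn, dates) {
  f <- build_forcing(stn$daily, stn$geometry)
  f <- f[f$date %in% dates & f$flag != "missing", , drop = FALSE]
  if (nrow(f) == 0) stop("no usable calibration days")
  h <- stn$hourly[stn$hourly$date %in% f$date & !is.na(stn$hourly$temp), ,
                  drop = FALSE]
  hidx <- match(h$date, f$date)
  list(forcing = f, obs = h$temp, hour = h$hour, hidx = hidx,
       day_of_obs = h$date,
       n_days = nrow(f), n_years = length(unique(format(f$date, "%Y"))))
}

# Objective evaluation on one or more pooled frames. Returns the metric
# (higher = better) or -Inf for parameter triples outside the sanity box.
.frames_objective <- function(par, frames, pooling, night_form) {
  if (par[2] <= 0 || par[1] <= -2 || par[1] >= 6 || par[3] <= -2 || par[3] >= 4)
    return(-1e6)
  params <- structure(list(a = par[1], b = par[2], c = par[3]),
                      class = "model_params")
  obs <- numeric(0); sim <- numeric(0); day <- character(0)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    f <- fr$forcing
    ts <- .day_branch(f$sunset, par[1], par[3], f$tn, f$tx, f$sunrise, f$sunset)
    ts_prev <- .day_branch(f$sunset_prev, par[1], par[3], f$tn_prev, f$tx_prev,
                           f$sunrise_prev, f$sunset_prev)
    if (any(f$sunset - f$sunrise - par[3] <= 0) ||
        any(f$sunset - f$sunrise + 2 * par[1] - 2 * par[3] <= 0))
      return(-1e6)
    i <- fr$hidx
    s <- .eval_model(fr$hour, params, f$tn[i], f$tx[i], f$tn_next[i],
                     ts[i], ts_prev[i], f$sunrise[i], f$sunset[i],
                     f$sunset_prev[i], f$sunrise_next[i], night_form)
    obs <- c(obs, fr$obs); sim <- c(sim, s)
    day <- c(day, paste(fi, fr$day_of_obs))
  }
  if (pooling == "pooled") return(mia(obs, sim))
  mean(vapply(split(seq_along(obs), day),
              function(k) mia(obs[k], sim[k]), numeric(1)))
}

.fit_frames <- function(frames, start, pooling, night_form,
                        control, sites) {
  p0 <- c(start$a, start$b, start$c)
  obj0 <- .frames_objective(p0, frames, pooling, night_form)
  opt <- stats::optim(p0, function(p)
    -.frames_objective(p, frames, pooling, night_form),
    method = "Nelder-Mead", control = control)
  params <- model_params(opt$par[1], opt$par[2], opt$par[3])
  res <- structure(list(
    params = params,
    objective = -opt$value,
    objective_at_start = obj0,
    n_days = sum(vapply(frames, `[[`, numeric(1), "n_days")),
    n_years = sum(vapply(frames, `[[`, numeric(1), "n_years")),
    sites = sites,
    converged = opt$convergence == 0L,
    start = start,
    realistic = opt$par[1] <= 5.5,
    control = control), class = "calibration_result")
  if (!res$realistic)
    warning("fitted a = ", signif(opt$par[1], 3),
            " > 5.5: unrealistic timing of the daily maximum")
  res
}

#' Fit the diurnal-curve parameters for one station
#'
#' Maximises the modified index of agreement (MIA) between observed hourly
#' temperatures and the model reconstruction over the pooled hours of the
#' calibration days, using Nelder-Mead simplex search on (a, b, c).
#'
#' @param stn A [station()].
#' @param dates Calibration days (Date vector), e.g. from
#'   [select_calibration_days()]; NULL uses every day of the record.
#' @param start Starting [model_params()]; defaults to the mean of the
#'   site-specific Swiss calibrations, (2.79, 3.16, 0.79).
#' @param pooling `"pooled"` computes one MIA over all concatenated hours
#'   (default); `"per_day"` averages per-day MIA values.
#' @param night_form See [hourly_temperature()].
#' @param control Passed to [stats::optim()]; defaults to relative tolerance
#'   1e-6 and at most 2000 iterations.
#' @return A `calibration_result`: fitted `params`, `objective` (MIA at the
#'   optimum), day/year counts, convergence flag, and a `realistic` flag
#'   (FALSE when a > 5.5 h, a timing no mid-latitude station exhibits).
#' @export
fit_parameters <- function(stn, dates = NULL, start = params_site_mean(),
                           pooling = c("pooled", "per_day"),
                           night_form = c("factored", "literal"),
                           control = list(reltol = 1e-6, maxit = 2000)) {
  pooling <- match.arg(pooling); night_form <- match.arg(night_form)
  stopifnot(inherits(stn, "tt_station"), inherits(start, "model_params"))
  if (is.null(dates)) dates <- stn$daily$date
  fr <- .calibration_frame(stn, dates)
  .fit_frames(list(fr), start, pooling, night_form, control, stn$id)
}

#' Fit one generic parameter triple over several stations
#'
#' Pools the calibration hours of all stations into a single objective, so
#' one (a, b, c) triple compromises across sites — the "generic model".
#'
#' @param stns List of [station()] objects (a single station reduces to
#'   [fit_parameters()]).
#' @param dates_list Optional list of Date vectors, parallel to `stns`.
#' @inheritParams fit_parameters
#' @return A `calibration_result`.
#' @export
fit_generic <- function(stns, dates_list = NULL, start = params_site_mean(),
                        pooling = c("pooled", "per_day"),
                        night_form = c("factored", "literal"),
                        control = list(reltol = 1e-6, maxit = 2000)) {
  pooling <- match.arg(pooling); night_form <- match.arg(night_form)
  stopifnot(length(stns) >= 1)
  frames <- lapply(seq_along(stns), function(i) {
    d <- if (is.null(dates_list)) stns[[i]]$daily$date else dates_list[[i]]
    .calibration_frame(stns[[i]], d)
  })
  .fit_frames(frames, start, pooling, night_form, control,
              vapply(stns, `[[`, character(1), "id"))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("calibration over %d days (%d site-years, sites: %s)\n",
                     "  a = %.3f h, b = %.3f, c = %.3f h\n",
                     "  MIA = %.4f (start %.4f), converged: %s\n"),
              x$n_days, x$n_years, paste(x$sites, collapse = ", "),
              x$params$a, x$params$b, x$params$c,
              x$objective, x$objective_at_start, x$converged))
  invisible(x)
}

#' Stratified performance of a parameter set at a station
#'
#' Reconstructs the station's hourly temperatures from its daily Tn/Tx with
#' the given parameters and compares them with the observed hourly record,
#' overall or stratified by hour of day or meteorological season.
#'
#' @param params A [model_params()].
#' @param stn A [station()].
#' @param by `"all"`, `"hour"` or `"season"`.
#' @param night_form See [hourly_temperature()].
#' @return data.frame with a `stratum` column and the six statistics of
#'   [model_metrics()]. Empty strata are omitted with a warning.
#' @export
evaluate_model <- function(params, stn, by = c("all", "hour", "season"),
                           night_form = c("factored", "literal")) {
  by <- match.arg(by); night_form <- match.arg(night_form)
  sim <- simulate_series(params, stn$daily, stn$geometry,
                         night_form = night_form)
  key <- paste(sim$date, sim$hour)
  obs <- stn$hourly
  i <- match(paste(obs$date, obs$hour), key)
  pairs <- data.frame(date = obs$date, hour = obs$hour,
                      obs = obs$temp, sim = sim$temp[i])
  pairs <- pairs[!is.na(pairs$obs) & !is.na(pairs$sim), , drop = FALSE]
  strata <- switch(by,
    all = factor(rep("all", nrow(pairs))),
    hour = factor(sprintf("%02d:00", pairs$hour %% 24)),
    season = meteorological_season(pairs$date))
  keep <- table(strata) >= 2
  if (any(!keep))
    warning("omitting empty/degenerate strata: ",
            paste(names(keep)[!keep], collapse = ", "))
  out <- do.call(rbind, lapply(levels(strata)[keep], function(s) {
    k <- strata == s
    cbind(stratum = s, model_metrics(pairs$obs[k], pairs$sim[k]))
  }))
  rownames(out) <- NULL
  out
}
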