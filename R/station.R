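#' Station bundle
#'
#' Bundles everything the calibration and evaluation stages need for one
#' site: geometry, the observed hourly series (TST hour grid 1..24), the
#' daily Tn/Tx series, and daily observed + potential global radiation.
#' The daily series may be supplied or derived from the hourly one with
#' [daily_from_hourly()].
#'
#' @param id Character station identifier.
#' @param geometry A [site_geometry()].
#' @param hourly data.frame with columns `date`, `hour` (1..24, TST), `temp`.
#' @param daily data.frame with columns `date`, `tmin`, `tmax`; derived from
#'   `hourly` when `NULL`.
#' @param radiation data.frame with columns `date`, `rad_obs`, `rad_pot`
#'   (MJ m^-2 d^-1), or `NULL` if clear-sky screening is not needed.
#' @return An object of class `tt_station`.
#' @export
station <- function(id, geometry, hourly, daily = NULL, radiation = NULL) {
  stopifnot(inherits(geometry, "site_geometry"),
            all(c("date", "hour", "temp") %in% names(hourly)))
  if (is.null(daily)) daily <- daily_from_hourly(hourly)[c("date", "tmin", "tmax")]
  if (!is.null(radiation))
    stopifnot(all(c("date", "rad_obs", "rad_pot") %in% names(radiation)))
  structure(list(id = id, geometry = geometry, hourly = hourly,
                 daily = daily, radiation = radiation),
            class = "tt_station")
}

#' @export
print.tt_station <- function(x, ...) {
  cat(sprintf("station %s: lat %.2f, %d days (%s to %s)\n", x$id,
              x$geometry$latitude, nrow(x$daily),
              min(x$daily$date), max(x$daily$date)))
  invisible(x)
}

# Run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Meteorological season of a date
#'
#' DJF/MAM/JJA/SON by calendar month.
#'
#' @param date Date vector.
#' @return Factor with levels DJF, MAM, JJA, SON.
#' @export
meteorological_season <- function(date) {
  m <- as.POSIXlt(date)$mon + 1L
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}
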