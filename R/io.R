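#' Read and write hourly temperature CSV
#'
#' The on-disk schema is `datetime` (ISO-8601, `YYYY-MM-DD HH:MM:SS`),
#' `temperature` (degrees C, empty or NA for missing) and an optional
#' `flag` column. Internally hours live on the 1..24 TST grid of the model
#' (hour 24 = the following midnight), so midnight stamps are attributed to
#' hour 24 of the preceding day. Round-tripping a series through
#' `write_hourly_csv()` and `read_hourly_csv()` is lossless.
#'
#' @param path File path.
#' @return `read_hourly_csv()`: data.frame with columns `date`, `hour`,
#'   `temp` (and `flag` if present), strictly increasing in time.
#' @export
read_hourly_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("datetime", "temperature") %in% names(x)))
    stop("hourly CSV needs columns 'datetime' and 'temperature': ", path)
  dt <- as.POSIXct(NA)[rep(1, nrow(x))]
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M")) {
    miss <- is.na(dt)
    if (!any(miss)) break
    dt[miss] <- as.POSIXct(strptime(x$datetime[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(dt) & !is.na(x$datetime))
  if (length(bad))
    stop("unparseable datetime at line ", bad[1] + 1L, ": '",
         x$datetime[bad[1]], "'")
  dup <- which(duplicated(dt))
  if (length(dup))
    stop("duplicated hour at line ", dup[1] + 1L, ": ",
         format(dt[dup[1]], "%Y-%m-%d %H:%M:%S"))
  if (is.unsorted(dt))
    stop("timestamps are not strictly increasing in ", path)
  hr <- as.POSIXlt(dt)$hour
  date <- as.Date(dt, tz = "UTC")
  midnight <- hr == 0L
  hr[midnight] <- 24L
  date[midnight] <- date[midnight] - 1L
  out <- data.frame(date = date, hour = hr,
                    temp = as.numeric(x$temperature))
  rng <- range(out$temp, na.rm = TRUE)
  if (rng[1] < -60 || rng[2] > 50)
    warning("temperatures outside the plausible range [-60, 50] degC")
  if ("flag" %in% names(x)) out$flag <- x$flag
  out
}

#' @rdname read_hourly_csv
#' @param x Hourly data.frame (`date`, `hour`, `temp`, optional `flag`).
#' @export
write_hourly_csv <- function(x, path) {
  stopifnot(all(c("date", "hour", "temp") %in% names(x)))
  dt <- as.POSIXct(paste(x$date, "00:00:00"), tz = "UTC") + x$hour * 3600
  out <- data.frame(datetime = format(dt, "%Y-%m-%d %H:%M:%S"),
                    temperature = x$temp)
  if ("flag" %in% names(x)) out$flag <- x$flag
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write daily Tn/Tx CSV
#'
#' Schema: `date` (ISO-8601), `tmin`, `tmax` (degrees C). Rows with
#' `tmin > tmax` are handled per `policy`: `"reject"` (default) aborts with
#' the offending row, `"swap"` exchanges the two values, `"drop"` sets both
#' to missing.
#'
#' @param path File path.
#' @param policy One of `"reject"`, `"swap"`, `"drop"`.
#' @return data.frame with columns `date`, `tmin`, `tmax`.
#' @export
read_daily_csv <- function(path, policy = c("reject", "swap", "drop")) {
  policy <- match.arg(policy)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tmin", "tmax") %in% names(x)))
    stop("daily CSV needs columns 'date', 'tmin', 'tmax': ", path)
  d <- as.Date(x$date)
  bad <- which(is.na(d) & !is.na(x$date))
  if (length(bad))
    stop("unparseable date at line ", bad[1] + 1L, ": '", x$date[bad[1]], "'")
  dup <- which(duplicated(d))
  if (length(dup))
    stop("duplicated date at line ", dup[1] + 1L, ": ", d[dup[1]])
  out <- data.frame(date = d, tmin = as.numeric(x$tmin),
                    tmax = as.numeric(x$tmax))
  inv <- which(out$tmin > out$tmax)
  if (length(inv)) {
    if (policy == "reject")
      stop("tmin > tmax at line ", inv[1] + 1L, " (", out$date[inv[1]], ")")
    if (policy == "swap") {
      tmp <- out$tmin[inv]; out$tmin[inv] <- out$tmax[inv]; out$tmax[inv] <- tmp
    } else {
      out$tmin[inv] <- NA_real_; out$tmax[inv] <- NA_real_
    }
  }
  out[order(out$date), , drop = FALSE]
}

#' @rdname read_daily_csv
#' @param x Daily data.frame (`date`, `tmin`, `tmax`).
#' @export
write_daily_csv <- function(x, path) {
  stopifnot(all(c("date", "tmin", "tmax") %in% names(x)))
  utils::write.csv(x[c("date", "tmin", "tmax")], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write a calibration report as JSON
#'
#' @param result A `calibration_result` from [fit_parameters()] or
#'   [fit_generic()].
#' @param path File path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(list(
    params = list(a = result$params$a, b = result$params$b,
                  c = result$params$c),
    objective = result$objective,
    objective_at_start = result$objective_at_start,
    n_days = result$n_days, n_years = result$n_years,
    sites = as.list(result$sites),
    converged = result$converged, realistic = result$realistic,
    start = list(a = result$start$a, b = result$start$b, c = result$start$c)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Gridded Tn/Tx fields on disk
#'
#' NetCDF interchange for `grid_field` objects, with dimensions
#' (lon, lat, time), variables `tmin`/`tmax` (degrees C) and `elevation`
#' (m), time as days since the first date. Requires the `ncdf4` package.
#' `grid_to_long()` offers a plain-text alternative: one row per
#' (date, cell).
#'
#' @param grid A `grid_field`.
#' @param path File path (`.nc`).
#' @export
write_grid_ncdf <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the 'ncdf4' package is required for NetCDF I/O")
  stopifnot(inherits(grid, "grid_field"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dtim <- ncdf4::ncdim_def("time",
                           paste("days since", format(grid$dates[1])),
                           as.numeric(grid$dates - grid$dates[1]))
  vtmin <- ncdf4::ncvar_def("tmin", "degC", list(dlon, dlat, dtim), -9999)
  vtmax <- ncdf4::ncvar_def("tmax", "degC", list(dlon, dlat, dtim), -9999)
  velev <- ncdf4::ncvar_def("elevation", "m", list(dlon, dlat), -9999)
  nc <- ncdf4::nc_create(path, list(vtmin, vtmax, velev))
  on.exit(ncdf4::nc_close(nc))
  # internal layout is (time, lat, lon); NetCDF wants (lon, lat, time)
  ncdf4::ncvar_put(nc, vtmin, aperm(grid$tmin, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vtmax, aperm(grid$tmax, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, velev, t(grid$elevation))
  invisible(path)
}

#' @rdname write_grid_ncdf
#' @export
read_grid_ncdf <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the 'ncdf4' package is required for NetCDF I/O")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  tunits <- ncdf4::ncatt_get(nc, "time", "units")$value
  origin <- as.Date(sub("days since ", "", tunits))
  dates <- origin + as.numeric(ncdf4::ncvar_get(nc, "time"))
  tmin <- aperm(ncdf4::ncvar_get(nc, "tmin"), c(3, 2, 1))
  tmax <- aperm(ncdf4::ncvar_get(nc, "tmax"), c(3, 2, 1))
  elevation <- t(ncdf4::ncvar_get(nc, "elevation"))
  structure(list(lat = lat, lon = lon, elevation = elevation,
                 dates = dates, tmin = tmin, tmax = tmax),
            class = "grid_field")
}

#' @rdname write_grid_ncdf
#' @return `grid_to_long()`: data.frame with columns `date`, `lat`, `lon`,
#'   `elevation`, `tmin`, `tmax`.
#' @export
grid_to_long <- function(grid) {
  stopifnot(inherits(grid, "grid_field"))
  nd <- length(grid$dates); nlat <- length(grid$lat); nlon <- length(grid$lon)
  data.frame(
    date = rep(grid$dates, times = nlat * nlon),
    lat = rep(rep(grid$lat, each = nd), times = nlon),
    lon = rep(grid$lon, each = nd * nlat),
    elevation = rep(as.vector(grid$elevation), each = nd),
    tmin = as.vector(grid$tmin),
    tmax = as.vector(grid$tmax))
}

#' Write a threshold-date map as long-format CSV
#'
#' One row per cell: `lat`, `lon`, `mean_doy`, `sd_doy`, `n_reached`,
#' `high_elevation`. Cells that never reach the threshold carry empty
#' `mean_doy`/`sd_doy`.
#'
#' @param map A `doy_map` from [map_threshold_dates()].
#' @param path File path.
#' @export
write_doy_map_csv <- function(map, path) {
  stopifnot(inherits(map, "doy_map"))
  nlat <- length(map$lat); nlon <- length(map$lon)
  out <- data.frame(
    lat = rep(map$lat, times = nlon),
    lon = rep(map$lon, each = nlat),
    mean_doy = as.vector(map$mean_doy),
    sd_doy = as.vector(map$sd_doy),
    n_reached = as.vector(map$n_reached),
    high_elevation = as.vector(map$high_elevation))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
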