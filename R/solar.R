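#' Site geometry
#'
#' Describes a station or grid cell for solar computations: latitude drives
#' sunrise/sunset, the longitude offset from the time-zone standard meridian
#' and the equation of time drive the conversion between mean local time and
#' true solar time (TST).
#'
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east.
#' @param standard_meridian Degrees east of the civil time zone's reference
#'   meridian (15 for CET). Must be within 30 degrees of `longitude`.
#' @param elevation Metres above sea level.
#' @return An object of class `site_geometry`.
#' @examples
#' site_geometry(47.5, 7.6, standard_meridian = 15, elevation = 316)
#' @export
site_geometry <- function(latitude, longitude = 0, standard_meridian = longitude,
                          elevation = 0) {
  stopifnot(is.numeric(latitude), length(latitude) == 1L)
  if (latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90], got ", latitude)
  if (abs(longitude - standard_meridian) >= 30)
    stop("longitude is more than 30 degrees from the standard meridian; ",
         "true-solar-time offsets would be implausible")
  structure(
    list(latitude = latitude, longitude = longitude,
         standard_meridian = standard_meridian, elevation = elevation),
    class = "site_geometry")
}

.check_doy <- function(day_of_year) {
  if (any(!is.finite(day_of_year)) ||
      any(day_of_year < 1) || any(day_of_year > 366))
    stop("day_of_year must be in 1..366")
  invisible(day_of_year)
}

# Day angle (radians) used by the Fourier-series declination and equation of
# time below.
.day_angle <- function(day_of_year) 2 * pi * (day_of_year - 1) / 365

#' Solar declination
#'
#' Spencer's Fourier-series declination (accurate to < 0.3 degrees), the form
#' commonly tabulated in solar-engineering references.
#'
#' @param day_of_year Integer day of year, 1..366.
#' @return Declination in radians, bounded by +/- 23.45 degrees.
#' @examples
#' solar_declination(81) # near-zero at the March equinox
#' @export
solar_declination <- function(day_of_year) {
  .check_doy(day_of_year)
  g <- .day_angle(day_of_year)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

#' Equation of time
#'
#' Difference between apparent (sun-dial) and mean solar time, from Spencer's
#' harmonic expansion; bounded within about -14 to +16 minutes over the year.
#'
#' @inheritParams solar_declination
#' @return Minutes (positive when the sun runs ahead of the mean clock).
#' @export
equation_of_time <- function(day_of_year) {
  .check_doy(day_of_year)
  g <- .day_angle(day_of_year)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
}

#' Sunrise and sunset hours in true solar time
#'
#' Computed from the hour angle of the rising/setting sun,
#' `cos H = -tan(lat) tan(decl)`; no refraction or horizon correction is
#' applied. Results are symmetric about TST noon: `sunrise + sunset = 24`.
#'
#' @param geometry A [site_geometry()].
#' @param day_of_year Integer vector, 1..366.
#' @return A data.frame with columns `day_of_year`, `sunrise`, `sunset`,
#'   `daylength` (decimal hours, TST).
#' @examples
#' sunrise_sunset(site_geometry(47), 172)
#' @export
sunrise_sunset <- function(geometry, day_of_year) {
  stopifnot(inherits(geometry, "site_geometry"))
  .check_doy(day_of_year)
  decl <- solar_declination(day_of_year)
  cosH <- -tan(geometry$latitude * pi / 180) * tan(decl)
  if (any(cosH <= -1) || any(cosH >= 1))
    stop("polar day or polar night at latitude ", geometry$latitude,
         ": no sunrise/sunset exists")
  H <- acos(cosH) * 180 / pi  # half daylength, degrees of hour angle
  data.frame(day_of_year = day_of_year,
             sunrise = 12 - H / 15,
             sunset = 12 + H / 15,
             daylength = 2 * H / 15)
}

#' Convert mean local time to true solar time
#'
#' `TST = local + 4 (longitude - standard_meridian) / 60 + EoT / 60`,
#' wrapped into \[0, 24). [tst_to_local()] is the exact inverse.
#'
#' @param local_hour Decimal hours, in \[0, 24).
#' @inheritParams sunrise_sunset
#' @return Decimal hours TST in \[0, 24).
#' @export
local_to_tst <- function(local_hour, geometry, day_of_year) {
  stopifnot(all(local_hour >= 0), all(local_hour < 24))
  off <- 4 * (geometry$longitude - geometry$standard_meridian) / 60 +
    equation_of_time(day_of_year) / 60
  (local_hour + off) %% 24
}

#' @rdname local_to_tst
#' @param tst_hour Decimal hours TST in \[0, 24).
#' @export
tst_to_local <- function(tst_hour, geometry, day_of_year) {
  off <- 4 * (geometry$longitude - geometry$standard_meridian) / 60 +
    equation_of_time(day_of_year) / 60
  (tst_hour - off) %% 24
}

#' Potential daily global radiation
#'
#' Daily extraterrestrial radiation on a horizontal surface scaled by a
#' constant clear-sky transmissivity. Used as the denominator of the
#' observed/potential radiation ratio that classifies clear-sky days; the
#' transmissivity is a free, documented knob (default 0.75) because the
#' classification only needs a consistent reference, not an atmospheric model.
#'
#' @inheritParams sunrise_sunset
#' @param transmissivity Fraction of extraterrestrial radiation reaching the
#'   ground on a cloud-free day, in (0, 1\].
#' @return MJ m^-2 d^-1; zero (with a warning) in polar night.
#' @export
potential_daily_radiation <- function(geometry, day_of_year,
                                      transmissivity = 0.75) {
  stopifnot(transmissivity > 0, transmissivity <= 1)
  .check_doy(day_of_year)
  decl <- solar_declination(day_of_year)
  lat <- geometry$latitude * pi / 180
  cosH <- -tan(lat) * tan(decl)
  polar_night <- cosH >= 1
  if (any(polar_night))
    warning("polar night: potential radiation set to 0")
  ws <- acos(pmin(1, pmax(-1, cosH)))  # sunset hour angle, radians
  gsc <- 1367                          # solar constant, W m^-2
  e0 <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)  # eccentricity factor
  h0 <- (24 * 3600 / pi) * gsc * e0 *
    (cos(lat) * cos(decl) * sin(ws) + ws * sin(lat) * sin(decl)) / 1e6
  h0[polar_night] <- 0
  transmissivity * h0
}
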