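test_that("sunset temperature reduces to the day-branch closed form", {
  times <- list(sunrise = 6, sunset = 18)
  # a = c = 0: sine argument is pi at sunset, so T_S collapses to Tn.
  # (b is irrelevant to the day branch.)
  p0 <- model_params(a = 1e-12, b = 3, c = 0)
  expect_equal(sunset_temperature(p0, 10, 20, 6, 18), 10, tolerance = 1e-6)
  # zero amplitude
  p <- params_generic()
  expect_equal(sunset_temperature(p, 15, 15, 6, 18), 15)
  # independent transcription of the sine expression at h = sunset
  expected <- 10 + (20 - 10) *
    sin(pi * (18 - 6 - 0.75) / (18 - 6 + 2 * 2.71 - 2 * 0.75))
  expect_equal(sunset_temperature(p, 10, 20, 6, 18), expected,
               tolerance = 1e-12)
  expect_error(sunset_temperature(p, 20, 10, 6, 18), "tn > tx")
  expect_error(sunset_temperature(model_params(2, 3, 3.9), 10, 20, 12, 15),
               "degenerate")
})

test_that("the curve is forced through the daily extremes for random
           parameters and forcings", {
  set.seed(42)
  g <- swiss_geometry()
  for (k in 1:25) {
    p <- model_params(runif(1, 0, 4), runif(1, 1, 6), runif(1, 0, 2))
    daily <- mild_daily(5, tn = runif(1, -5, 12), tx = runif(1, 14, 30),
                        jitter = 2, seed = k)
    f <- build_forcing(daily, g)
    r <- f[3, ]
    expect_equal(hourly_temperature(p, r, r$sunrise + p$c), r$tn,
                 tolerance = 1e-9)
    expect_equal(hourly_temperature(p, r, (r$sunrise + r$sunset) / 2 + p$a),
                 r$tx, tolerance = 1e-9)
    # branch agreement at both boundaries
    eps <- 1e-9
    expect_equal(hourly_temperature(p, r, r$sunrise + p$c - eps),
                 hourly_temperature(p, r, r$sunrise + p$c), tolerance = 1e-6)
    expect_equal(hourly_temperature(p, r, r$sunset + eps),
                 hourly_temperature(p, r, r$sunset), tolerance = 1e-6)
  }
})

test_that("the evening branch matches an independent transcription of the
           closed form", {
  # transcribed directly from the piecewise definition, kept independent of
  # the package internals
  a <- 2.71; b <- 3.14; cc <- 0.75
  tn <- 10; tx <- 22; tn_next <- 12
  hr <- 6; hs <- 18; hs_prev <- 18; hr_next <- 6
  ts <- tn + (tx - tn) * sin(pi * (hs - hr - cc) / (hs - hr + 2 * a - 2 * cc))
  n2 <- hr_next - hs + cc + 24
  t <- 23 - hs
  expected <- tn_next + (ts - tn_next) * (exp(-b * t / n2) - (t / n2) * exp(-b))
  f <- list(tn = tn, tx = tx, tn_next = tn_next, tn_prev = tn, tx_prev = tx,
            sunrise = hr, sunset = hs, sunrise_prev = hr, sunset_prev = hs_prev,
            sunrise_next = hr_next)
  got <- hourly_temperature(params_generic(), f, 23)
  expect_equal(got, expected, tolerance = 1e-12)
  # the literal (unscaled) night correction misses the minimum on purpose
  got_lit <- hourly_temperature(params_generic(), f, 23, night_form = "literal")
  expect_false(isTRUE(all.equal(got, got_lit)))
})

test_that("only the factored night form passes exactly through the minimum", {
  g <- swiss_geometry()
  f <- build_forcing(mild_daily(5, tn = 8, tx = 24), g)[3, ]
  p <- params_generic()
  at_min <- function(form) hourly_temperature(p, f, f$sunrise + p$c - 1e-12,
                                              night_form = form)
  expect_equal(at_min("factored"), f$tn, tolerance = 1e-6)
  expect_gt(abs(at_min("literal") - f$tn), 1e-3)
})

test_that("simulated series are continuous across midnight and periodic
           under constant forcing", {
  p <- params_generic()
  # constant forcing: exactly 24-hour periodic after day 1. At the equator
  # sunrise/sunset are fixed at 6/18 all year, so the recursion has a true
  # fixed point (elsewhere the slow drift of the solar times perturbs it).
  g0 <- site_geometry(0)
  sim <- simulate_series(p, mild_daily(6), g0)
  m <- matrix(sim$temp, nrow = 24)
  for (d in 3:5) expect_equal(m[, d], m[, d - 1], tolerance = 1e-9)
  # zero amplitude: flat series
  flat <- simulate_series(p, mild_daily(4, tn = 12, tx = 12), g0)
  expect_equal(flat$temp, rep(12, 96))
  g <- swiss_geometry()
  # midnight continuity on a varying series: T(24) of day i must equal
  # T(0) of day i+1
  daily <- clean_station(years = 1, seed = 3)$daily
  both <- simulate_series(p, daily, g, hours = c(0, 24))
  t24 <- both$temp[both$hour == 24][-nrow(daily)]
  t0 <- both$temp[both$hour == 0][-1]
  expect_lt(max(abs(t24 - t0)), 1e-9)
})

test_that("dense-grid extrema sit at the forced-through points; the hourly
           grid only adds bounded discretisation error", {
  stn <- clean_station(years = 1, seed = 7)
  p <- params_generic(); g <- stn$geometry
  f <- build_forcing(stn$daily, g)
  days <- seq(30, 330, by = 50)
  # exact extrema at sunrise + c and mid-day + a
  for (i in days) {
    r <- f[i, ]
    expect_equal(hourly_temperature(p, r, r$sunrise + p$c), r$tn,
                 tolerance = 1e-9)
    expect_equal(hourly_temperature(p, r, (r$sunrise + r$sunset) / 2 + p$a),
                 r$tx, tolerance = 1e-9)
  }
  # 1-minute dense oracle bounds the discretisation error of the 1:24 grid
  sub <- stn$daily[60:80, ]
  dense <- simulate_series(p, sub, g, hours = seq(1 / 60, 24, by = 1 / 60))
  hourly <- simulate_series(p, sub, g)
  dmin <- tapply(dense$temp, dense$date, min)
  dmax <- tapply(dense$temp, dense$date, max)
  hmin <- tapply(hourly$temp, hourly$date, min)
  hmax <- tapply(hourly$temp, hourly$date, max)
  expect_true(all(hmin >= dmin - 1e-9))
  expect_true(all(hmax <= dmax + 1e-9))
  expect_lt(max(hmin - dmin), 0.5)
  expect_lt(max(dmax - hmax), 0.5)
})

test_that("raising the daily maximum warms every daytime hour", {
  g <- swiss_geometry()
  f <- build_forcing(mild_daily(3), g)[2, ]
  f2 <- f; f2$tx <- f$tx + 2; f2$tx_prev <- f$tx_prev + 2
  p <- params_generic()
  h <- seq(f$sunrise + p$c + 0.1, f$sunset - 0.1, by = 0.25)
  expect_true(all(hourly_temperature(p, f2, h) > hourly_temperature(p, f, h)))
})

test_that("edge days are flagged, gaps rejected, missing days propagated", {
  g <- swiss_geometry()
  daily <- mild_daily(5)
  sim <- simulate_series(params_generic(), daily, g)
  expect_setequal(unique(sim$flag[sim$date == daily$date[1]]), "edge")
  expect_setequal(unique(sim$flag[sim$date == daily$date[5]]), "edge")
  expect_setequal(unique(sim$flag[sim$date == daily$date[3]]), "ok")
  gappy <- daily[-3, ]
  expect_error(simulate_series(params_generic(), gappy, g), "gaps")
  daily$tmin[3] <- NA
  sim2 <- simulate_series(params_generic(), daily, g)
  expect_true(all(is.na(sim2$temp[sim2$date == daily$date[3]])))
  expect_setequal(unique(sim2$flag[sim2$date == daily$date[3]]), "missing")
  # neighbours of the missing day fall back to same-day surrogates
  expect_true(all(!is.na(sim2$temp[sim2$date == daily$date[4]])))
})

test_that("daily extremes round-trip from hourly records", {
  stn <- clean_station(years = 1, seed = 5)
  d <- daily_from_hourly(stn$hourly)
  expect_equal(nrow(d), nrow(stn$daily))
  # the hourly grid lands within an hour of the forced extremes, so the
  # re-extracted maximum trails the generating one by at most the sine's
  # curvature over half an hour; night hours may exceed it only when the
  # previous day was warmer (the decay starts from that day's sunset value)
  tx <- stn$daily$tmax
  tx_prev <- c(tx[1], tx[-length(tx)])
  tn <- stn$daily$tmin
  tn_next <- c(tn[-1], tn[length(tn)])
  expect_true(all(d$tmax > tx - 0.5))
  # night hours are bracketed by the sunset value they start from and the
  # minimum they relax towards, so only a warmer neighbour can lift them
  # past the day's own maximum
  expect_true(all(d$tmax < pmax(tx, tx_prev, tn_next) + 1e-9))
  # the minimum is pinned at sunrise + c; the sampled value sits just above
  # it, unless a colder following day pulls the late evening lower
  expect_true(all(d$tmin < stn$daily$tmin + 0.5))
})
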