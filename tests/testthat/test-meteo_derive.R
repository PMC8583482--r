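test_that("vapour pressure follows the Antoine relation", {
  expect_equal(vapour_pressure(20, 0), 0)
  # direct high-precision evaluation: 0.1 * 0.5 * exp(18.965 - 4030/255)
  expect_equal(vapour_pressure(20, 50), 0.05 * exp(18.965 - 4030 / 255), tolerance = 1e-12)
  expect_equal(round(vapour_pressure(20, 50), 2), 1.18)
  expect_error(vapour_pressure(-240, 50), class = "thermindex_domain_error")
})

test_that("vapour pressure is monotone in temperature and humidity", {
  t <- seq(-30, 45, by = 5)
  expect_true(all(diff(vapour_pressure(t, 80)) > 0))
  rh <- seq(0, 100, by = 10)
  expect_true(all(diff(vapour_pressure(25, rh)) > 0))
  expect_gt(vapour_pressure(30, 80), vapour_pressure(20, 80))
})

test_that("2 m wind is the exact quarter-power scaling of the 10 m wind", {
  expect_equal(wind_at_2m(0), 0)
  expect_equal(wind_at_2m(1), 0.2^0.25, tolerance = 1e-12)
  expect_equal(round(wind_at_2m(1), 2), 0.67) # printed rounding
  expect_equal(wind_at_2m(3), 3 * 0.2^0.25, tolerance = 1e-12)
  # linearity: factor identical for any speed
  v <- c(0.3, 1.7, 9.2)
  expect_equal(wind_at_2m(v) / v, rep(0.2^0.25, 3), tolerance = 1e-12)
  expect_error(wind_at_2m(-1), class = "thermindex_domain_error")
})

test_that("cloud transmittance spans clear sky down to the 8-octa floor", {
  expect_equal(cloud_transmittance(0), 1)
  expect_equal(cloud_transmittance(8), 0.25)
  expect_equal(cloud_transmittance(4), 1 - 0.75 * 0.5^3.4, tolerance = 1e-12)
  n <- 0:8
  tr <- cloud_transmittance(n)
  expect_true(all(tr >= 0.25 & tr <= 1))
  expect_true(all(diff(tr) < 0))
  expect_error(cloud_transmittance(9), class = "thermindex_domain_error")
})

test_that("suggested indoor humidity preserves outdoor moisture content", {
  pv <- vapour_pressure(20, 50)
  expect_equal(suggested_indoor_rh(20, pv), 50, tolerance = 1e-9)
  expect_lt(suggested_indoor_rh(25, pv), 50)
  expect_equal(suggested_indoor_rh(10, vapour_pressure(20, 100)), 100) # capped
})

test_that("solar geometry has almanac-consistent distance and zenith limits", {
  # Earth-Sun distance bounds hold across a full year
  times <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + (0:365) * 86400
  sp <- solar_position(0, 0, times)
  expect_true(all(sp$d_solar >= 0.983 & sp$d_solar <= 1.017))
  expect_true(all(sp$cza >= -1 & sp$cza <= 1))
  # perihelion (early January) closer than aphelion (early July)
  expect_lt(sp$d_solar[3], sp$d_solar[184])

  # equator, equinox, local solar noon: sun nearly overhead
  eq <- solar_position(0, 0, as.POSIXct("2021-03-20 12:07:00", tz = "UTC"))
  expect_gt(eq$cza, 0.995)

  # midnight: sun below horizon, zero radiation after the clamp
  night <- solar_position(48, 10, as.POSIXct("2021-06-21 00:00:00", tz = "UTC"))
  expect_lt(night$elevation_deg, 0)
  expect_equal(solar_radiation(night$cza, night$d_solar)$q_solar, 0)
})

test_that("solar elevation agrees with an independent ephemeris within 2 degrees", {
  sites <- list(c(69.6, 18.9), c(52.1, 5.1), c(40.4, -3.7), c(0, 0), c(-33.9, 151.2))
  offsets <- outer(seq(0, 360, by = 30) * 86400, c(0, 6, 12, 18) * 3600, "+")
  times <- as.POSIXct("2021-01-05 00:00:00", tz = "UTC") + as.vector(offsets)
  for (s in sites) {
    ours <- solar_position(s[1], s[2], times)$elevation_deg
    ref <- vapply(times, function(tt) ref_solar_elevation(s[1], s[2], tt), numeric(1))
    expect_lt(max(abs(ours - ref)), 2)
  }
})

test_that("surface radiation is bounded by the atmospheric maximum", {
  times <- as.POSIXct("2021-06-21 00:00:00", tz = "UTC") + seq(0, 86400 * 30, by = 7200)
  sp <- solar_position(35, 20, times)
  sr <- solar_radiation(sp$cza, sp$d_solar)
  expect_true(all(sr$q_solar >= 0))
  expect_true(all(sr$q_solar <= 1367 * 0.85 / sp$d_solar^2 + 1e-9))
  # linearity in cza
  half <- solar_radiation(0.5, 1)
  full <- solar_radiation(1, 1)
  expect_equal(half$q_solar_toa, full$q_solar_toa / 2)
  expect_equal(full$q_solar_toa, 1367)
  expect_equal(full$q_solar, 1161.95)
  expect_equal(solar_radiation(-0.3, 1)$q_solar, 0)
})

test_that("derive_meteo appends consistent derived columns", {
  f <- synthetic_forecast("temperate", seed = 1)
  m <- derive_meteo(f)
  expect_true(all(c("pv_air", "v2", "q_solar", "q_solar_toa", "transmittance", "cza") %in% names(m)))
  expect_true(all(m$pv_air >= 0))
  expect_true(all(m$v2 <= m$v10))
  expect_true(all(m$transmittance >= 0.25 & m$transmittance <= 1))
})
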