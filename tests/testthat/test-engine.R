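mk_sample <- function(t_air, v10 = 2, rh = 60, cloud = 4,
                      time = as.POSIXct("2021-07-15 12:00:00", tz = "UTC"),
                      lat = 40.4, lon = -3.7) {
  tibble::tibble(
    time = time, t_air = t_air, rh = rh, p_air = 101.3, v10 = v10,
    cloud = cloud, rain = 0, snow = 0, lat = lat, lon = lon
  )
}

test_that("mode dispatch: hot, cold-paradox and indoor", {
  ctx <- thermal_context(person_profile(), "moderate", "summer")
  hot <- assess_sample(mk_sample(38, rh = 40, cloud = 0), ctx)
  expect_equal(hot$mode, "heat")
  expect_gte(hot$index, 1)
  expect_false(is.null(hot$phs))

  # arctic, heavily dressed, working hard: cold mode with a positive index
  # plus simultaneous frostbite warning
  ctx2 <- thermal_context(person_profile(), "very-high", "extreme-winter")
  cold <- assess_sample(
    mk_sample(-5,
      v10 = 6, cloud = 8, lat = 69.6, lon = 18.9,
      time = as.POSIXct("2021-01-15 12:00:00", tz = "UTC")
    ),
    ctx2
  )
  expect_equal(cold$mode, "cold")
  expect_gt(cold$index, 0)
  expect_true("frostbite_risk" %in% cold$notifications$code)

  ctxi <- thermal_context(person_profile(), "low", "casual",
    indoor = indoor_environment(22, rh = 50)
  )
  ind <- assess_sample(mk_sample(0), ctxi)
  expect_equal(ind$mode, "indoor")
  expect_equal(ind$index, ind$indoor$pmv)
})

test_that("every sample gets exactly one mode and a bounded index", {
  ctx <- thermal_context(person_profile(), "moderate", "casual")
  for (ta in seq(-30, 45, by = 5)) {
    a <- assess_sample(mk_sample(ta), ctx)
    expect_true(a$mode %in% c("heat", "cold"))
    expect_true(a$index >= -4 && a$index <= 4)
    # exactly the sub-result matching the mode is present
    if (a$mode == "heat") expect_null(a$cold) else expect_false(is.null(a$cold))
  }
})

test_that("notification gates fire exactly per the decision-tree rules", {
  # cold side: windchill 2 degC below air -> wind stopper; below 0 -> frostbite
  ctx <- thermal_context(person_profile(), "low", "winter")
  a <- assess_sample(
    mk_sample(-5, v10 = 7, time = as.POSIXct("2021-01-15 12:00:00", tz = "UTC"), lat = 69.6, lon = 18.9),
    ctx
  )
  expect_equal(a$mode, "cold")
  expect_true(all(c("wind_stopper", "frostbite_risk") %in% a$notifications$code))
  expect_true(a$cold$t_windchill <= -5 - 2)

  # calm mild cold: neither gate fires
  b <- assess_sample(
    mk_sample(6, v10 = 0.5, time = as.POSIXct("2021-01-15 12:00:00", tz = "UTC"), lat = 69.6, lon = 18.9),
    ctx
  )
  expect_false(any(c("wind_stopper", "frostbite_risk") %in% b$notifications$code))

  # heat side: HRL in the approach band emits the approach code;
  # CAV <= 0 and low activity suppress clothing/rescheduling tips
  ctx_light <- thermal_context(person_profile(), "low", "summer")
  h <- assess_sample(mk_sample(36, rh = 45, cloud = 0), ctx_light)
  expect_equal(h$mode, "heat")
  expect_false("reduce_clothing" %in% h$notifications$code) # summer CAV < 0
  expect_false("reschedule_work" %in% h$notifications$code)
  expect_true("hydrate" %in% h$notifications$code)
  if (h$heat$hrl > 0.8 && h$heat$hrl < 1.0) {
    expect_true("heat_alert_approaching" %in% h$notifications$code)
  }

  # heavy clothing and very high activity flip the gates
  ctx_heavy <- thermal_context(person_profile(), "very-high", "double-layer")
  h2 <- assess_sample(mk_sample(34, rh = 45, cloud = 0), ctx_heavy)
  expect_true(all(c("reduce_clothing", "reschedule_work", "use_fans", "cooling_vest")
  %in% h2$notifications$code))
})

test_that("notification texts exist for every emitted code and audience", {
  ctxs <- list(
    thermal_context(person_profile(profile = "personal"), "very-high", "double-layer"),
    thermal_context(person_profile(profile = "senior-caregiver"), "very-high", "double-layer"),
    thermal_context(person_profile(profile = "child-caregiver"), "low", "winter")
  )
  samples <- list(mk_sample(38, cloud = 0), mk_sample(38, cloud = 0), mk_sample(-10, v10 = 8))
  for (i in seq_along(ctxs)) {
    a <- assess_sample(samples[[i]], ctxs[[i]])
    for (j in seq_len(nrow(a$notifications))) {
      txt <- notification_text(
        a$notifications$code[j], a$notifications$audience[j],
        a$notifications$param[j]
      )
      expect_true(nzchar(txt))
    }
  }
  expect_error(notification_text("no_such_code"), class = "thermindex_usage_error")
})

test_that("forecast assessment flags exactly the constructed windows", {
  ctx <- thermal_context(person_profile(), "moderate", "summer")
  temperate <- assess_forecast(synthetic_forecast("temperate", seed = 1), ctx)
  expect_equal(nrow(flag_windows(temperate)), 0)

  hw <- synthetic_forecast("heatwave", seed = 1)
  heat <- assess_forecast(hw, ctx)
  w <- flag_windows(heat)
  expect_gte(nrow(w), 1)
  peak_time <- heat$time[which.max(heat$index)]
  expect_true(any(peak_time >= w$start & peak_time <= w$end))
})

test_that("peak cold strain can decouple from the air-temperature minimum", {
  # evening gale: coldest hour is calm, the windiest hour is milder
  f <- synthetic_forecast("arctic", seed = 1, overrides = list(cloud = 8))
  f$t_air <- c(-18, -16, -14, -12, -10, -9, -10, -11, -12)
  f$v10 <- c(0.5, 0.5, 0.5, 0.5, 1, 10, 12, 10, 8)
  ctx <- thermal_context(person_profile(), "low", "winter")
  a <- assess_forecast(f, ctx)
  expect_false(which.min(a$index) == which.min(a$t_air))
})

test_that("tidy and glance summarise assessments", {
  ctx <- thermal_context(person_profile(), "moderate", "casual")
  a <- assess_sample(mk_sample(30), ctx)
  td <- tidy(a)
  expect_equal(nrow(td), 1)
  expect_true(all(c("time", "mode", "index", "wbgt", "hrl", "notifications") %in% names(td)))
  g <- glance(a)
  expect_equal(g$mode, a$mode)
  expect_equal(g$n_notifications, nrow(a$notifications))
})

test_that("autoplot returns ggplot objects for both result types", {
  ctx <- thermal_context(person_profile(), "moderate", "summer")
  af <- assess_forecast(synthetic_forecast("heatwave", seed = 1), ctx)
  expect_s3_class(ggplot2::autoplot(af), "ggplot")
  g <- sensitivity_grid(t_air = c(0, 20, 40), activities = c("low", "high"))
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
})

test_that("sensitivity grid reproduces the qualitative design claims", {
  light <- sensitivity_grid(t_air = seq(-20, 45, by = 5))
  expect_true(all(light$index >= -4 & light$index <= 4))

  # acclimatisation shifts the onset of the heat band upward
  acc <- sensitivity_grid(t_air = seq(-20, 45, by = 5), acclimatised = TRUE)
  onset <- function(g, lvl) {
    heat_rows <- g$t_air[g$activity == lvl & g$mode == "heat"]
    if (length(heat_rows) == 0) Inf else min(heat_rows)
  }
  expect_gte(onset(acc, "moderate"), onset(light, "moderate"))
  expect_gte(onset(acc, "high"), onset(light, "high"))

  # winter attire removes cold-band indices at 0..10 degC for >= moderate work
  winter <- sensitivity_grid(
    t_air = seq(-20, 45, by = 5),
    clothing = clothing_ensemble(icl = clo_to_si(1.5), im_st = 0.38, p_air_perm = 5)
  )
  sel <- function(g) {
    g$index[g$t_air %in% c(0, 5, 10) &
      g$activity %in% c("moderate", "high", "very-high")]
  }
  expect_true(all(sel(winter) > sel(light)))
  expect_true(all(sel(winter) > -1))

  # within the heat regime each activity column is non-decreasing in t_air
  for (lvl in c("moderate", "high")) {
    hx <- light[light$activity == lvl & light$mode == "heat", ]
    hx <- hx[order(hx$t_air), ]
    if (nrow(hx) > 1) expect_true(all(diff(hx$index) >= -1e-9))
  }
})

test_that("perception is echoed but never alters the index", {
  ctx0 <- thermal_context(person_profile(), "moderate", "casual")
  ctx3 <- thermal_context(person_profile(), "moderate", "casual", perception = 3)
  a0 <- assess_sample(mk_sample(30), ctx0)
  a3 <- assess_sample(mk_sample(30), ctx3)
  expect_equal(a0$index, a3$index)
  expect_equal(a3$perception, 3)
})
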