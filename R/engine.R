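# Orchestration: per-sample assessment with worst-case radiation policy
# (heat path ignores clouds; cold path assumes full 8-octa overcast),
# heat/cold/indoor mode dispatch, decision-tree advice codes, 24 h
# forecast flagging and the temperature-by-activity sensitivity grid.

#' Engine settings
#'
#' @param heat_handover_hrl Heat mode is entered when the Heat Risk Level
#'   reaches this value (the first WBGT alert band, 0.8, by default);
#'   below it the cold path (IREQ, stretched upward in temperature) rules.
#' @param phs_duration_min Simulated shift length for the PHS panel.
#' @param fan_activity_min,vest_activity_min Minimum activity level
#'   gating the fan / cooling-vest advice codes.
#' @param flag_threshold Absolute index value above which forecast windows
#'   are flagged.
#' @return A list of settings.
#' @export
engine_settings <- function(heat_handover_hrl = 0.8,
                            phs_duration_min = 480,
                            fan_activity_min = "moderate",
                            vest_activity_min = "high",
                            flag_threshold = 2) {
  list(
    heat_handover_hrl = heat_handover_hrl,
    phs_duration_min = phs_duration_min,
    fan_activity_min = fan_activity_min,
    vest_activity_min = vest_activity_min,
    flag_threshold = flag_threshold
  )
}

.activity_rank <- function(level) match(level, .activity_levels)

#' Assess one weather sample
#'
#' Indoor contexts take the PMV path (index = PMV). Outdoor contexts run
#' the heat path on the unattenuated solar load (worst case for sun
#' exposure) and, if the Heat Risk Level stays below the handover
#' threshold, the cold path with a forced 8-octa overcast (worst case for
#' radiative cooling). The resulting index is clamped to \[-4, 4\].
#'
#' @param sample A one-row forecast tibble (or a list with the same
#'   fields).
#' @param context A [thermal_context()].
#' @param settings An [engine_settings()] list.
#' @return A `thermal_assessment` object; see [tidy.thermal_assessment()].
#' @export
assess_sample <- function(sample, context, settings = engine_settings()) {
  stopifnot(inherits(context, "thermal_context"))
  sample <- tibble::as_tibble(sample)[1, ]
  person <- context$person
  activity <- context$activity
  clothing <- context$clothing

  if (!is.null(context$indoor)) {
    env <- context$indoor
    if (is.null(env$rh)) {
      pv_out <- vapour_pressure(sample$t_air, sample$rh)
      env$rh <- suggested_indoor_rh(env$t_air, pv_out)
    }
    ind <- pmv_ppd(env, activity$q_met_wm2, clothing$icl)
    out <- .new_assessment(
      mode = "indoor", index = .clamp(ind$index, -4, 4),
      indoor = ind, sample = sample, context = context, settings = settings
    )
    return(out)
  }

  met <- derive_meteo(sample)

  # heat path: full sun, no cloud attenuation
  globe_heat <- globe_set(
    met$t_air, met$rh, met$v2, met$q_solar, met$p_air,
    cza = met$cza, q_solar_toa = met$q_solar_toa
  )
  heat <- assess_heat(globe_heat, clothing, activity, person)

  if (heat$hrl >= settings$heat_handover_hrl) {
    phs <- run_phs(
      met$t_air, globe_heat$t_mr, met$pv_air, met$v2,
      activity$q_met_wm2, clothing, person,
      duration_min = settings$phs_duration_min,
      v_walk = activity$v_walk
    )
    return(.new_assessment(
      mode = "heat", index = .clamp(heat$index, -4, 4),
      heat = heat, phs = phs, globe = globe_heat,
      sample = sample, context = context, settings = settings
    ))
  }

  # cold path: forced full overcast
  q_cold <- met$q_solar * cloud_transmittance(8)
  globe_cold <- globe_set(
    met$t_air, met$rh, met$v2, q_cold, met$p_air,
    cza = met$cza, q_solar_toa = met$q_solar_toa
  )
  cold <- assess_cold(
    met$t_air, globe_cold$t_mr, met$rh, met$v2, met$v10,
    activity, clothing
  )
  .new_assessment(
    mode = "cold", index = .clamp(cold$index, -4, 4),
    heat = heat, cold = cold, globe = globe_cold,
    sample = sample, context = context, settings = settings
  )
}

.new_assessment <- function(mode, index, sample, context, settings,
                            heat = NULL, cold = NULL, indoor = NULL,
                            phs = NULL, globe = NULL) {
  a <- structure(
    list(
      mode = mode, index = index, heat = heat, cold = cold, indoor = indoor,
      phs = phs, globe = globe, weather_echo = sample,
      perception = context$perception,
      notifications = NULL
    ),
    class = "thermal_assessment"
  )
  a$notifications <- decision_tree(a, context, settings)
  a
}

#' @export
print.thermal_assessment <- function(x, ...) {
  cat(sprintf("<thermal_assessment> mode: %s, index: %+.2f\n", x$mode, x$index))
  if (nrow(x$notifications) > 0) {
    cat("notifications:", paste(x$notifications$code, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Decision-tree advice codes
#'
#' Pure function of an assessment and the personal context. Heat side:
#' an alert-approach note for 0.8 < HRL < 1.0, a clothing-adjustment tip
#' iff CAV > 0, a rescheduling tip iff activity exceeds moderate, a
#' hydration reminder in heat mode, and fan / cooling-vest tips gated on
#' the configured activity levels. Cold side: a wind-stopper tip iff the
#' windchill is at least 2 degC below air temperature, a frostbite notice
#' iff windchill < 0 degC, an underdressed notice carrying the exposure
#' limit in minutes, and a sweat-prevention notice when overdressed.
#' The caregiver profiles only swap advice texts, never the codes' logic.
#'
#' @param assessment A `thermal_assessment`.
#' @param context A [thermal_context()].
#' @param settings An [engine_settings()].
#' @return A tibble with columns `code`, `param`, `audience`.
#' @export
decision_tree <- function(assessment, context, settings = engine_settings()) {
  codes <- character()
  params <- numeric()
  add <- function(code, param = NA_real_) {
    codes <<- c(codes, code)
    params <<- c(params, param)
  }
  act_rank <- .activity_rank(context$activity$level)
  heat <- assessment$heat
  if (assessment$mode == "heat") {
    if (heat$hrl > 0.8 && heat$hrl < 1.0) add("heat_alert_approaching", heat$hrl)
    if (heat$cav > 0) add("reduce_clothing", heat$cav)
    if (act_rank > .activity_rank("moderate")) add("reschedule_work")
    add("hydrate")
    if (act_rank >= .activity_rank(settings$fan_activity_min)) add("use_fans")
    if (act_rank >= .activity_rank(settings$vest_activity_min)) add("cooling_vest")
    if (!is.null(assessment$phs) && assessment$phs$dle_hot < settings$phs_duration_min) {
      add("limit_exposure_heat", assessment$phs$dle_hot)
    }
  }
  cold <- assessment$cold
  if (assessment$mode == "cold") {
    t_air <- assessment$weather_echo$t_air
    if (cold$t_windchill <= t_air - 2) add("wind_stopper", cold$t_windchill)
    if (cold$frostbite_flag) add("frostbite_risk", cold$t_windchill)
    if (assessment$index < -1) add("underdressed_limit_exposure", cold$dle_cold)
    if (assessment$index > 0) add("overdressed_prevent_sweating", assessment$index)
  }
  if (assessment$mode == "indoor") {
    if (assessment$indoor$pmv > 1) add("indoor_warm_discomfort", assessment$indoor$pmv)
    if (assessment$indoor$pmv < -1) add("indoor_cold_discomfort", assessment$indoor$pmv)
  }
  tibble::tibble(
    code = codes,
    param = params,
    audience = rep(context$person$profile, length(codes))
  )
}

.notification_texts <- list(
  personal = c(
    heat_alert_approaching = "Heat stress is approaching the recommended alert limit.",
    reduce_clothing = "Your clothing adds heat stress; lighter, more permeable clothing would help.",
    reschedule_work = "Consider rescheduling intense work to a cooler time of day.",
    hydrate = "Remember to drink regularly.",
    use_fans = "Increased air movement (fans) can help you shed heat.",
    cooling_vest = "A cooling vest can reduce heat strain at this work intensity.",
    limit_exposure_heat = "Limit continuous exposure: core temperature may reach 38 degC in about %d minutes.",
    wind_stopper = "Wind-stopping outer clothing is advised (windchill well below air temperature).",
    frostbite_risk = "Windchill below freezing: protect exposed skin against frostbite.",
    underdressed_limit_exposure = "You are underdressed for these conditions; limit exposure to about %d minutes.",
    overdressed_prevent_sweating = "You are overdressed; avoid sweating into your clothing.",
    indoor_warm_discomfort = "Indoor conditions are on the warm side of comfort.",
    indoor_cold_discomfort = "Indoor conditions are on the cool side of comfort."
  ),
  `senior-caregiver` = c(
    hydrate = "Offer seniors drinks regularly; thirst perception declines with age.",
    reschedule_work = "Plan strenuous care activities for cooler hours.",
    frostbite_risk = "Check that seniors' skin is covered; frostbite risk on exposed skin."
  ),
  `child-caregiver` = c(
    hydrate = "Offer children water often; they dehydrate faster than adults.",
    reschedule_work = "Move active play to shaded areas or cooler hours.",
    frostbite_risk = "Check children's hands and faces; frostbite risk on exposed skin."
  )
)

#' Advice text for a notification code
#'
#' Message catalogue keyed by code and audience; caregiver audiences fall
#' back to the personal text when no tailored variant exists.
#'
#' @param code Notification code.
#' @param audience `"personal"`, `"senior-caregiver"` or
#'   `"child-caregiver"`.
#' @param param Optional numeric payload interpolated into the text.
#' @return A character string.
#' @export
notification_text <- function(code, audience = "personal", param = NA) {
  txt <- .notification_texts[[audience]][code]
  if (is.na(txt)) txt <- .notification_texts$personal[code]
  if (is.na(txt)) {
    rlang::abort(sprintf("unknown notification code '%s'", code),
      class = "thermindex_usage_error"
    )
  }
  if (grepl("%d", txt, fixed = TRUE) && !is.na(param)) {
    txt <- sprintf(txt, round(param))
  }
  unname(txt)
}

#' Assess a full forecast series
#'
#' Runs [assess_sample()] for every 3 h step and returns one tidy row per
#' step.
#'
#' @param forecast A forecast tibble.
#' @param context A [thermal_context()].
#' @param settings An [engine_settings()].
#' @return A tibble of class `thermal_forecast_assessment` with columns
#'   `time`, `mode`, `index`, `t_air`, `v10`, `wbgt`, `hrl`,
#'   `t_windchill`, `dle_min` and a `notifications` list-column.
#' @export
assess_forecast <- function(forecast, context, settings = engine_settings()) {
  validate_forecast(forecast)
  rows <- purrr::map(seq_len(nrow(forecast)), function(i) {
    a <- assess_sample(forecast[i, ], context, settings)
    tidy(a)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("thermal_forecast_assessment", class(out))
  attr(out, "flag_threshold") <- settings$flag_threshold
  out
}

#' Flag high-stress windows in an assessed forecast
#'
#' Contiguous runs where `|index|` exceeds the threshold (default 2) are
#' reported with their start/end times and peak index.
#'
#' @param assessed A [assess_forecast()] result.
#' @param threshold Absolute index threshold.
#' @return A tibble with columns `start`, `end`, `n_samples`,
#'   `peak_index`.
#' @export
flag_windows <- function(assessed, threshold = attr(assessed, "flag_threshold") %||% 2) {
  hot <- abs(assessed$index) > threshold
  if (!any(hot)) {
    return(tibble::tibble(
      start = assessed$time[0], end = assessed$time[0],
      n_samples = integer(), peak_index = numeric()
    ))
  }
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  tibble::tibble(
    start = assessed$time[starts[keep]],
    end = assessed$time[ends[keep]],
    n_samples = runs$lengths[keep],
    peak_index = purrr::map2_dbl(
      starts[keep], ends[keep],
      ~ assessed$index[.x:.y][which.max(abs(assessed$index[.x:.y]))]
    )
  )
}

#' Sensitivity grid of the index over temperature and activity
#'
#' Reproduces the app's sensitivity-analysis design: the index over a grid
#' of air temperatures and activity levels with the absolute humidity
#' fixed at the vapour pressure of 20 degC / 50 percent RH (relative
#' humidity capped at 100 percent at low temperatures), wind 1 m/s, no
#' solar irradiation, for a 1.80 m / 80 kg person.
#'
#' @param t_air Vector of air temperatures, degC.
#' @param activities Vector of activity level keys.
#' @param clothing A [clothing_ensemble()] (or catalogue key).
#' @param acclimatised Logical.
#' @param person A [person_profile()]; defaults to the 1.80 m / 80 kg
#'   reference person with the requested acclimatisation.
#' @param settings An [engine_settings()].
#' @return A tibble of class `thermal_sensitivity_grid` with columns
#'   `t_air`, `activity`, `index`, `mode`.
#' @export
sensitivity_grid <- function(t_air = seq(-20, 45, by = 5),
                             activities = .activity_levels,
                             clothing = clothing_ensemble(icl = clo_to_si(0.6), im_st = 0.38, p_air_perm = 50),
                             acclimatised = FALSE,
                             person = NULL,
                             settings = engine_settings()) {
  if (is.character(clothing)) clothing <- clothing_ensemble(clothing)
  person <- person %||% person_profile(
    height = 180, weight = 80, age = 40, sex = "male",
    acclimatised = acclimatised
  )
  pv_fixed <- vapour_pressure(20, 50)
  grid <- tidyr::expand_grid(t_air = t_air, activity = activities)
  # winter night at mid-latitude: sun below horizon, so no solar load
  base_time <- as.POSIXct("2021-01-15 00:00:00", tz = "UTC")
  rows <- purrr::pmap(grid, function(t_air, activity) {
    rh <- min(100, 100 * pv_fixed / saturation_vapour_pressure(t_air))
    sample <- tibble::tibble(
      time = base_time, t_air = t_air, rh = rh, p_air = 101.325,
      v10 = 1, cloud = 8, rain = 0, snow = 0, lat = 55, lon = 12
    )
    ctx <- thermal_context(person = person, activity = activity, clothing = clothing)
    a <- assess_sample(sample, ctx, settings)
    tibble::tibble(t_air = t_air, activity = activity, index = a$index, mode = a$mode)
  })
  out <- dplyr::bind_rows(rows)
  out$activity <- factor(out$activity, levels = .activity_levels)
  class(out) <- c("thermal_sensitivity_grid", class(out))
  out
}
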