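# Outdoor WBGT components after Liljegren et al.: a 5 cm black globe and a
# naturally ventilated wet wick, each solved from an energy balance between
# radiative gain and convective/evaporative loss. Temperatures inside the
# solvers are Kelvin, pressures in hPa (mb), matching the reference
# parameterisations of air properties.

.lj <- local({
  r_gas <- 8314.34
  m_air <- 28.97
  m_h2o <- 18.015
  cp <- 1003.5
  r_air <- r_gas / m_air
  list(
    stefanb = 5.6696e-8,
    cp = cp, m_air = m_air, m_h2o = m_h2o,
    r_air = r_air,
    pr = cp / (cp + 1.25 * r_air),
    ratio = cp * m_air / m_h2o,
    emis_globe = 0.95, alb_globe = 0.05, diam_globe = 0.05,
    emis_wick = 0.95, alb_wick = 0.4, diam_wick = 0.007, len_wick = 0.0254,
    emis_sfc = 0.999, alb_sfc = 0.45,
    converge = 0.02, max_iter = 500,
    min_speed = 0.13, cza_min = 0.00873, normsolar_max = 0.85
  )
})

# saturation vapour pressure over water, mb (tk in K)
.lj_esat <- function(tk) {
  1.004 * 6.1121 * exp(17.502 * (tk - 273.15) / (tk - 32.18))
}

# dew point (K) from vapour pressure e (mb); closed-form inverse of .lj_esat
.lj_dewpoint <- function(e) {
  x <- log(e / (1.004 * 6.1121))
  273.15 + 240.97 * x / (17.502 - x)
}

# dynamic viscosity of air, kg/(m s)
.lj_viscosity <- function(tk) {
  omega <- (tk / 97 - 2.9) / 0.4 * (-0.034) + 1.048
  2.6693e-6 * sqrt(.lj$m_air * tk) / (3.617^2 * omega)
}

.lj_thermal_cond <- function(tk) {
  (.lj$cp + 1.25 * .lj$r_air) * .lj_viscosity(tk)
}

# diffusivity of water vapour in air, m2/s (p in atm)
.lj_diffusivity <- function(tk, p_atm) {
  pcrit13 <- (36.4 * 218)^(1 / 3)
  tcrit512 <- (132 * 647.3)^(5 / 12)
  tcrit12 <- (132 * 647.3)^0.5
  mmix <- sqrt(1 / .lj$m_air + 1 / .lj$m_h2o)
  0.000364 * (tk / tcrit12)^2.334 * pcrit13 * tcrit512 * mmix / p_atm * 1e-4
}

.lj_h_evap <- function(tk) {
  (313.15 - tk) / 30 * (-71100) + 2.4073e6
}

.lj_emis_atm <- function(tk, rh_frac) {
  0.575 * (rh_frac * .lj_esat(tk))^0.143
}

# convective coefficient, sphere (globe), W/(m2 K)
.lj_h_sphere <- function(tk, p_mb, speed) {
  density <- p_mb * 100 / (.lj$r_air * tk)
  re <- max(speed, .lj$min_speed) * density * .lj$diam_globe / .lj_viscosity(tk)
  nu <- 2 + 0.6 * sqrt(re) * .lj$pr^(1 / 3)
  nu * .lj_thermal_cond(tk) / .lj$diam_globe
}

# convective coefficient, cylinder (wick), W/(m2 K)
.lj_h_cylinder <- function(tk, p_mb, speed) {
  a <- 0.56; b <- 0.281; c <- 0.4
  density <- p_mb * 100 / (.lj$r_air * tk)
  re <- max(speed, .lj$min_speed) * density * .lj$diam_wick / .lj_viscosity(tk)
  nu <- b * re^(1 - c) * .lj$pr^(1 - a)
  nu * .lj_thermal_cond(tk) / .lj$diam_wick
}

# direct-beam fraction of surface solar irradiance from the normalised
# (surface / top-of-atmosphere) irradiance, per the Liljegren scheme
.lj_fdir <- function(normsolar) {
  ifelse(normsolar > 0,
    pmax(0, pmin(0.9, exp(3 - 1.34 * normsolar - 1.65 / normsolar))),
    0
  )
}

.globe_scalar <- function(t_air, v2, q_solar, p_air, cza, fdir, rh) {
  tair <- t_air + 273.15
  p_mb <- p_air * 10
  ea <- .lj_emis_atm(tair, rh / 100)
  cza_eff <- max(cza, .lj$cza_min)
  tsfc <- tair
  tglobe_prev <- tair
  for (i in seq_len(.lj$max_iter)) {
    tref <- 0.5 * (tglobe_prev + tair)
    h <- .lj_h_sphere(tref, p_mb, v2)
    rad <- 0.5 * (ea * tair^4 + .lj$emis_sfc * tsfc^4) -
      h / (.lj$stefanb * .lj$emis_globe) * (tglobe_prev - tair) +
      q_solar / (2 * .lj$stefanb * .lj$emis_globe) * (1 - .lj$alb_globe) *
        (fdir * (1 / (2 * cza_eff) - 1) + 1 + .lj$alb_sfc)
    tglobe <- rad^0.25
    if (abs(tglobe - tglobe_prev) < .lj$converge) {
      return(tglobe - 273.15)
    }
    tglobe_prev <- 0.9 * tglobe_prev + 0.1 * tglobe
  }
  rlang::abort(
    sprintf(
      "globe temperature failed to converge (t_air=%.1f, v2=%.2f, q_solar=%.0f)",
      t_air, v2, q_solar
    ),
    class = "thermindex_numerical_error"
  )
}

.nwb_scalar <- function(t_air, rh, v2, q_solar, p_air, cza, fdir) {
  tair <- t_air + 273.15
  p_mb <- p_air * 10
  tsfc <- tair
  eair <- (rh / 100) * .lj_esat(tair)
  ea <- .lj_emis_atm(tair, rh / 100)
  sza <- acos(pmin(1, pmax(-1, cza)))
  # tan(sza) blows up at the horizon; the reference caps via cza floor
  sza <- min(sza, acos(.lj$cza_min))
  twb_prev <- if (eair > 0) .lj_dewpoint(eair) else tair - 30
  for (i in seq_len(.lj$max_iter)) {
    tref <- 0.5 * (twb_prev + tair)
    h <- .lj_h_cylinder(tref, p_mb, v2)
    density <- p_mb * 100 / (.lj$r_air * tref)
    sc <- .lj_viscosity(tref) / (density * .lj_diffusivity(tref, p_mb / 1013.25))
    fatm <- .lj$stefanb * .lj$emis_wick *
      (0.5 * (ea * tair^4 + .lj$emis_sfc * tsfc^4) - twb_prev^4) +
      (1 - .lj$alb_wick) * q_solar *
        ((1 - fdir) * (1 + 0.25 * .lj$diam_wick / .lj$len_wick) +
          fdir * (tan(sza) / pi + 0.25 * .lj$diam_wick / .lj$len_wick) +
          .lj$alb_sfc)
    ewick <- .lj_esat(twb_prev)
    evap <- .lj_h_evap(twb_prev)
    twb <- tair - evap / .lj$ratio * (ewick - eair) / (p_mb - ewick) *
      (.lj$pr / sc)^0.56 + fatm / h
    if (abs(twb - twb_prev) < .lj$converge) {
      return(twb - 273.15)
    }
    twb_prev <- 0.9 * twb_prev + 0.1 * twb
  }
  rlang::abort(
    sprintf(
      "natural wet bulb failed to converge (t_air=%.1f, rh=%.0f, v2=%.2f, q_solar=%.0f)",
      t_air, rh, v2, q_solar
    ),
    class = "thermindex_numerical_error"
  )
}

#' Black-globe temperature (Liljegren energy balance)
#'
#' Fixed-point solution of the 5 cm black globe energy balance: long-wave
#' and solar radiative gain against convective loss, converged to within
#' 0.02 degC.
#'
#' @param t_air Air temperature, degC.
#' @param v2 Wind speed at 2 m, m/s (floored at 0.13 m/s inside the solver).
#' @param q_solar Total solar irradiance at the surface, W m-2.
#' @param p_air Atmospheric pressure, kPa.
#' @param cza Cosine of the solar zenith angle (used to split the direct
#'   beam over the globe cross-section). Default 1 (sun overhead).
#' @param fdir Direct-beam fraction of `q_solar`; if `NULL`, derived from
#'   `q_solar / q_solar_toa`.
#' @param rh Relative humidity, percent (enters the sky emissivity).
#' @param q_solar_toa Top-of-atmosphere irradiance used to normalise
#'   `q_solar` when deriving `fdir`. Defaults to `q_solar / 0.85`
#'   (clear sky).
#' @return Globe temperature, degC.
#' @export
globe_temperature <- function(t_air, v2, q_solar, p_air = 101.325,
                              cza = 1, fdir = NULL, rh = 50,
                              q_solar_toa = q_solar / 0.85) {
  if (any(v2 < 0)) {
    rlang::abort("`v2` must be >= 0", class = "thermindex_domain_error")
  }
  if (is.null(fdir)) {
    ns <- ifelse(q_solar_toa > 0, pmin(q_solar / q_solar_toa, .lj$normsolar_max), 0)
    fdir <- .lj_fdir(ns)
  }
  unlist(Map(.globe_scalar, t_air, v2, q_solar, p_air, cza, fdir, rh))
}

#' Natural wet-bulb temperature (Liljegren wick energy balance)
#'
#' Iterative solution of the wetted-wick balance: evaporative cooling
#' against convective and radiative gain, converged to within 0.02 degC.
#' At 100 percent humidity with no sun it returns (approximately) the air
#' temperature.
#'
#' @inheritParams globe_temperature
#' @param rh Relative humidity, percent (0-100).
#' @return Natural wet-bulb temperature, degC.
#' @export
natural_wet_bulb <- function(t_air, rh, v2, q_solar, p_air = 101.325,
                             cza = 1, fdir = NULL,
                             q_solar_toa = q_solar / 0.85) {
  if (any(rh < 0 | rh > 100)) {
    rlang::abort("`rh` must lie in [0, 100]", class = "thermindex_domain_error")
  }
  if (is.null(fdir)) {
    ns <- ifelse(q_solar_toa > 0, pmin(q_solar / q_solar_toa, .lj$normsolar_max), 0)
    fdir <- .lj_fdir(ns)
  }
  unlist(Map(.nwb_scalar, t_air, rh, v2, q_solar, p_air, cza, fdir))
}

#' Wet bulb globe temperature
#'
#' The ISO 7243 outdoor weighting: 0.7 natural wet bulb + 0.2 globe +
#' 0.1 air temperature.
#'
#' @param t_nwb Natural wet-bulb temperature, degC.
#' @param t_g Globe temperature, degC.
#' @param t_air Air temperature, degC.
#' @return WBGT, degC.
#' @export
wbgt <- function(t_nwb, t_g, t_air) {
  0.7 * t_nwb + 0.2 * t_g + 0.1 * t_air
}

#' Mean radiant temperature from a globe reading
#'
#' Inverts the globe thermometer balance: the radiant field that, combined
#' with convection at the globe surface, reproduces the observed globe
#' temperature. The convective coefficient takes the larger of the natural
#' (0.4 |tg - ta|^0.25) and forced (2.5 v^0.6) branches.
#'
#' @param t_g Globe temperature, degC.
#' @param t_air Air temperature, degC.
#' @param v2 Wind speed at 2 m, m/s.
#' @return Mean radiant temperature, degC. If the bracket under the fourth
#'   root is negative (extreme cold sky), it is clamped to zero with a
#'   warning.
#' @export
mean_radiant_temperature <- function(t_g, t_air, v2) {
  h_c <- pmax(0.4 * abs(t_g - t_air)^0.25, 2.5 * v2^0.6)
  bracket <- ((t_g + 273) / 100)^4 + h_c * (t_g - t_air)
  if (any(bracket < 0)) {
    rlang::warn("mean radiant temperature bracket negative; clamped to 0")
    bracket <- pmax(bracket, 0)
  }
  100 * bracket^0.25 - 273
}

#' Full globe set for one weather state
#'
#' Runs both Liljegren solvers and derives WBGT (clear and
#' cloud-attenuated) and mean radiant temperature.
#'
#' @inheritParams natural_wet_bulb
#' @param transmittance Cloud transmittance ratio applied to `q_solar` for
#'   the cloud-attenuated variant (see [cloud_transmittance()]).
#' @return A tibble with columns `t_g`, `t_nwb`, `wbgt`, `wbgt_clouds`,
#'   `t_mr`.
#' @export
globe_set <- function(t_air, rh, v2, q_solar, p_air = 101.325, cza = 1,
                      q_solar_toa = q_solar / 0.85, transmittance = 1) {
  t_g <- globe_temperature(t_air, v2, q_solar, p_air,
    cza = cza, rh = rh,
    q_solar_toa = q_solar_toa
  )
  t_nwb <- natural_wet_bulb(t_air, rh, v2, q_solar, p_air,
    cza = cza,
    q_solar_toa = q_solar_toa
  )
  q_cl <- q_solar * transmittance
  t_g_cl <- globe_temperature(t_air, v2, q_cl, p_air,
    cza = cza, rh = rh,
    q_solar_toa = q_solar_toa
  )
  t_nwb_cl <- natural_wet_bulb(t_air, rh, v2, q_cl, p_air,
    cza = cza,
    q_solar_toa = q_solar_toa
  )
  tibble::tibble(
    t_g = t_g,
    t_nwb = t_nwb,
    wbgt = wbgt(t_nwb, t_g, t_air),
    wbgt_clouds = wbgt(t_nwb_cl, t_g_cl, t_air),
    t_mr = mean_radiant_temperature(t_g, t_air, v2)
  )
}
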