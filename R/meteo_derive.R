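#' Water vapour pressure of air (Antoine relation)
#'
#' Partial pressure of water vapour computed from air temperature and
#' relative humidity. This is the evaporative driving force used by the
#' heat-strain and cold models.
#'
#' @param t_air Air temperature, degrees C. Must be above -235 (the pole of
#'   the Antoine relation).
#' @param rh Relative humidity, percent (0-100).
#' @return Vapour pressure in kPa.
#' @examples
#' vapour_pressure(20, 50) # about 1.18 kPa
#' @export
vapour_pressure <- function(t_air, rh) {
  if (any(t_air <= -235)) {
    rlang::abort("`t_air` must be > -235 degC", class = "thermindex_domain_error")
  }
  if (any(rh < 0 | rh > 100)) {
    rlang::abort("`rh` must lie in [0, 100]", class = "thermindex_domain_error")
  }
  0.1 * (rh / 100) * exp(18.965 - 4030 / (t_air + 235))
}

#' Saturation water vapour pressure (Antoine relation)
#'
#' @param t_air Air temperature, degrees C.
#' @return Saturation vapour pressure in kPa.
#' @export
saturation_vapour_pressure <- function(t_air) {
  0.1 * exp(18.965 - 4030 / (t_air + 235))
}

#' Wind speed at 2 m from the 10 m forecast wind
#'
#' Standard weather reports give wind at 10 m; all models except windchill
#' need it at 2 m. Uses the neutral-stability (class D) power-law profile,
#' v2 = v10 * (2/10)^0.25. The exact power form is used throughout; the
#' factor rounds to 0.67.
#'
#' @param v10 Wind speed at 10 m, m/s (non-negative).
#' @return Wind speed at 2 m, m/s.
#' @export
wind_at_2m <- function(v10) {
  if (any(v10 < 0)) {
    rlang::abort("`v10` must be >= 0", class = "thermindex_domain_error")
  }
  v10 * (2 / 10)^0.25
}

#' Cloud transmittance ratio for solar radiation
#'
#' Fraction of clear-sky solar radiation transmitted under a cloud cover of
#' `n_octa` eighths: 1 - 0.75 * (n/8)^3.4. Ranges from 1 (clear) down to
#' 0.25 (full overcast).
#'
#' @param n_octa Cloud cover in octa (0-8).
#' @return Transmittance ratio in \[0.25, 1\].
#' @export
cloud_transmittance <- function(n_octa) {
  if (any(n_octa < 0 | n_octa > 8)) {
    rlang::abort("`n_octa` must lie in [0, 8]", class = "thermindex_domain_error")
  }
  1 - 0.75 * (n_octa / 8)^3.4
}

#' Suggested indoor relative humidity
#'
#' Indoor air warmed (or cooled) from outside retains the outdoor moisture
#' content, so the suggested indoor RH is the ratio of the outdoor vapour
#' pressure to the saturation vapour pressure at the suggested indoor
#' temperature, capped at 100 percent.
#'
#' @param t_indoor Suggested indoor air temperature, degrees C.
#' @param pv_air_outdoor Outdoor water vapour pressure, kPa.
#' @return Relative humidity, percent (capped at 100).
#' @export
suggested_indoor_rh <- function(t_indoor, pv_air_outdoor) {
  pmin(100, 100 * pv_air_outdoor / saturation_vapour_pressure(t_indoor))
}

#' Solar position from coordinates and UTC time
#'
#' Low-precision astronomical-almanac solar ephemeris (mean anomaly, mean
#' longitude, ecliptic longitude, declination, sidereal-time hour angle),
#' accurate to well under a degree of elevation -- ample for radiation
#' modelling. Polar night simply yields a negative elevation.
#'
#' @param lat,lon Latitude / longitude in degrees (lon positive east).
#' @param time A `POSIXct` time (UTC).
#' @return A tibble with columns `elevation_deg`, `cza` (cosine of the
#'   solar zenith angle), `d_solar` (Earth-Sun distance, AU) and
#'   `mean_anomaly_deg`.
#' @export
solar_position <- function(lat, lon, time) {
  stopifnot(inherits(time, "POSIXct"))
  if (any(lat < -90 | lat > 90)) {
    rlang::abort("`lat` must lie in [-90, 90]", class = "thermindex_domain_error")
  }
  deg2rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  d <- jd - 2451545.0
  g <- (357.529 + 0.98560028 * d) %% 360          # mean anomaly
  q <- (280.459 + 0.98564736 * d) %% 360          # mean longitude
  L <- q + 1.915 * sin(g * deg2rad) + 0.020 * sin(2 * g * deg2rad)
  d_solar <- 1.00014 - 0.01671 * cos(g * deg2rad) - 0.00014 * cos(2 * g * deg2rad)
  obliq <- (23.439 - 0.00000036 * d) * deg2rad
  Lr <- L * deg2rad
  dec <- asin(sin(obliq) * sin(Lr))
  ra <- atan2(cos(obliq) * sin(Lr), cos(Lr)) / deg2rad # right ascension, deg
  gmst <- (18.697374558 + 24.06570982441908 * d) %% 24 # hours
  ha <- ((gmst * 15 + lon - ra + 180) %% 360 - 180) * deg2rad
  latr <- lat * deg2rad
  sin_elev <- sin(latr) * sin(dec) + cos(latr) * cos(dec) * cos(ha)
  sin_elev <- pmin(1, pmax(-1, sin_elev))
  tibble::tibble(
    elevation_deg = asin(sin_elev) / deg2rad,
    cza = sin_elev, # cos(zenith) = sin(elevation)
    d_solar = d_solar,
    mean_anomaly_deg = g
  )
}

#' Solar radiation from solar geometry
#'
#' Top-of-atmosphere irradiance on a horizontal surface,
#' `q_solar_toa = 1367 * max(0, cza) / d^2`, and the clear-sky surface
#' irradiance `q_solar = 0.85 * q_solar_toa` (0.85 being the maximum
#' atmospheric transmission). A sun below the horizon contributes zero.
#'
#' @param cza Cosine of the solar zenith angle.
#' @param d_solar Earth-Sun distance in AU.
#' @return A tibble with columns `q_solar_toa` and `q_solar` (W m-2).
#' @export
solar_radiation <- function(cza, d_solar) {
  q_toa <- 1367 * pmax(0, cza) / d_solar^2
  tibble::tibble(q_solar_toa = q_toa, q_solar = 0.85 * q_toa)
}

#' Derive model-grade meteorology for a forecast
#'
#' Adds to a forecast table the variables the thermal models consume:
#' vapour pressure `pv_air`, 2 m wind `v2`, solar geometry (`cza`,
#' `d_solar`, `elevation_deg`), clear-sky solar radiation (`q_solar_toa`,
#' `q_solar`, unattenuated -- the heat path's worst case) and the cloud
#' transmittance `transmittance` for the reported cloud cover.
#'
#' @param forecast A forecast tibble as returned by [read_forecast()] or
#'   [synthetic_forecast()].
#' @return The input tibble with derived columns appended.
#' @export
derive_meteo <- function(forecast) {
  validate_forecast(forecast)
  sp <- solar_position(forecast$lat, forecast$lon, forecast$time)
  sr <- solar_radiation(sp$cza, sp$d_solar)
  dplyr::mutate(
    forecast,
    pv_air = vapour_pressure(.data$t_air, .data$rh),
    v2 = wind_at_2m(.data$v10),
    elevation_deg = sp$elevation_deg,
    cza = sp$cza,
    d_solar = sp$d_solar,
    q_solar_toa = sr$q_solar_toa,
    q_solar = sr$q_solar,
    transmittance = cloud_transmittance(.data$cloud)
  )
}
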