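# Forecast I/O: a 3-hourly JSON forecast dialect mirroring the
# OpenWeatherMap 5-day/3-hour schema (metric units), parsed into a
# validated tibble, plus a deterministic synthetic-forecast generator so
# the whole pipeline is testable offline.

.forecast_cols <- c(
  "time", "t_air", "rh", "p_air", "v10", "cloud", "rain", "snow", "lat", "lon"
)

#' Validate a forecast table
#'
#' Enforces the per-sample invariants (rh in \[0, 100\], non-negative wind,
#' cloud in \[0, 8\] octa, coordinates in range) and the series invariants
#' (strictly increasing, uniformly spaced timestamps).
#'
#' @param forecast A forecast tibble.
#' @param field_prefix Prefix used in error messages (e.g. the file name).
#' @return The input, invisibly, if valid; otherwise an error of class
#'   `thermindex_validation_error`.
#' @export
validate_forecast <- function(forecast, field_prefix = "") {
  miss <- setdiff(.forecast_cols, names(forecast))
  if (length(miss) > 0) {
    rlang::abort(
      sprintf("%smissing mandatory field(s): %s", field_prefix, paste(miss, collapse = ", ")),
      class = "thermindex_schema_error"
    )
  }
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rlang::abort(sprintf("%sinvalid value for %s", field_prefix, what),
        class = "thermindex_validation_error"
      )
    }
  }
  bad(forecast$rh < 0 | forecast$rh > 100, "rh (must be 0-100 %)")
  bad(forecast$v10 < 0, "v10 (must be >= 0 m/s)")
  bad(forecast$cloud < 0 | forecast$cloud > 8, "cloud (must be 0-8 octa)")
  bad(forecast$lat < -90 | forecast$lat > 90, "lat (must be -90..90)")
  bad(forecast$lon <= -180 | forecast$lon > 180, "lon (must be in (-180, 180])")
  bad(forecast$p_air <= 0, "p_air (must be > 0 kPa)")
  if (nrow(forecast) > 1) {
    dt <- diff(as.numeric(forecast$time))
    if (any(dt <= 0)) {
      rlang::abort(paste0(field_prefix, "timestamps must be strictly increasing"),
        class = "thermindex_validation_error"
      )
    }
    if (max(dt) - min(dt) > 1) {
      rlang::abort(paste0(field_prefix, "timestamps must be uniformly spaced"),
        class = "thermindex_validation_error"
      )
    }
  }
  invisible(forecast)
}

#' Read a forecast JSON file
#'
#' Parses the documented 3-hourly JSON dialect (field names mirroring the
#' OpenWeatherMap 5-day/3-hour schema, metric units): one object per step
#' under `list`, each with `dt` (unix UTC), `main.temp` (degC),
#' `main.humidity` (percent), `main.pressure` (hPa), `wind.speed` (m/s, or
#' km/h when the top-level `wind_unit` is "km/h"), `clouds.all` (percent
#' cover), optional `rain.3h` (ml) and `snow.3h` (cm); coordinates under
#' `city.coord`. Units are normalised at the boundary: pressure hPa to
#' kPa, percent cloud cover to the nearest octa.
#'
#' @param path Path to the JSON file.
#' @param dialect Format name; only `"owm3h"` is implemented.
#' @return A validated forecast tibble (one row per 3 h step) with columns
#'   `time`, `t_air`, `rh`, `p_air` (kPa), `v10`, `cloud` (octa), `rain`,
#'   `snow`, `lat`, `lon`.
#' @export
read_forecast <- function(path, dialect = "owm3h") {
  if (dialect != "owm3h") {
    rlang::abort(sprintf("unknown forecast dialect '%s'", dialect),
      class = "thermindex_usage_error"
    )
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("forecast file '%s' does not exist", path),
      class = "thermindex_usage_error"
    )
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(x, field) {
    if (is.null(x)) {
      rlang::abort(sprintf("%s: missing mandatory field '%s'", basename(path), field),
        class = "thermindex_schema_error"
      )
    }
    x
  }
  coord <- need(raw$city$coord, "city.coord")
  lat <- need(coord$lat, "city.coord.lat")
  lon <- need(coord$lon, "city.coord.lon")
  entries <- need(raw$list, "list")
  kmh <- identical(raw$wind_unit, "km/h")
  rows <- purrr::map(entries, function(e) {
    tibble::tibble(
      time = as.POSIXct(need(e$dt, "dt"), origin = "1970-01-01", tz = "UTC"),
      t_air = need(e$main$temp, "main.temp"),
      rh = need(e$main$humidity, "main.humidity"),
      p_air = need(e$main$pressure, "main.pressure") / 10, # hPa -> kPa
      v10 = need(e$wind$speed, "wind.speed") / if (kmh) 3.6 else 1,
      cloud = round(need(e$clouds$all, "clouds.all") / 12.5), # % -> octa
      rain = e$rain$`3h` %||% 0,
      snow = e$snow$`3h` %||% 0,
      lat = lat,
      lon = lon
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_forecast(out, field_prefix = paste0(basename(path), ": "))
  class(out) <- c("thermindex_forecast", class(out))
  out
}

#' Write a forecast table to the JSON dialect
#'
#' Inverse of [read_forecast()]: kPa back to hPa, octa back to percent
#' cloud cover.
#'
#' @param forecast A forecast tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(forecast, path) {
  validate_forecast(forecast)
  entries <- purrr::pmap(forecast, function(time, t_air, rh, p_air, v10, cloud,
                                            rain, snow, lat, lon, ...) {
    list(
      dt = as.numeric(time),
      main = list(temp = t_air, humidity = rh, pressure = p_air * 10),
      wind = list(speed = v10),
      clouds = list(all = cloud * 12.5),
      rain = list(`3h` = rain),
      snow = list(`3h` = snow)
    )
  })
  obj <- list(
    cnt = nrow(forecast),
    list = entries,
    city = list(coord = list(lat = forecast$lat[1], lon = forecast$lon[1]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.scenarios <- list(
  heatwave = list(
    t_mean = 33, t_amp = 4.5, t_range = c(28, 38), rh = c(25, 45),
    v = c(0.5, 3), cloud = c(0, 1), lat = 40.4, lon = -3.7,
    date = "2021-07-15", p_air = 94.5
  ),
  arctic = list(
    t_mean = -15, t_amp = 4.5, t_range = c(-25, -5), rh = c(60, 90),
    v = c(2, 9), cloud = c(4, 8), lat = 69.6, lon = 18.9,
    date = "2021-01-15", p_air = 101.3
  ),
  temperate = list(
    t_mean = 13, t_amp = 4, t_range = c(5, 21), rh = c(50, 85),
    v = c(1, 6), cloud = c(2, 6), lat = 52.1, lon = 5.1,
    date = "2021-04-15", p_air = 101.3
  ),
  `diurnal-cycle` = list(
    t_mean = 20, t_amp = 8, t_range = c(-100, 100), rh = c(40, 70),
    v = c(1, 4), cloud = c(0, 3), lat = 48.2, lon = 16.4,
    date = "2021-06-21", p_air = 101.3
  )
)

#' Generate a synthetic 24 h forecast
#'
#' Deterministic (for a fixed seed) stand-in for the live weather service.
#' Four scenarios are available: `heatwave` (air temperature confined to
#' 28-38 degC, dry, sunny), `arctic` (-25 to -5 degC, windy, overcast),
#' `temperate` (mild mid-latitude spring day) and `diurnal-cycle` (a clean
#' sinusoid on air temperature whose phase follows local solar time:
#' coolest shortly before sunrise, warmest mid-afternoon).
#'
#' @param scenario One of `"heatwave"`, `"arctic"`, `"temperate"`,
#'   `"diurnal-cycle"`.
#' @param seed Integer seed; the same seed always yields the same series.
#' @param n_samples Number of 3 h steps (9 covers 24 h inclusive).
#' @param overrides Named list of per-column constant overrides applied to
#'   every sample (e.g. `list(v10 = 1.0)`).
#' @return A forecast tibble as from [read_forecast()].
#' @export
synthetic_forecast <- function(scenario, seed = 1, n_samples = 9,
                               overrides = list()) {
  if (!scenario %in% names(.scenarios)) {
    rlang::abort(
      sprintf(
        "unknown scenario '%s' (available: %s)", scenario,
        paste(names(.scenarios), collapse = ", ")
      ),
      class = "thermindex_usage_error"
    )
  }
  sc <- .scenarios[[scenario]]
  withr::with_seed(seed, {
    t0 <- as.POSIXct(paste(sc$date, "00:00:00"), tz = "UTC")
    time <- t0 + 3 * 3600 * (seq_len(n_samples) - 1)
    hour_utc <- as.numeric(format(time, "%H", tz = "UTC")) +
      as.numeric(format(time, "%M")) / 60
    solar_hour <- (hour_utc + sc$lon / 15) %% 24
    # diurnal sinusoid: maximum near 15:00 local solar time
    diurnal <- cos(2 * pi * (solar_hour - 15) / 24)
    t_air <- sc$t_mean + sc$t_amp * diurnal + stats::rnorm(n_samples, 0, 0.3)
    t_air <- .clamp(t_air, sc$t_range[1], sc$t_range[2])
    out <- tibble::tibble(
      time = time,
      t_air = t_air,
      rh = .clamp(
        stats::runif(n_samples, sc$rh[1], sc$rh[2]) - 5 * diurnal,
        0, 100
      ),
      p_air = sc$p_air,
      v10 = stats::runif(n_samples, sc$v[1], sc$v[2]),
      cloud = round(stats::runif(n_samples, sc$cloud[1], sc$cloud[2])),
      rain = 0,
      snow = 0,
      lat = sc$lat,
      lon = sc$lon
    )
    for (nm in names(overrides)) {
      if (!nm %in% names(out)) {
        rlang::abort(sprintf("unknown override field '%s'", nm),
          class = "thermindex_usage_error"
        )
      }
      out[[nm]] <- overrides[[nm]]
    }
    validate_forecast(out)
    class(out) <- c("thermindex_forecast", class(out))
    out
  })
}
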