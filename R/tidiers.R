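#' Tidy a thermal assessment into one row
#'
#' @param x A `thermal_assessment`.
#' @param ... Unused.
#' @return A one-row tibble with the index, mode, key sub-model outputs
#'   and a `notifications` list-column.
#' @exportS3Method generics::tidy
tidy.thermal_assessment <- function(x, ...) {
  wx <- x$weather_echo
  tibble::tibble(
    time = wx$time %||% as.POSIXct(NA),
    mode = x$mode,
    index = x$index,
    t_air = wx$t_air,
    v10 = wx$v10 %||% NA_real_,
    wbgt = if (!is.null(x$heat)) x$heat$wbgt else NA_real_,
    wbgt_effective = if (!is.null(x$heat)) x$heat$wbgt_effective else NA_real_,
    hrl = if (!is.null(x$heat)) x$heat$hrl else NA_real_,
    category = if (!is.null(x$heat)) x$heat$category else NA_character_,
    t_windchill = if (!is.null(x$cold)) x$cold$t_windchill else NA_real_,
    icl_neutral = if (!is.null(x$cold)) x$cold$icl_neutral else NA_real_,
    icl_minimal = if (!is.null(x$cold)) x$cold$icl_minimal else NA_real_,
    dle_min = if (x$mode == "cold") {
      x$cold$dle_cold
    } else if (!is.null(x$phs)) {
      x$phs$dle_hot
    } else {
      NA_real_
    },
    sweat_per_hour_g = if (!is.null(x$phs)) x$phs$sweat_per_hour_g else NA_real_,
    pmv = if (!is.null(x$indoor)) x$indoor$pmv else NA_real_,
    ppd = if (!is.null(x$indoor)) x$indoor$ppd else NA_real_,
    notifications = list(x$notifications)
  )
}

#' One-line summary of a thermal assessment
#'
#' @param x A `thermal_assessment`.
#' @param ... Unused.
#' @return A one-row tibble with `mode`, `index` and the notification
#'   count.
#' @exportS3Method generics::glance
glance.thermal_assessment <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    index = x$index,
    n_notifications = nrow(x$notifications)
  )
}

#' Plot an assessed 24 h forecast
#'
#' Index trajectory over the forecast period with the +/- flag thresholds
#' and any flagged high-stress windows shaded.
#'
#' @param object A [assess_forecast()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.thermal_forecast_assessment <- function(object, ...) {
  thr <- attr(object, "flag_threshold") %||% 2
  windows <- flag_windows(object, thr)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$index))
  if (nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.12
    )
  }
  p +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mode)) +
    ggplot2::scale_y_continuous(limits = c(-4, 4)) +
    ggplot2::labs(
      x = NULL, y = "thermal stress index",
      title = "24 h personal thermal stress forecast"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity grid as a heatmap
#'
#' @param object A [sensitivity_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.thermal_sensitivity_grid <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$t_air, y = .data$activity, fill = .data$index)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = 0, limits = c(-4, 4)
    ) +
    ggplot2::labs(
      x = "air temperature (degC)", y = NULL, fill = "index",
      title = "Thermal stress index by temperature and activity"
    ) +
    ggplot2::theme_minimal()
}
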