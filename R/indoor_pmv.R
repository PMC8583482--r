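# Indoor mode: Fanger PMV/PPD heat-balance comfort model (ISO 7730) with
# the app's indoor conventions (mean radiant = air temperature, fixed air
# speeds for open/closed windows). The indoor thermal stress index equals
# the PMV.

.pmv_scalar <- function(ta, tr, vel, rh, met_wm2, icl_si) {
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235)) # Pa
  icl <- icl_si
  m <- met_wm2
  w <- 0
  mw <- m - w
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hcf <- 12.1 * sqrt(vel)
  taa <- ta + 273
  tra <- tr + 273
  # clothing surface temperature by damped fixed-point iteration
  tcla <- taa + (35.5 - ta) / (3.5 * icl + 0.1)
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * mw + p2 * (tra / 100)^4
  xn <- tcla / 100
  xf <- tcla / 50
  n <- 0
  while (abs(xn - xf) > 1.5e-5) {
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa)^0.25
    hc <- max(hcf, hcn)
    xn <- (p5 + p4 * hc - p2 * xf^4) / (100 + p3 * hc)
    n <- n + 1
    if (n > 300) {
      rlang::abort("PMV clothing-temperature iteration failed to converge",
        class = "thermindex_numerical_error"
      )
    }
  }
  tcl <- 100 * xn - 273
  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0
  hl3 <- 1.7e-5 * m * (5867 - pa)
  hl4 <- 0.0014 * m * (34 - ta)
  hl5 <- 3.96 * fcl * (xn^4 - (tra / 100)^4)
  hl6 <- fcl * hc * (tcl - ta)
  ts <- 0.303 * exp(-0.036 * m) + 0.028
  ts * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6)
}

#' Predicted percentage dissatisfied from PMV
#'
#' `PPD = 100 - 95 exp(-0.03353 PMV^4 - 0.2179 PMV^2)`; minimum 5 percent
#' at PMV = 0 and symmetric in the sign of PMV.
#'
#' @param pmv Predicted mean vote.
#' @return PPD, percent.
#' @export
ppd <- function(pmv) {
  100 - 95 * exp(-0.03353 * pmv^4 - 0.2179 * pmv^2)
}

#' Indoor PMV/PPD assessment
#'
#' Fanger whole-body heat-balance comfort model. The indoor thermal stress
#' index is the PMV itself; `|index| <= 0.5` is comfortable and
#' `|index| >= 2` signals significant thermal risk indoors.
#'
#' @param env An [indoor_environment()].
#' @param q_met_wm2 Metabolic rate, W m-2.
#' @param icl Basic clothing insulation, m2 K W-1.
#' @return A one-row tibble with `pmv`, `ppd`, `index` and `valid`
#'   (envelope check: t_air 10-30 degC, met 46-232 W m-2, icl up to 2 Clo).
#' @export
pmv_ppd <- function(env, q_met_wm2, icl) {
  stopifnot(inherits(env, "indoor_environment"))
  rh <- env$rh %||% 50
  pmv <- unlist(Map(
    .pmv_scalar, env$t_air, env$t_mr, env$v_air, rh, q_met_wm2, icl
  ))
  valid <- env$t_air >= 10 & env$t_air <= 30 &
    q_met_wm2 >= 46 & q_met_wm2 <= 232 & icl <= clo_to_si(2)
  tibble::tibble(pmv = pmv, ppd = ppd(pmv), index = pmv, valid = valid)
}

#' Suggested indoor air temperature
#'
#' Advisory adaptive-comfort suggestion: a linear function of the outdoor
#' air temperature (`0.33 t_out + 18.8` degC, the adaptive neutral line for
#' naturally ventilated buildings), clamped to \[17, 30\] degC and shifted
#' by `thermostat_step` degC per thermostat position away from the neutral
#' setting 3. Window state does not change the suggestion. Only values the
#' user actually enters feed the assessment; this is guidance.
#'
#' @param t_air_outdoor Outdoor air temperature, degC.
#' @param thermostat Thermostat position 1-5 (3 = neutral).
#' @param windows_open Logical (unused by the default relation; kept for
#'   the documented interface).
#' @param thermostat_step Degrees per thermostat position, default 1.
#' @return Suggested indoor temperature, degC.
#' @export
suggested_indoor_temperature <- function(t_air_outdoor, thermostat = 3,
                                         windows_open = FALSE,
                                         thermostat_step = 1) {
  if (any(!thermostat %in% 1:5)) {
    rlang::abort("`thermostat` must be 1-5", class = "thermindex_domain_error")
  }
  .clamp(0.33 * t_air_outdoor + 18.8, 17, 30) + (thermostat - 3) * thermostat_step
}
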