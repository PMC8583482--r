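# Cold path: required clothing insulation (IREQ, ISO 11079 heat balance)
# at a thermoneutral and a minimal (high-strain) criterion, the duration
# limit of exposure from the permissible body heat debt, the windchill
# index for exposed-skin risk, and the cold branch of the index.

#' Windchill index
#'
#' JAG/TI-form windchill computed from air temperature and the 10 m wind:
#' `13.12 + 0.6215 T - 11.37 v^0.16 + 0.3965 T v^0.16`. The 0.16 power
#' doubles as the 10 m to 2 m wind scaling, so the 10 m wind in m/s enters
#' directly. Below the 1.34 m/s validity floor the air temperature is
#' returned; above it the result is additionally capped at the air
#' temperature so light winds can never "warm" the skin.
#'
#' @param t_air Air temperature, degC.
#' @param v10 Wind speed at 10 m, m/s.
#' @return Windchill temperature, degC.
#' @examples
#' windchill(-12, 5) # about -15.2
#' @export
windchill <- function(t_air, v10) {
  if (any(v10 < 0)) {
    rlang::abort("`v10` must be >= 0", class = "thermindex_domain_error")
  }
  raw <- 13.12 + 0.6215 * t_air - 11.37 * v10^0.16 + 0.3965 * t_air * v10^0.16
  ifelse(v10 < 1.34, t_air, pmin(raw, t_air))
}

# saturation vapour pressure, kPa, ISO 11079 coefficients (t in degC)
.ireq_psat <- function(t) 0.1333 * exp(18.6686 - 4030.183 / (t + 235))

# convective coefficient used in the cold heat balance
.ireq_hc <- function(v) ifelse(v < 1, 3.5 + 5.2 * v, 8.7 * v^0.6)

# skin temperature / skin wetness criteria, by strain level
.ireq_criteria <- function(m, strain = c("neutral", "minimal")) {
  strain <- match.arg(strain)
  if (strain == "neutral") {
    list(t_sk = 35.7 - 0.0285 * m, wetness = 0.001 * m)
  } else {
    list(t_sk = 33.34 - 0.0354 * m, wetness = 0.06)
  }
}

# resultant-to-basic insulation correction for wind and motion:
# wind penetration scales with the ensemble's air permeability p (L m-2 s-1)
.ireq_wind_corr <- function(v, w, p_air_perm) {
  0.54 * exp(-0.15 * v - 0.22 * w) * p_air_perm^0.075 - 0.06 * log(p_air_perm) + 0.5
}

# heat-balance residual M - W - E - Hres - R - C - S for clothing
# insulation `icl_si` (resultant, m2 K W-1) and storage rate S (W m-2)
.ireq_balance <- function(icl_si, s, m, w_ext, t_air, t_mr, pa, v, crit, i_a_r) {
  t_ex <- 29 + 0.2 * t_air
  p_ex <- .ireq_psat(t_ex)
  p_sks <- .ireq_psat(crit$t_sk)
  h_res <- 1.73e-2 * m * (p_ex - pa) + 1.4e-3 * m * (t_ex - t_air)
  r_t <- (0.06 / 0.38) * (i_a_r + icl_si)
  e <- crit$wetness * (p_sks - pa) / r_t
  t_cl <- crit$t_sk - icl_si * (m - w_ext - e - h_res - s)
  f_cl <- 1 + 1.197 * icl_si
  dt_r <- t_cl - t_mr
  h_r <- if (abs(dt_r) > 1e-9) {
    5.67e-8 * 0.95 * 0.77 * ((t_cl + 273)^4 - (t_mr + 273)^4) / dt_r
  } else {
    4 * 5.67e-8 * 0.95 * 0.77 * (t_cl + 273)^3
  }
  r <- f_cl * h_r * (t_cl - t_mr)
  c <- f_cl * .ireq_hc(v) * (t_cl - t_air)
  m - w_ext - e - h_res - r - c - s
}

#' Required clothing insulation and cold exposure limit (IREQ)
#'
#' Solves the whole-body heat balance for the clothing insulation required
#' to sustain 8 h work in the cold at two strain criteria: thermoneutral
#' (`icl_neutral`, with thermoregulatory sweating) and minimal
#' (`icl_minimal`, high strain, no sweating). With the user's actual
#' clothing it then solves for the steady heat debt rate and converts the
#' permissible debt (40 Wh m-2) into a duration limit of exposure.
#'
#' Inputs are clamped to the standard's validity ranges (metabolic rate to
#' \[58, 290\] W m-2, air speed to \[0.4, 18\] m/s) before solving.
#'
#' @param t_air Air temperature, degC.
#' @param t_mr Mean radiant temperature, degC.
#' @param rh Relative humidity, percent.
#' @param v2 Air speed at 2 m, m/s.
#' @param q_met_wm2 Metabolic rate, W m-2.
#' @param clothing A [clothing_ensemble()] (air permeability drives the
#'   wind-penetration correction; insulation drives the exposure limit).
#' @param v_walk Walking speed, m/s.
#' @return A one-row tibble with `icl_neutral` and `icl_minimal` (required
#'   basic insulation, Clo), `dle_cold` (minutes, capped at 480 when no
#'   limit applies within a shift) and `s_rate` (heat debt rate, W m-2,
#'   negative when cooling).
#' @export
run_ireq <- function(t_air, t_mr, rh, v2, q_met_wm2, clothing, v_walk = 0.8) {
  stopifnot(inherits(clothing, "clothing_ensemble"))
  m <- .clamp(q_met_wm2, 58, 290)
  v <- .clamp(v2, 0.4, 18)
  w_walk <- .clamp(max(v_walk, 0.0052 * (m - 58)), 0, 1.2)
  w_ext <- 0
  pa <- (rh / 100) * .ireq_psat(t_air)
  i_a_r <- 0.092 * exp(-0.15 * v - 0.22 * w_walk) - 0.0045
  corr <- .ireq_wind_corr(v, w_walk, clothing$p_air_perm)

  solve_ireq <- function(strain) {
    crit <- .ireq_criteria(m, strain)
    f <- function(icl) {
      .ireq_balance(icl, 0, m, w_ext, t_air, t_mr, pa, v, crit, i_a_r)
    }
    # the balance rises with insulation (less heat escapes); if it is
    # already non-negative with no clothing, none is required
    if (f(1e-6) >= 0) {
      return(0)
    }
    uniroot(f, c(1e-6, 2), extendInt = "upX", tol = 1e-6)$root
  }
  icl_neutral_si <- solve_ireq("neutral")
  icl_minimal_si <- solve_ireq("minimal")
  # required basic insulation: undo the wind/motion penalty
  icl_neutral <- si_to_clo(icl_neutral_si / corr)
  icl_minimal <- si_to_clo(icl_minimal_si / corr)
  if (icl_minimal > icl_neutral) icl_minimal <- icl_neutral

  # duration limit with the worn clothing (high-strain criterion)
  icl_r <- clothing$icl * corr
  crit <- .ireq_criteria(m, "minimal")
  g <- function(s) {
    .ireq_balance(max(icl_r, 1e-6), s, m, w_ext, t_air, t_mr, pa, v, crit, i_a_r)
  }
  s_rate <- uniroot(g, c(-600, 600), extendInt = "yes", tol = 1e-6)$root
  dle_cold <- if (s_rate >= -40 / 8) 480 else min(480, 60 * 40 / abs(s_rate))
  tibble::tibble(
    icl_neutral = icl_neutral,
    icl_minimal = icl_minimal,
    dle_cold = dle_cold,
    s_rate = s_rate
  )
}

#' Cold branch of the thermal stress index
#'
#' Scales the worn insulation against the IREQ requirements: one Clo of
#' underdressing below the minimal requirement costs one index unit below
#' -1; between minimal and neutral the index interpolates linearly from -1
#' to 0; overdressing counts one unit per Clo above neutral. Clamped to
#' \[-4, 4\].
#'
#' @param icl_user Worn basic insulation, Clo.
#' @param icl_neutral,icl_minimal Required insulation at the neutral and
#'   minimal criteria, Clo (`icl_minimal <= icl_neutral`).
#' @return Index value.
#' @examples
#' cold_index(1.5, icl_neutral = 2.5, icl_minimal = 2.0) # -1.5
#' @export
cold_index <- function(icl_user, icl_neutral, icl_minimal) {
  if (any(icl_minimal > icl_neutral + 1e-12)) {
    rlang::abort("`icl_minimal` must be <= `icl_neutral`", class = "thermindex_domain_error")
  }
  if (any(icl_user < 0)) {
    rlang::abort("`icl_user` must be >= 0", class = "thermindex_domain_error")
  }
  n <- max(length(icl_user), length(icl_neutral), length(icl_minimal))
  u <- rep_len(icl_user, n)
  nt <- rep_len(icl_neutral, n)
  mn <- rep_len(icl_minimal, n)
  degenerate <- (nt - mn) < 1e-12
  idx <- dplyr::case_when(
    u < mn ~ -1 - (mn - u),
    u > nt ~ u - nt,
    degenerate ~ 0,
    .default = -1 + (u - mn) / (nt - mn)
  )
  .clamp(idx, -4, 4)
}

#' Cold-stress assessment for one weather state
#'
#' @param t_air Air temperature, degC.
#' @param t_mr Mean radiant temperature under the worst-case full
#'   overcast, degC.
#' @param rh Relative humidity, percent.
#' @param v2 Air speed at 2 m, m/s.
#' @param v10 Wind at 10 m, m/s (windchill).
#' @param activity An [activity_profile()].
#' @param clothing A [clothing_ensemble()].
#' @return A one-row tibble with the IREQ outputs, `t_windchill`,
#'   `frostbite_flag` and `index`.
#' @export
assess_cold <- function(t_air, t_mr, rh, v2, v10, activity, clothing) {
  ireq <- run_ireq(t_air, t_mr, rh, v2, activity$q_met_wm2, clothing,
    v_walk = activity$v_walk
  )
  t_wc <- windchill(t_air, v10)
  tibble::tibble(
    icl_neutral = ireq$icl_neutral,
    icl_minimal = ireq$icl_minimal,
    dle_cold = ireq$dle_cold,
    t_windchill = t_wc,
    frostbite_flag = t_wc < 0,
    index = cold_index(si_to_clo(clothing$icl), ireq$icl_neutral, ireq$icl_minimal)
  )
}
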