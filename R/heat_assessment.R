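# Heat path: WBGT screening after the HEAT-SHIELD algorithm. The measured
# (modelled) WBGT is corrected for clothing (CAV), compared with the
# acclimatisation- and metabolism-dependent reference limit, and the
# resulting Heat Risk Level is mapped onto the positive half of the
# thermal stress index.

#' Clothing area factor
#'
#' Enlargement of the heat-exchange area by clothing. Linear in insulation
#' up to 2 Clo (0.31 m2 K W-1), `1.00 + 1.81 icl`; above that, the power
#' form `1.2424 clo^0.1546` with insulation expressed in Clo.
#'
#' @param icl Basic clothing insulation, m2 K W-1.
#' @return Dimensionless factor >= 1.
#' @export
clothing_area_factor <- function(icl) {
  stopifnot(all(icl >= 0))
  ifelse(icl < clo_to_si(2), 1.00 + 1.81 * icl, 1.2424 * si_to_clo(icl)^0.1546)
}

#' Clothing adjustment value (CAV)
#'
#' Additive WBGT correction for clothing other than the reference cotton
#' ensemble, parameterised through the static evaporative resistance of
#' clothing plus air: `Re,T,s = 0.16 (Ia/fcl + Icl)` with Ia = 0.085
#' m2 K W-1, then `CAV = 5.81 ln(Re,T,s) + 20.7` degC.
#'
#' @param icl Basic clothing insulation, m2 K W-1.
#' @return CAV in degC (negative for lighter-than-reference clothing).
#' @export
cav <- function(icl) {
  re_t_s <- evaporative_resistance(icl)$re_t_s
  5.81 * log(re_t_s) + 20.7
}

#' Static evaporative resistance of clothing plus air
#'
#' @param icl Basic clothing insulation, m2 K W-1.
#' @return A tibble with `f_cl`, `i_t` (total insulation, m2 K W-1) and
#'   `re_t_s` (m2 kPa W-1).
#' @export
evaporative_resistance <- function(icl) {
  f_cl <- clothing_area_factor(icl)
  i_t <- .i_a_static / f_cl + icl
  tibble::tibble(f_cl = f_cl, i_t = i_t, re_t_s = 0.16 * i_t)
}

#' WBGT reference limit
#'
#' The effective-WBGT level sustainable over an 8 h shift, decreasing with
#' the logarithm of metabolic heat production and higher for acclimatised
#' workers: `56.7 - 11.5 log10(M)` (acclimatised) or `59.9 - 14.1 log10(M)`.
#'
#' @param m_watts Metabolic heat production, W (> 0).
#' @param acclimatised Logical.
#' @return Reference WBGT, degC.
#' @export
wbgt_ref <- function(m_watts, acclimatised) {
  if (any(m_watts <= 0)) {
    rlang::abort("`m_watts` must be > 0", class = "thermindex_domain_error")
  }
  ifelse(acclimatised, 56.7 - 11.5 * log10(m_watts), 59.9 - 14.1 * log10(m_watts))
}

#' Heat branch of the thermal stress index
#'
#' Piecewise-linear mapping of the Heat Risk Level (HRL = effective WBGT
#' over the reference limit) onto the index: HRL/0.8 below the 0.8 alert
#' band, then one index unit per 0.2 of HRL up to 1.2, then unit slope,
#' clamped at +4.
#'
#' @param hrl Heat risk level, a non-negative ratio.
#' @return Index value in \[0, 4\].
#' @examples
#' heat_index(c(0.4, 0.9, 1.1, 1.7)) # 0.5, 1.5, 2.5, 3.5
#' @export
heat_index <- function(hrl) {
  if (any(hrl < 0)) {
    rlang::abort("`hrl` must be >= 0", class = "thermindex_domain_error")
  }
  idx <- ifelse(hrl < 0.8, hrl / 0.8,
    ifelse(hrl < 1.0, 1 + (hrl - 0.8) / 0.2,
      ifelse(hrl < 1.2, 2 + (hrl - 1.0) / 0.2, 3 + (hrl - 1.2))
    )
  )
  pmin(idx, 4)
}

.hrl_category <- function(hrl) {
  cut(hrl,
    breaks = c(-Inf, 0.8, 1.0, 1.2, Inf),
    labels = c("not-significant", "low", "moderate", "high"),
    right = FALSE
  )
}

#' Heat-stress assessment for one weather state
#'
#' Combines the modelled WBGT (worst case: unattenuated solar load) with
#' the clothing adjustment value and the personal reference limit into
#' the Heat Risk Level, its category and the index value.
#'
#' @param globe A one-row tibble from [globe_set()] (uses the `wbgt`
#'   column).
#' @param clothing A [clothing_ensemble()].
#' @param activity An [activity_profile()].
#' @param person A [person_profile()].
#' @return A one-row tibble with `wbgt`, `cav`, `wbgt_effective`,
#'   `wbgt_ref`, `hrl`, `category`, `index`.
#' @export
assess_heat <- function(globe, clothing, activity, person) {
  cav_val <- cav(clothing$icl)
  wbgt_eff <- globe$wbgt + cav_val
  ref <- wbgt_ref(activity$q_met_w, person$acclimatised)
  hrl <- wbgt_eff / ref
  tibble::tibble(
    wbgt = globe$wbgt,
    cav = cav_val,
    wbgt_effective = wbgt_eff,
    wbgt_ref = ref,
    hrl = hrl,
    category = as.character(.hrl_category(hrl)),
    index = heat_index(pmax(hrl, 0))
  )
}
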