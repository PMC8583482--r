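# Predicted Heat Strain: minute-by-minute heat-balance integration of core
# temperature and sweat rate for a clothed, standing worker, following the
# published ISO 7933 reference algorithm. Exposed outputs are the duration
# limit until rectal temperature reaches 38 degC and the accumulated sweat
# loss; the full rectal-temperature trace is kept as a diagnostic.

#' Run the Predicted Heat Strain simulation
#'
#' @param t_air Air temperature, degC (model envelope 15-50 degC; values
#'   outside attach a validity warning to the result rather than failing).
#' @param t_mr Mean radiant temperature, degC.
#' @param pv_air Water vapour pressure, kPa.
#' @param v2 Air speed at 2 m, m/s.
#' @param q_met_wm2 Metabolic rate, W m-2.
#' @param clothing A [clothing_ensemble()] (uses `icl` and `im_st`).
#' @param person A [person_profile()] (weight, height, acclimatisation).
#' @param duration_min Simulated shift length in minutes (<= 480).
#' @param v_walk Walking speed fed to the dynamic-insulation correction,
#'   m/s (0 at rest, 0.8 otherwise by convention).
#' @return A `phs_result` list: `dle_hot` (minutes; `duration_min` means no
#'   limit was reached), `sweat_total_g`, `sweat_per_hour_g`,
#'   `t_rectal_series`, `valid` and `validity_notes`.
#' @export
run_phs <- function(t_air, t_mr, pv_air, v2, q_met_wm2, clothing, person,
                    duration_min = 480, v_walk = 0.8) {
  stopifnot(
    inherits(clothing, "clothing_ensemble"),
    inherits(person, "person_profile"),
    duration_min >= 1, duration_min <= 480
  )
  notes <- character()
  if (t_air < 15 || t_air > 50) {
    notes <- c(notes, sprintf("t_air %.1f degC outside PHS envelope [15, 50]", t_air))
  }
  if (q_met_wm2 < 100 || q_met_wm2 > 450) {
    notes <- c(notes, sprintf("metabolic rate %.0f W m-2 outside PHS envelope [100, 450]", q_met_wm2))
  }

  met <- q_met_wm2
  clo <- si_to_clo(clothing$icl)
  im_st <- clothing$im_st
  wme <- 0
  adu <- person$bsa
  sp_heat <- 57.83 * person$weight / adu
  acclim <- person$acclimatised

  # static clothing and air-layer insulation
  i_cl_st <- clothing$icl
  fcl <- 1 + 0.3 * clo
  i_a_st <- 0.111
  i_tot_st <- i_cl_st + i_a_st / fcl

  # relative air speed: walking direction unknown
  walk_sp <- v_walk
  v_r <- max(v2, walk_sp)

  # dynamic corrections for insulation and permeability
  v_ux <- min(v_r, 3)
  w_ux <- min(walk_sp, 1.5)
  corr_cl <- min(1, 1.044 * exp((0.066 * v_ux - 0.398) * v_ux + (0.094 * w_ux - 0.378) * w_ux))
  corr_ia <- min(1, exp((0.047 * v_r - 0.472) * v_r + (0.117 * w_ux - 0.342) * w_ux))
  corr_tot <- if (clo <= 0.6) ((0.6 - clo) * corr_ia + clo * corr_cl) / 0.6 else corr_cl
  i_tot_dyn <- i_tot_st * corr_tot
  i_a_dyn <- corr_ia * i_a_st
  i_cl_dyn <- i_tot_dyn - i_a_dyn / fcl
  corr_e <- (2.6 * corr_tot - 6.5) * corr_tot + 4.9
  im_dyn <- min(0.9, im_st * corr_e)
  r_t_dyn <- i_tot_dyn / im_dyn / 16.7

  # respiratory heat losses (kPa-based linearisations)
  c_res <- 0.00152 * met * (28.56 - 0.885 * t_air + 0.641 * pv_air)
  e_res <- 0.00127 * met * (59.34 + 0.53 * t_air - 11.63 * pv_air)

  # maximum sweat rate, W m-2
  sw_max <- (met - 32) * adu
  sw_max <- min(400, max(250, sw_max))
  if (acclim) sw_max <- sw_max * 1.25
  w_max <- if (acclim) 1 else 0.85

  # initial physiological state
  t_sk <- 34.1
  t_cr <- 36.8
  t_re <- 36.8
  t_cr_eq <- 36.8
  wg <- 0.3 # skin/core weighting of mean body temperature
  sw_p <- 0
  sw_tot <- 0
  dle <- NA_real_
  t_re_series <- numeric(duration_min)
  a_r_du <- 0.7 # effective radiating area fraction

  for (minute in seq_len(duration_min)) {
    t_sk0 <- t_sk; t_re0 <- t_re; t_cr0 <- t_cr
    t_cr_eq0 <- t_cr_eq; wg0 <- wg

    # equilibrium core temperature for this metabolic rate (10 min constant)
    t_cr_eq_m <- 0.0036 * met + 36.6
    t_cr_eq <- t_cr_eq0 * exp(-1 / 10) + t_cr_eq_m * (1 - exp(-1 / 10))
    d_stored_eq <- sp_heat * (t_cr_eq - t_cr_eq0) * (1 - wg0)

    # skin temperature equilibrium (clothed/nude blend), 3 min constant
    t_sk_eq_cl <- 12.165 + 0.02017 * t_air + 0.04361 * t_mr + 0.19354 * pv_air -
      0.25315 * v2 + 0.005346 * met + 0.51274 * t_re
    t_sk_eq_nu <- 7.191 + 0.064 * t_air + 0.061 * t_mr + 0.198 * pv_air -
      0.348 * v2 + 0.616 * t_re
    t_sk_eq <- if (clo >= 0.6) {
      t_sk_eq_cl
    } else if (clo <= 0.2) {
      t_sk_eq_nu
    } else {
      t_sk_eq_nu + 2.5 * (t_sk_eq_cl - t_sk_eq_nu) * (clo - 0.2)
    }
    t_sk <- t_sk0 * exp(-1 / 3) + t_sk_eq * (1 - exp(-1 / 3))
    p_sk <- 0.6105 * exp(17.27 * t_sk / (t_sk + 237.3))

    # convective coefficient (natural vs forced)
    hc <- 2.38 * abs(t_sk - t_air)^0.25
    hc_forced <- if (v_r < 1) 3.5 + 5.2 * v_r else 8.7 * v_r^0.6
    hc <- max(hc, hc_forced)

    # clothing surface temperature (fixed point with radiative coupling)
    t_cl <- t_mr + 0.1
    h_r <- 0
    repeat {
      dt <- t_cl - t_mr
      h_r <- if (abs(dt) > 1e-9) {
        5.67e-8 * a_r_du * ((t_cl + 273)^4 - (t_mr + 273)^4) / dt
      } else {
        4 * 5.67e-8 * a_r_du * (t_cl + 273)^3
      }
      t_cl_new <- (fcl * (hc * t_air + h_r * t_mr) + t_sk / i_cl_dyn) /
        (fcl * (hc + h_r) + 1 / i_cl_dyn)
      if (abs(t_cl_new - t_cl) <= 0.001) break
      t_cl <- (t_cl + t_cl_new) / 2
    }
    conv <- fcl * hc * (t_cl - t_air)
    rad <- fcl * h_r * (t_cl - t_mr)

    e_max <- (p_sk - pv_air) / r_t_dyn
    e_req <- met - d_stored_eq - wme - c_res - e_res - conv - rad

    # required sweat rate with evaporative efficiency
    if (e_req <= 0) {
      e_req <- 0
      sw_req <- 0
    } else if (e_max <= 0) {
      e_max <- 0
      sw_req <- sw_max
    } else {
      w_req <- e_req / e_max
      if (w_req >= 1.7) {
        sw_req <- sw_max
      } else {
        e_v_eff <- if (w_req <= 1) 1 - w_req^2 / 2 else (2 - w_req)^2 / 2
        sw_req <- min(e_req / e_v_eff, sw_max)
      }
    }
    sw_p <- sw_p * exp(-1 / 10) + sw_req * (1 - exp(-1 / 10))
    if (sw_p <= 0) {
      e_p <- 0
      sw_p <- 0
    } else {
      k <- e_max / sw_p
      wp <- 1
      if (k >= 0.5) wp <- -k + sqrt(k * k + 2)
      wp <- min(wp, w_max)
      e_p <- wp * e_max
    }

    d_storage <- e_req - e_p + d_stored_eq

    # core temperature consistent with the storage and the new weighting
    t_cr_new <- t_cr0
    repeat {
      wg <- .clamp(0.3 - 0.09 * (t_cr_new - 36.8), 0.1, 0.3)
      t_cr_cand <- d_storage / sp_heat + t_sk0 * wg0 / 2 - t_sk * wg / 2
      t_cr_cand <- (t_cr_cand + t_cr0 * (1 - wg0 / 2)) / (1 - wg / 2)
      if (abs(t_cr_cand - t_cr_new) <= 0.001) break
      t_cr_new <- (t_cr_new + t_cr_cand) / 2
    }
    t_cr <- t_cr_cand

    t_re <- t_re0 + (2 * t_cr - 1.962 * t_re0 - 1.31) / 9
    t_re_series[minute] <- t_re
    if (is.na(dle) && t_re >= 38) dle <- minute

    sw_tot <- sw_tot + sw_p + e_res
  }

  sweat_total_g <- sw_tot * 2.67 * adu / 1.8 / 60
  structure(
    list(
      dle_hot = if (is.na(dle)) duration_min else dle,
      sweat_total_g = sweat_total_g,
      sweat_per_hour_g = sweat_total_g / (duration_min / 60),
      t_rectal_series = t_re_series,
      valid = length(notes) == 0,
      validity_notes = notes
    ),
    class = "phs_result"
  )
}
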