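# Independent reference implementations used as cross-check oracles.
# Each is a deliberately flat transcription of the published reference
# listing for the model in question, solved by a DIFFERENT numerical route
# than the package implementation (stepwise marches / bisection via
# uniroot instead of damped fixed-point iterations), so a transcription or
# solver error on either side shows up as disagreement.

# ---- Liljegren outdoor WBGT (flat transcription of the published C code) ----

ref_liljegren <- function(t_air, rh, v2, q_solar, p_kpa = 101.325,
                          cza = 1, fdir = NULL) {
  stefanb <- 5.6696e-8
  m_air <- 28.97; m_h2o <- 18.015; r_gas <- 8314.34
  cp <- 1003.5; r_air <- r_gas / m_air
  pr <- cp / (cp + 1.25 * r_air)
  ratio <- cp * m_air / m_h2o
  emis_globe <- 0.95; alb_globe <- 0.05; diam_globe <- 0.05
  emis_wick <- 0.95; alb_wick <- 0.4; diam_wick <- 0.007; len_wick <- 0.0254
  emis_sfc <- 0.999; alb_sfc <- 0.45
  conv_lim <- 0.02; max_iter <- 500
  pair <- p_kpa * 10 # mb
  tk <- t_air + 273.15
  speed <- max(v2, 0.13)

  esat <- function(t) 1.004 * 6.1121 * exp(17.502 * (t - 273.15) / (t - 32.18))
  visc <- function(t) {
    omega <- (t / 97 - 2.9) / 0.4 * (-0.034) + 1.048
    2.6693e-6 * sqrt(m_air * t) / (3.617^2 * omega)
  }
  thermcond <- function(t) (cp + 1.25 * r_air) * visc(t)
  diffus <- function(t, p_atm) {
    0.000364 * (t / sqrt(132 * 647.3))^2.334 * (36.4 * 218)^(1 / 3) *
      (132 * 647.3)^(5 / 12) * sqrt(1 / m_air + 1 / m_h2o) / p_atm * 1e-4
  }
  h_evap <- function(t) (313.15 - t) / 30 * (-71100) + 2.4073e6
  emis_atm <- 0.575 * ((rh / 100) * esat(tk))^0.143
  if (is.null(fdir)) {
    ns <- if (q_solar > 0) min(q_solar / (q_solar / 0.85), 0.85) else 0
    fdir <- if (ns > 0) max(0, min(0.9, exp(3 - 1.34 * ns - 1.65 / ns))) else 0
  }
  czae <- max(cza, 0.00873)

  # globe
  tg <- tk
  i <- 0
  repeat {
    i <- i + 1
    tref <- 0.5 * (tg + tk)
    dens <- pair * 100 / (r_air * tref)
    re <- speed * dens * diam_globe / visc(tref)
    nu <- 2 + 0.6 * sqrt(re) * pr^(1 / 3)
    h <- nu * thermcond(tref) / diam_globe
    tg_new <- (0.5 * (emis_atm * tk^4 + emis_sfc * tk^4) -
      h / (stefanb * emis_globe) * (tg - tk) +
      q_solar / (2 * stefanb * emis_globe) * (1 - alb_globe) *
        (fdir * (1 / (2 * czae) - 1) + 1 + alb_sfc))^0.25
    if (abs(tg_new - tg) < conv_lim || i > max_iter) break
    tg <- 0.9 * tg + 0.1 * tg_new
  }
  t_g <- tg_new - 273.15

  # natural wet bulb
  eair <- (rh / 100) * esat(tk)
  x <- log(eair / (1.004 * 6.1121))
  tdew <- 273.15 + 240.97 * x / (17.502 - x)
  twb <- tdew
  sza <- min(acos(min(max(cza, -1), 1)), acos(0.00873))
  i <- 0
  repeat {
    i <- i + 1
    tref <- 0.5 * (twb + tk)
    dens <- pair * 100 / (r_air * tref)
    re <- speed * dens * diam_wick / visc(tref)
    nu <- 0.281 * re^(1 - 0.4) * pr^(1 - 0.56)
    h <- nu * thermcond(tref) / diam_wick
    sc <- visc(tref) / (dens * diffus(tref, pair / 1013.25))
    fatm <- stefanb * emis_wick *
      (0.5 * (emis_atm * tk^4 + emis_sfc * tk^4) - twb^4) +
      (1 - alb_wick) * q_solar *
        ((1 - fdir) * (1 + 0.25 * diam_wick / len_wick) +
          fdir * (tan(sza) / pi + 0.25 * diam_wick / len_wick) + alb_sfc)
    ewick <- esat(twb)
    evap <- h_evap(twb)
    twb_new <- tk - evap / ratio * (ewick - eair) / (pair - ewick) *
      (pr / sc)^0.56 + fatm / h
    if (abs(twb_new - twb) < conv_lim || i > max_iter) break
    twb <- 0.9 * twb + 0.1 * twb_new
  }
  t_nwb <- twb_new - 273.15
  list(t_g = t_g, t_nwb = t_nwb, wbgt = 0.7 * t_nwb + 0.2 * t_g + 0.1 * t_air)
}

# ---- Fanger PMV with the clothing temperature solved by uniroot ----

ref_pmv <- function(ta, tr, vel, rh, met_wm2, icl_si) {
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235))
  m <- met_wm2
  mw <- m
  icl <- icl_si
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hcf <- 12.1 * sqrt(vel)
  # residual of the clothing-surface balance at temperature tcl (degC)
  resid <- function(tcl) {
    hcn <- 2.38 * abs(tcl - ta)^0.25
    hc <- max(hcf, hcn)
    rhs <- 35.7 - 0.028 * mw - icl * (
      3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4) + fcl * hc * (tcl - ta)
    )
    tcl - rhs
  }
  tcl <- uniroot(resid, c(ta - 40, ta + 60), tol = 1e-7)$root
  hcn <- 2.38 * abs(tcl - ta)^0.25
  hc <- max(hcf, hcn)
  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0
  hl3 <- 1.7e-5 * m * (5867 - pa)
  hl4 <- 0.0014 * m * (34 - ta)
  hl5 <- 3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4)
  hl6 <- fcl * hc * (tcl - ta)
  ts <- 0.303 * exp(-0.036 * m) + 0.028
  ts * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6)
}

# ---- IREQ solved by the published stepwise 0.001-insulation march ----

ref_ireq <- function(t_air, t_mr, rh, v2, q_met_wm2, icl_clo, p_air_perm,
                     v_walk = 0.8) {
  m <- min(max(q_met_wm2, 58), 290)
  v <- min(max(v2, 0.4), 18)
  w <- min(max(v_walk, 0.0052 * (m - 58)), 1.2)
  psat <- function(t) 0.1333 * exp(18.6686 - 4030.183 / (t + 235))
  pa <- (rh / 100) * psat(t_air)
  i_a_r <- 0.092 * exp(-0.15 * v - 0.22 * w) - 0.0045
  corr <- 0.54 * exp(-0.15 * v - 0.22 * w) * p_air_perm^0.075 -
    0.06 * log(p_air_perm) + 0.5
  hc_of <- function(vv) if (vv < 1) 3.5 + 5.2 * vv else 8.7 * vv^0.6
  t_ex <- 29 + 0.2 * t_air
  h_res <- 1.73e-2 * m * (psat(t_ex) - pa) + 1.4e-3 * m * (t_ex - t_air)

  balance <- function(icl, s, t_sk, wet) {
    r_t <- (0.06 / 0.38) * (i_a_r + icl)
    e <- wet * (psat(t_sk) - pa) / r_t
    t_cl <- t_sk - icl * (m - e - h_res - s)
    f_cl <- 1 + 1.197 * icl
    dt <- t_cl - t_mr
    h_r <- if (abs(dt) > 1e-9) {
      5.67e-8 * 0.95 * 0.77 * ((t_cl + 273)^4 - (t_mr + 273)^4) / dt
    } else {
      4 * 5.67e-8 * 0.95 * 0.77 * (t_cl + 273)^3
    }
    r <- f_cl * h_r * (t_cl - t_mr)
    cc <- f_cl * hc_of(v) * (t_cl - t_air)
    m - e - h_res - r - cc - s
  }

  march_icl <- function(t_sk, wet) {
    icl <- 0.5
    for (i in 1:20000) {
      b <- balance(icl, 0, t_sk, wet)
      if (abs(b) < 0.01) break
      icl <- icl + if (b > 0) -0.0005 else 0.0005
      if (icl <= 0) {
        return(0)
      }
    }
    icl
  }
  t_sk_n <- 35.7 - 0.0285 * m
  t_sk_m <- 33.34 - 0.0354 * m
  icl_neutral <- march_icl(t_sk_n, 0.001 * m) / corr / 0.155
  icl_minimal <- march_icl(t_sk_m, 0.06) / corr / 0.155

  # heat-debt march for the duration limit with the worn clothing
  icl_r <- max(icl_clo * 0.155 * corr, 1e-6)
  s <- 0
  for (i in 1:40000) {
    b <- balance(icl_r, s, t_sk_m, 0.06)
    if (abs(b) < 0.01) break
    s <- s + if (b > 0) 0.05 else -0.05
  }
  dle <- if (s >= -5) 480 else min(480, 60 * 40 / abs(s))
  list(
    icl_neutral = icl_neutral, icl_minimal = min(icl_minimal, icl_neutral),
    dle_cold = dle, s_rate = s
  )
}

# ---- ISO 7933 heat-strain minute loop with uniroot inner solves ----

ref_phs <- function(t_air, t_mr, pv_air, v2, met, clo, im_st,
                    weight = 80, height_cm = 180, acclim = FALSE,
                    duration = 480, v_walk = 0.8) {
  adu <- 0.007184 * weight^0.425 * height_cm^0.725
  sp_heat <- 57.83 * weight / adu
  i_cl_st <- clo * 0.155
  fcl <- 1 + 0.3 * clo
  i_tot_st <- i_cl_st + 0.111 / fcl
  v_r <- max(v2, v_walk)
  v_ux <- min(v_r, 3); w_ux <- min(v_walk, 1.5)
  corr_cl <- min(1, 1.044 * exp((0.066 * v_ux - 0.398) * v_ux + (0.094 * w_ux - 0.378) * w_ux))
  corr_ia <- min(1, exp((0.047 * v_r - 0.472) * v_r + (0.117 * w_ux - 0.342) * w_ux))
  corr_tot <- if (clo <= 0.6) ((0.6 - clo) * corr_ia + clo * corr_cl) / 0.6 else corr_cl
  i_tot_dyn <- i_tot_st * corr_tot
  i_cl_dyn <- i_tot_dyn - corr_ia * 0.111 / fcl
  im_dyn <- min(0.9, im_st * ((2.6 * corr_tot - 6.5) * corr_tot + 4.9))
  r_t_dyn <- i_tot_dyn / im_dyn / 16.7
  c_res <- 0.00152 * met * (28.56 - 0.885 * t_air + 0.641 * pv_air)
  e_res <- 0.00127 * met * (59.34 + 0.53 * t_air - 11.63 * pv_air)
  sw_max <- min(400, max(250, (met - 32) * adu))
  if (acclim) sw_max <- sw_max * 1.25
  w_max <- if (acclim) 1 else 0.85

  t_sk <- 34.1; t_cr <- 36.8; t_re <- 36.8; t_cr_eq <- 36.8
  wg <- 0.3; sw_p <- 0; sw_tot <- 0; dle <- NA
  for (minute in 1:duration) {
    t_sk0 <- t_sk; t_re0 <- t_re; t_cr0 <- t_cr
    t_cr_eq0 <- t_cr_eq; wg0 <- wg
    t_cr_eq <- t_cr_eq0 * exp(-0.1) + (0.0036 * met + 36.6) * (1 - exp(-0.1))
    d_stored_eq <- sp_heat * (t_cr_eq - t_cr_eq0) * (1 - wg0)
    t_sk_cl <- 12.165 + 0.02017 * t_air + 0.04361 * t_mr + 0.19354 * pv_air -
      0.25315 * v2 + 0.005346 * met + 0.51274 * t_re
    t_sk_nu <- 7.191 + 0.064 * t_air + 0.061 * t_mr + 0.198 * pv_air -
      0.348 * v2 + 0.616 * t_re
    t_sk_eq <- if (clo >= 0.6) t_sk_cl else if (clo <= 0.2) t_sk_nu else
      t_sk_nu + 2.5 * (t_sk_cl - t_sk_nu) * (clo - 0.2)
    t_sk <- t_sk0 * exp(-1 / 3) + t_sk_eq * (1 - exp(-1 / 3))
    p_sk <- 0.6105 * exp(17.27 * t_sk / (t_sk + 237.3))
    hc <- max(
      2.38 * abs(t_sk - t_air)^0.25,
      if (v_r < 1) 3.5 + 5.2 * v_r else 8.7 * v_r^0.6
    )
    # clothing-surface temperature via uniroot
    tcl_resid <- function(tcl) {
      dt <- tcl - t_mr
      hr <- if (abs(dt) > 1e-9) {
        5.67e-8 * 0.7 * ((tcl + 273)^4 - (t_mr + 273)^4) / dt
      } else {
        4 * 5.67e-8 * 0.7 * (tcl + 273)^3
      }
      tcl - (fcl * (hc * t_air + hr * t_mr) + t_sk / i_cl_dyn) /
        (fcl * (hc + hr) + 1 / i_cl_dyn)
    }
    t_cl <- uniroot(tcl_resid, c(min(t_air, t_mr) - 30, max(t_air, t_mr, t_sk) + 30),
      tol = 1e-6
    )$root
    dt <- t_cl - t_mr
    hr <- if (abs(dt) > 1e-9) {
      5.67e-8 * 0.7 * ((t_cl + 273)^4 - (t_mr + 273)^4) / dt
    } else {
      4 * 5.67e-8 * 0.7 * (t_cl + 273)^3
    }
    conv <- fcl * hc * (t_cl - t_air)
    rad <- fcl * hr * (t_cl - t_mr)
    e_max <- (p_sk - pv_air) / r_t_dyn
    e_req <- met - d_stored_eq - c_res - e_res - conv - rad
    if (e_req <= 0) {
      e_req <- 0; sw_req <- 0
    } else if (e_max <= 0) {
      e_max <- 0; sw_req <- sw_max
    } else {
      w_req <- e_req / e_max
      if (w_req >= 1.7) {
        sw_req <- sw_max
      } else {
        e_v <- if (w_req <= 1) 1 - w_req^2 / 2 else (2 - w_req)^2 / 2
        sw_req <- min(e_req / e_v, sw_max)
      }
    }
    sw_p <- sw_p * exp(-0.1) + sw_req * (1 - exp(-0.1))
    if (sw_p <= 0) {
      e_p <- 0; sw_p <- 0
    } else {
      k <- e_max / sw_p
      wp <- if (k >= 0.5) -k + sqrt(k * k + 2) else 1
      wp <- min(wp, w_max)
      e_p <- wp * e_max
    }
    d_storage <- e_req - e_p + d_stored_eq
    # core temperature via uniroot on the self-consistent weighting
    cr_resid <- function(tc) {
      wgx <- min(0.3, max(0.1, 0.3 - 0.09 * (tc - 36.8)))
      lhs <- d_storage / sp_heat + t_sk0 * wg0 / 2 - t_sk * wgx / 2 +
        t_cr0 * (1 - wg0 / 2)
      tc - lhs / (1 - wgx / 2)
    }
    t_cr <- uniroot(cr_resid, c(t_cr0 - 5, t_cr0 + 5), extendInt = "yes", tol = 1e-6)$root
    wg <- min(0.3, max(0.1, 0.3 - 0.09 * (t_cr - 36.8)))
    t_re <- t_re0 + (2 * t_cr - 1.962 * t_re0 - 1.31) / 9
    if (is.na(dle) && t_re >= 38) dle <- minute
    sw_tot <- sw_tot + sw_p + e_res
  }
  list(
    dle_hot = if (is.na(dle)) duration else dle,
    sweat_total_g = sw_tot * 2.67 * adu / 1.8 / 60,
    t_re_final = t_re
  )
}

# ---- solar elevation from the Spencer (1971) Fourier series ----

ref_solar_elevation <- function(lat, lon, time) {
  doy <- as.numeric(format(time, "%j", tz = "UTC"))
  hour <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- hour + lon / 15 + eot / 60
  ha <- (15 * (tst - 12)) * pi / 180
  latr <- lat * pi / 180
  asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)) * 180 / pi
}

# reference context objects used across test files
make_person <- function(...) thermindex::person_profile(...)
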