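test_that("windchill evaluates the published formula with 10 m wind in m/s", {
  v16 <- 5^0.16
  expect_equal(
    windchill(-12, 5),
    13.12 + 0.6215 * -12 - 11.37 * v16 + 0.3965 * -12 * v16,
    tolerance = 1e-12
  )
  expect_equal(round(windchill(-12, 5), 1), -15.2)
})

test_that("windchill boundary handling and monotonicity", {
  # below the validity floor the air temperature is returned
  expect_equal(windchill(10, 1.2), 10)
  expect_equal(windchill(-5, 0), -5)
  # capped at air temperature just above the floor (light winds cannot warm)
  expect_equal(windchill(10, 1.34), 10)
  # monotone in wind in the cold
  expect_lt(windchill(-20, 10), windchill(-20, 5))
  # never exceeds air temperature
  grid <- expand.grid(t = seq(-30, 9, by = 3), v = seq(1.5, 15, by = 1.5))
  expect_true(all(windchill(grid$t, grid$v) <= grid$t))
  expect_error(windchill(0, -1), class = "thermindex_domain_error")
})

test_that("required insulation responds physically to climate and workload", {
  cl <- clothing_ensemble("winter")
  # warmer air: requirement can only drop
  neutral <- vapply(c(-25, -15, -5, 5), function(ta) {
    run_ireq(ta, ta, 70, 1, 115, cl)$icl_neutral
  }, numeric(1))
  expect_true(all(diff(neutral) <= 0))
  # more metabolic heat substitutes for insulation
  by_m <- vapply(c(70, 115, 165, 230), function(m) {
    run_ireq(-15, -15, 70, 1, m, cl)$icl_neutral
  }, numeric(1))
  expect_true(all(diff(by_m) < 0))
  # minimal criterion never demands more than neutral
  r <- run_ireq(-20, -20, 70, 2, 115, cl)
  expect_lte(r$icl_minimal, r$icl_neutral)
  expect_gt(r$dle_cold, 0)
})

test_that("IREQ matches the reference stepwise march within 10 percent", {
  cl <- clothing_ensemble("winter")
  for (ta in c(-25, -10, 0)) {
    for (v in c(0.4, 2, 5)) {
      for (m in c(115, 165)) {
        ours <- run_ireq(ta, ta, 70, v, m, cl)
        ref <- ref_ireq(ta, ta, 70, v, m, si_to_clo(cl$icl), cl$p_air_perm)
        expect_lt(
          abs(ours$icl_neutral - ref$icl_neutral) / max(ref$icl_neutral, 0.5), 0.10
        )
        expect_lt(
          abs(ours$icl_minimal - ref$icl_minimal) / max(ref$icl_minimal, 0.5), 0.10
        )
        expect_lt(abs(ours$dle_cold - ref$dle_cold) / ref$dle_cold, 0.10)
      }
    }
  }
})

test_that("the cold mapping hits the worked interpretation values", {
  expect_equal(cold_index(1.5, icl_neutral = 2.5, icl_minimal = 2.0), -1.5)
  expect_equal(cold_index(2.5, icl_neutral = 2.5, icl_minimal = 2.0), 0)
  expect_equal(cold_index(3.0, icl_neutral = 2.5, icl_minimal = 2.0), 0.5)
  # the underdressed branch value is independent of the requirement level
  expect_equal(cold_index(0.7, 2.0, 1.2), cold_index(2.5, 4.0, 3.0))
  expect_error(cold_index(1, 1.5, 2.0), class = "thermindex_domain_error")
  expect_error(cold_index(-0.5, 2.5, 2.0), class = "thermindex_domain_error")
})

test_that("the cold mapping is continuous, increasing and clamped", {
  nt <- 2.5
  mn <- 1.8
  u <- seq(0, 7, by = 0.01)
  idx <- cold_index(u, nt, mn)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= -4 & idx <= 4))
  eps <- 1e-9
  expect_equal(cold_index(mn - eps, nt, mn), cold_index(mn + eps, nt, mn), tolerance = 1e-6)
  expect_equal(cold_index(nt - eps, nt, mn), cold_index(nt + eps, nt, mn), tolerance = 1e-6)
  expect_equal(cold_index(mn, nt, mn), -1)
  expect_equal(cold_index(8, nt, mn), 4) # clamp high
  expect_equal(cold_index(0, 6, 6), -4) # clamp low
  # degenerate neutral == minimal: continuous extension
  expect_equal(cold_index(6, 6, 6), 0)
  expect_equal(cold_index(6.5, 6, 6), 0.5)
  expect_equal(cold_index(5.5, 6, 6), -1.5)
})

test_that("assess_cold flags frostbite exactly when windchill is below zero", {
  act <- activity_profile("low", person_profile())
  cl <- clothing_ensemble("winter")
  freezing <- assess_cold(2, 2, 70, 2, 8, act, cl)
  expect_true(freezing$t_windchill < 0)
  expect_true(freezing$frostbite_flag)
  mild <- assess_cold(8, 8, 70, 1, 2, act, cl)
  expect_true(mild$t_windchill >= 0)
  expect_false(mild$frostbite_flag)
})
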