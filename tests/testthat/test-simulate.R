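test_that("birth state: thresholds, reserve and the two volume rules", {
  p <- deb_params()  # {p_Am} = 2000, v = 0.2 -> [E_m] = 10000
  s <- initialize_at_birth(p)
  expect_equal(s$E, 0.167)
  expect_equal(s$E_H, 0.55)
  expect_equal(s$E_R, 0)
  expect_equal(s$stage, "juvenile")
  expect_equal(s$V, 1e-4)
  s2 <- initialize_at_birth(p, V_birth = "reserve-capacity")
  expect_equal(s2$V, 0.167 / 10000)  # E_0 / [E_m]
  s3 <- initialize_at_birth(p, V_birth = 2e-4)
  expect_equal(s3$V, 2e-4)
  expect_error(initialize_at_birth(p, V_birth = -1), "positive")
})

test_that("integration argument handling and output grid", {
  p <- deb_params()
  expect_error(deb_simulate(p, constant_forcing(0.8), duration = 0), "positive")
  expect_error(deb_simulate(p, constant_forcing(0.8), duration = 10,
                            output_step = 0), "positive")
  tr <- deb_simulate(p, constant_forcing(0.8), duration = 1, output_step = 1)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$time, c(0, 1))
  tr2 <- deb_simulate(p, constant_forcing(0.8), duration = 10)
  expect_true(all(diff(tr2$time) > 0))
  expect_equal(attr(tr2, "status"), "ok")
  # stage sequence is monotone juvenile -> adult
  stg <- match(tr2$stage, c("embryo", "juvenile", "adult"))
  expect_true(all(diff(stg) >= 0))
})

test_that("constant-food integrations reach the analytic steady state", {
  for (pars in list(deb_params(p_Am_max = 2000, v_dot = 0.2, kappa = 0.43),
                    deb_params(p_Am_max = 8000, v_dot = 0.5, kappa = 0.58))) {
    for (f in c(0.4, 1)) {
      tr <- deb_simulate(pars, constant_forcing(f), duration = 1095)
      n <- nrow(tr)
      e_density <- tr$E[n] / (tr$V[n] * f * reserve_capacity(pars))
      expect_lt(abs(e_density - 1), 1e-3)
      L <- tr$V[n]^(1 / 3)
      expect_lt(abs(L / ultimate_length(pars, f) - 1), 0.005)
    }
  }
})

test_that("time to puberty: boundary, interpolation fallback and refinement", {
  p <- deb_params()
  # solver-located crossing
  tr <- deb_simulate(p, constant_forcing(0.2), duration = 30)
  tp <- time_to_puberty(tr)
  expect_true(is.finite(tp) && tp > 0)
  tr_half <- deb_simulate(p, constant_forcing(0.2), duration = 30,
                          output_step = 0.5)
  expect_lt(abs(time_to_puberty(tr_half) - tp), 1)
  # interpolation between bracketing samples on an event-free trajectory
  ft <- fake_trajectory(times = 0:5, E_H = c(0.6, 0.7, 0.8, 1.0, 1.2, 1.3),
                        params = p)
  expect_equal(time_to_puberty(ft), 3 + (1.09 - 1.0) / 0.2)  # 3.45 d
  # already past the threshold at the first sample
  ft0 <- fake_trajectory(times = 0:2, E_H = c(1.2, 1.3, 1.4), params = p)
  expect_equal(time_to_puberty(ft0), 0)
  # never crossed
  ftn <- fake_trajectory(times = 0:2, E_H = c(0.6, 0.7, 0.8), params = p)
  expect_true(is.na(time_to_puberty(ftn)))
})

test_that("run summaries: steady state, seasonal window and guards", {
  p <- deb_params(p_Am_max = 4000, v_dot = 0.3, kappa = 0.51)
  trc <- deb_simulate(p, constant_forcing(0.8), duration = 1095)
  sm <- summarize_run(trc, window_years = 2)
  expect_lt(abs(sm$mean_biomass / sm$ss_biomass - 1), 1e-3)
  trs <- deb_simulate(p, seasonal_forcing(0.8, 0.2), duration = 1095)
  sms <- summarize_run(trs, window_years = 2)
  expect_lt(sms$min_biomass, sms$mean_biomass)
  expect_gt(sms$max_biomass, sms$mean_biomass)
  expect_error(summarize_run(trc, window_years = 4), "window")
  expect_s3_class(sms$final_state, "deb_state")
})

test_that("solutions are converged in the solver tolerances", {
  p <- deb_params(p_Am_max = 2000, v_dot = 0.2, kappa = 0.58)
  tr1 <- deb_simulate(p, seasonal_forcing(0.6, 0.2), duration = 1095)
  tr2 <- deb_simulate(p, seasonal_forcing(0.6, 0.2), duration = 1095,
                      rtol = 1e-9, atol = 1e-11)
  n <- nrow(tr1)
  expect_lt(abs(tr1$dry_biomass[n] / tr2$dry_biomass[n] - 1), 1e-4)
})

test_that("seasonal steady cycle is annually periodic after the transient", {
  p <- deb_params(p_Am_max = 4000, v_dot = 0.3, kappa = 0.51)
  tr <- deb_simulate(p, seasonal_forcing(0.6, 0.2), duration = 1095)
  b1 <- tr$dry_biomass[tr$time %in% 400:700]
  b2 <- tr$dry_biomass[tr$time %in% (400:700 + 365)]
  expect_lt(max(abs(b2 / b1 - 1)), 0.005)
})

test_that("maturation is sensitive to the birth-volume rule, steady state is not", {
  p <- deb_params(p_Am_max = 2000, v_dot = 0.2, kappa = 0.58)
  tr_d <- deb_simulate(p, constant_forcing(0.2), duration = 1095)
  tr_r <- deb_simulate(p, constant_forcing(0.2), duration = 1095,
                       V_birth = "reserve-capacity")
  tp_d <- time_to_puberty(tr_d)
  tp_r <- time_to_puberty(tr_r)
  # early-life maturation depends on the starting volume...
  expect_gt(abs(tp_r - tp_d), 0.5)
  # ...but the steady state forgets it
  n <- nrow(tr_d)
  expect_lt(abs(tr_r$dry_biomass[n] / tr_d$dry_biomass[n] - 1), 1e-6)
})

test_that("trajectory CSV writer round-trips the state columns", {
  p <- deb_params()
  tr <- deb_simulate(p, constant_forcing(0.8), duration = 20)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back)[1:7],
               c("t_days", "f", "E_J", "V_cm3", "EH_J", "ER_J", "stage"))
  expect_equal(back$V_cm3, tr$V, tolerance = 1e-6)
  expect_equal(nrow(back), nrow(tr))
})
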