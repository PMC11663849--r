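test_that("mortality generator respects its degenerate limits", {
  # infinitely steep mortality curve centred between days 7 and 8:
  # every fly dies on day 8 exactly
  cfg <- bioassay_sim_config(lt50_true = 7.5, slope_true = 1e6,
                             control_daily_hazard = 0, seed = 11)
  m <- gen_mortality(cfg)
  expect_true(all(m$n_dead_cum[m$day < 8] == 0))
  expect_true(all(m$n_dead_cum[m$day >= 8] == m$n_initial[m$day >= 8]))

  # midpoint far beyond the horizon, no background hazard: nobody dies
  cfg <- bioassay_sim_config(lt50_true = 500, slope_true = 0.5,
                             control_daily_hazard = 0, seed = 11)
  expect_true(all(gen_mortality(cfg)$n_dead_cum == 0))
})

test_that("mortality counts are cumulative, bounded, seed-reproducible", {
  cfg <- bioassay_sim_config(lt50_true = 9, slope_true = 0.6, seed = 42)
  m1 <- gen_mortality(cfg)
  m2 <- gen_mortality(cfg)
  expect_identical(m1, m2)
  m3 <- gen_mortality(bioassay_sim_config(lt50_true = 9, slope_true = 0.6,
                                          seed = 43))
  expect_false(identical(m1, m3))
  for (d in split(m1, m1$replicate)) {
    expect_false(is.unsorted(d$n_dead_cum))
    expect_true(all(d$n_dead_cum >= 0 & d$n_dead_cum <= d$n_initial))
  }
  expect_equal(nrow(m1), 15 * 3)
})

test_that("invalid simulation configs are rejected naming the field", {
  expect_error(bioassay_sim_config(lt50_true = -1, slope_true = 0.5),
               "lt50_true")
  expect_error(bioassay_sim_config(lt50_true = 10, slope_true = 0.5,
                                   control_daily_hazard = 1),
               "control_daily_hazard")
  expect_error(tpc_sim_config(plug_radius = 50), "plug_radius")
  expect_error(tpc_sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(transmission_sim_config(initial_load = 1e5,
                                       daily_retention = 0.8,
                                       sampling_days = c(3, 1)),
               "sampling_days")
  expect_error(survival_sim_config(c(a = 1.2)), "group_hazards")
})

test_that("noiseless radial growth reproduces the generating rate exactly", {
  pars <- list(mu_opt = 2, Tmin = 10, Topt = 27, Tmax = 40)
  cfg <- tpc_sim_config(true_model = "ctmi", true_params = pars,
                        noise_sd = 0, seed = 5)
  rates <- absolute_growth_rate(gen_radial_growth(cfg))
  expected <- eval_tpc("ctmi", pars, rates$temperature)
  expect_equal(rates$beta, expected, tolerance = 1e-10)
  # at Tmax the rate is 0: radii stay at the plug radius
  rg <- gen_radial_growth(cfg)
  at_tmax <- rg[rg$temperature == 40, ]
  expect_true(all(abs(c(at_tmax$q1, at_tmax$q2, at_tmax$q3, at_tmax$q4)
                      - cfg$plug_radius) < 1e-12))
})

test_that("radii stay inside [plug_radius, plate_radius_max]", {
  cfg <- tpc_sim_config(noise_sd = 5, seed = 8)  # huge noise forces clipping
  rg <- gen_radial_growth(cfg)
  r <- c(rg$q1, rg$q2, rg$q3, rg$q4)
  expect_true(all(r >= cfg$plug_radius - 1e-12))
  expect_true(all(r <= cfg$plate_radius_max + 1e-12))
})

test_that("germination counts follow the supplied temperature response", {
  temps <- c(15, 25, 35)
  all1 <- gen_germination(function(T) rep(1, length(T)), temps, seed = 2)
  expect_true(all(all1$n_germinated == 100))
  all0 <- gen_germination(function(T) rep(0, length(T)), temps, seed = 2)
  expect_true(all(all0$n_germinated == 0))
  # binomial mean: p = 0.8 -> mean percent germination ~ 80%
  means <- vapply(1:300, function(s) {
    g <- gen_germination(function(T) 0.8, 25, n_plates = 1, seed = s)
    percent_germination(g)$mean_pct
  }, numeric(1))
  se_mc <- sqrt(0.8 * 0.2 / (4 * 100)) * 100 / sqrt(300)
  expect_lt(abs(mean(means) - 80), 4 * se_mc)
})

test_that("survival generator handles extreme hazards and censoring", {
  all_die <- gen_survival(survival_sim_config(c(g = 1), seed = 1))
  expect_true(all(all_die$time == 1 & all_die$event == 1))
  none_die <- gen_survival(survival_sim_config(c(g = 0), seed = 1))
  expect_true(all(none_die$time == 15 & none_die$event == 0))
  mid <- gen_survival(survival_sim_config(c(g = 0.2), seed = 1))
  expect_true(all(mid$time >= 1 & mid$time <= 15))
  expect_true(all(mid$event[mid$time < 15] == 1))
})

test_that("transmission loads decay as configured", {
  cfg <- transmission_sim_config(initial_load = 1e6, daily_retention = 1,
                                 lognormal_sd = 0, seed = 3)
  expect_true(all(gen_transmission(cfg)$conidia_per_ml == 1e6))
  cfg0 <- transmission_sim_config(initial_load = 0, daily_retention = 0.5,
                                  seed = 3)
  expect_true(all(gen_transmission(cfg0)$conidia_per_ml == 0))
  # deterministic decay: fitted log-linear slope recovers ln(retention)
  cfg8 <- transmission_sim_config(initial_load = 1e6, daily_retention = 0.8,
                                  lognormal_sd = 0, seed = 3)
  rs <- retention_summary(gen_transmission(cfg8))
  expect_equal(rs$decay$slope, log(0.8), tolerance = 1e-10)
  expect_equal(rs$decay$daily_retention, 0.8, tolerance = 1e-10)
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  invisible(gen_mortality(bioassay_sim_config(lt50_true = 9,
                                              slope_true = 0.5, seed = 1)))
  invisible(gen_survival(survival_sim_config(c(a = 0.1), seed = 1)))
  expect_identical(before, .Random.seed)
})
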