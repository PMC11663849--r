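test_that("percent germination: mean, SE and the 80% viability gate", {
  perfect <- data.frame(n_germinated = rep(100, 4), n_scored = 100)
  pg <- percent_germination(perfect)
  expect_equal(pg$mean_pct, 100)
  expect_equal(pg$se_pct, 0)
  expect_true(pg$passes_gate)

  counts <- data.frame(n_germinated = c(90, 85, 80, 95), n_scored = 100)
  pg <- percent_germination(counts)
  expect_equal(pg$mean_pct, 87.5)
  expect_equal(pg$se_pct, sd(c(90, 85, 80, 95)) / 2, tolerance = 1e-12)
  expect_equal(round(pg$se_pct, 3), 3.227)

  # exactly 80% is excluded (gate is strict)
  at_gate <- data.frame(n_germinated = rep(80, 4), n_scored = 100)
  expect_false(percent_germination(at_gate)$passes_gate)
  expect_error(percent_germination(data.frame()), "coverslip")
})

test_that("cumulative mortality percent: replicate mean and SE", {
  rec <- data.frame(treatment_id = "t", replicate = c("R1", "R2", "R3"),
                    day = 15, n_initial = 30, n_dead_cum = c(27, 28, 30))
  s <- cumulative_mortality_pct(rec, day = 15)
  pct <- 100 * c(27, 28, 30) / 30
  expect_equal(s$mean_pct, mean(pct))
  expect_equal(round(s$mean_pct, 2), 94.44)
  expect_equal(s$se_pct, sd(pct) / sqrt(3), tolerance = 1e-12)

  all_dead <- transform(rec, n_dead_cum = 30)
  expect_equal(cumulative_mortality_pct(all_dead, 15)$mean_pct, 100)
  expect_equal(cumulative_mortality_pct(all_dead, 15)$se_pct, 0)
  none <- transform(rec, n_dead_cum = 0)
  expect_equal(cumulative_mortality_pct(none, 15)$mean_pct, 0)
})

test_that("Abbott correction: formula, floor, and monotonicity", {
  expect_equal(abbott_correct(70, 0)$corrected_pct, 70)
  expect_equal(abbott_correct(10, 10)$corrected_pct, 0)
  expect_equal(abbott_correct(55, 10)$corrected_pct, 50)
  expect_equal(abbott_correct(5, 10)$corrected_pct, 0)  # floored
  expect_error(abbott_correct(50, 100), "control")
  # monotone nondecreasing in treated for fixed control; 100 maps to 100
  for (ctrl in c(0, 5, 20, 60)) {
    treated <- seq(0, 100, by = 5)
    corr <- abbott_correct(treated, ctrl)$corrected_pct
    expect_false(is.unsorted(corr))
    expect_equal(corr[length(corr)], 100)
  }
})

test_that("time-mortality GLM inverts a noiseless logistic exactly", {
  days <- 1:15
  n <- 300
  dead <- round(n * plogis(0.8 * (days - 12)))
  rec <- data.frame(treatment_id = "t", replicate = "R1", day = days,
                    n_initial = n, n_dead_cum = dead)
  est <- fit_time_mortality(rec)
  expect_equal(est$lt50, 12, tolerance = 1e-2)
  expect_true(est$converged)
  expect_gt(est$slope, 0)
})

test_that("pooled GLM matches the brute-force grid-search ML", {
  day <- c(3, 7, 11)
  dead <- c(4, 15, 26)
  n <- c(30, 30, 30)
  rec <- data.frame(treatment_id = "t", replicate = "R1", day = day,
                    n_initial = n, n_dead_cum = dead)
  est <- fit_time_mortality(rec)
  oracle <- grid_ml_logistic(day, dead, n)
  expect_equal(est$lt50, unname(oracle["lt50"]), tolerance = 1e-4)
  expect_equal(est$slope, unname(oracle["b1"]), tolerance = 1e-3)
})

test_that("LT50 delta-method SE matches dose.p", {
  skip_if_not_installed("MASS")
  cfg <- bioassay_sim_config(lt50_true = 12, slope_true = 0.5,
                             control_daily_hazard = 0, seed = 21)
  m <- gen_mortality(cfg)
  est <- fit_time_mortality(m)
  dp <- MASS::dose.p(est$glm_fit, p = 0.5)
  expect_equal(est$lt50, unname(as.numeric(dp)), tolerance = 1e-10)
  expect_equal(est$se_naive, unname(attr(dp, "SE")[1, 1]), tolerance = 1e-10)
  # the cluster-robust SE is wider than the model-based one on real
  # (correlated cumulative) assay data
  expect_gt(est$se, est$se_naive)
})

test_that("LT50 bias shrinks as the assay grows", {
  bias_at <- function(n_rep) {
    est <- vapply(1:30, function(s) {
      cfg <- bioassay_sim_config(n_replicates = n_rep, lt50_true = 12,
                                 slope_true = 0.5,
                                 control_daily_hazard = 0, seed = s)
      fit_time_mortality(gen_mortality(cfg))$lt50
    }, numeric(1))
    abs(mean(est) - 12)
  }
  expect_lt(bias_at(30), max(bias_at(3), 0.2))
})

test_that("degenerate and Abbott-corrected fits are handled", {
  # monotone all-dead-from-day-1 data: flagged, not crashed
  rec <- data.frame(treatment_id = "t", replicate = "R1", day = 1:5,
                    n_initial = 30, n_dead_cum = 30)
  est <- suppressWarnings(fit_time_mortality(rec))
  expect_false(est$converged)
  # with a control series the treated percentages are Abbott-corrected
  cfg <- bioassay_sim_config(lt50_true = 10, slope_true = 0.6,
                             control_daily_hazard = 0.05, seed = 31)
  m <- gen_mortality(cfg)
  ctrl <- gen_mortality(bioassay_sim_config(lt50_true = 1000,
                                            slope_true = 0.6,
                                            control_daily_hazard = 0.05,
                                            seed = 32),
                        treatment_id = "control")
  est_raw <- fit_time_mortality(m)
  est_cor <- fit_time_mortality(m, control = ctrl)
  expect_true(is.finite(est_cor$lt50))
  expect_gte(est_cor$lt50, est_raw$lt50 - 1e-9)  # removing background deaths
})

test_that("SIT compatibility window classifies and partitions correctly", {
  expect_equal(as.character(classify_sit_compatible(9.3)$class), "too_fast")
  expect_equal(as.character(classify_sit_compatible(30)$class), "too_slow")
  expect_equal(as.character(classify_sit_compatible(13.3)$class),
               "compatible")
  # boundaries are compatible; the window partitions (0, Inf)
  expect_equal(as.character(classify_sit_compatible(c(10, 20))$class),
               c("compatible", "compatible"))
  lt <- c(0.5, 9.999, 10, 15, 20, 20.001, 100)
  cls <- classify_sit_compatible(lt)$class
  expect_false(any(is.na(cls)))
  expect_equal(as.character(cls),
               c("too_fast", "too_fast", "compatible", "compatible",
                 "compatible", "too_slow", "too_slow"))
  expect_error(classify_sit_compatible(Inf), "finite")
})

test_that("mortality record invariants are enforced", {
  bad <- data.frame(treatment_id = "t", replicate = "R1", day = 1:3,
                    n_initial = 30, n_dead_cum = c(5, 3, 8))
  expect_error(cumulative_mortality_pct(bad, 3), "decrease")
})
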