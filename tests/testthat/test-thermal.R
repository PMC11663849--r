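test_that("CTMI equals mu_opt at Topt and vanishes at the cardinal ends", {
  # algebraic identity, checked across many admissible parameter sets
  set.seed(1)
  for (i in 1:25) {
    tmin <- runif(1, -5, 15)
    tmax <- tmin + runif(1, 10, 35)
    # Topt above the Tmin/Tmax midpoint: the model's admissibility condition
    # (below it the denominator has a root inside the thermal range)
    topt <- runif(1, (tmin + tmax) / 2 + 0.2, tmax - 1)
    mu <- runif(1, 0.1, 5)
    p <- list(mu_opt = mu, Tmin = tmin, Topt = topt, Tmax = tmax)
    expect_equal(eval_tpc("ctmi", p, topt), mu, tolerance = 1e-12)
    expect_equal(eval_tpc("ctmi", p, c(tmin, tmax)), c(0, 0),
                 tolerance = 1e-12)
    # nonnegative and continuous inside the range
    tt <- seq(tmin, tmax, length.out = 200)
    v <- eval_tpc("ctmi", p, tt)
    expect_true(all(v >= 0))
    expect_lt(max(abs(diff(v))), mu)  # no jumps on a fine grid
  }
})

test_that("Lactin-1 (printed polynomial form) evaluates by hand", {
  p <- list(a = 1e-4, Tmin = 5, Tmax = 40)
  expect_equal(eval_tpc("lactin1", p, 25), 1e-4 * 400 * 15)  # = 0.6
  expect_equal(eval_tpc("lactin1", p, c(5, 40)), c(0, 0))
  expect_equal(eval_tpc("lactin1", p, c(0, 50)), c(0, 0))  # clamped outside
  expect_error(eval_tpc("ctmi", list(mu_opt = 1, Tmin = 30, Topt = 20,
                                     Tmax = 40), 25), "Tmin < Topt")
  expect_error(eval_tpc("ctmi", list(mu_opt = 1, Tmin = 10), 25),
               "parameter")
})

test_that("absolute growth rate equals closed-form OLS", {
  # exact line: radius = 2 + 1.5 day
  d <- expand.grid(day = 1:14)
  series <- data.frame(plate_id = "p1", strain = "s", temperature = 25,
                       day = d$day, q1 = 2 + 1.5 * d$day,
                       q2 = 2 + 1.5 * d$day, q3 = 2 + 1.5 * d$day,
                       q4 = 2 + 1.5 * d$day)
  gr <- absolute_growth_rate(series)
  expect_equal(gr$beta, 1.5, tolerance = 1e-12)
  expect_equal(gr$fit_r2, 1, tolerance = 1e-12)
  # constant radius: slope 0, r2 undefined
  flat <- transform(series, q1 = 4, q2 = 4, q3 = 4, q4 = 4)
  expect_equal(absolute_growth_rate(flat)$beta, 0, tolerance = 1e-12)
  expect_true(is.na(absolute_growth_rate(flat)$fit_r2))
  # noisy series matches the sum-formula OLS oracle
  set.seed(7)
  noisy <- series
  noisy[, c("q1", "q2", "q3", "q4")] <-
    noisy[, c("q1", "q2", "q3", "q4")] + rnorm(14 * 4, 0, 0.3)
  gr <- absolute_growth_rate(noisy)
  mean_r <- rowMeans(noisy[, c("q1", "q2", "q3", "q4")])
  oracle <- ols_hand(noisy$day, mean_r)
  expect_equal(gr$beta, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(gr$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  # single day errors
  expect_error(absolute_growth_rate(series[series$day == 1, ]), "days")
})

test_that("fit_tpc recovers generating parameters", {
  # linear rates on an exact line
  rates <- data.frame(temperature = rep(c(15, 20, 25, 30, 35, 40), each = 2),
                      beta = 0.1 + 0.05 * rep(c(15, 20, 25, 30, 35, 40),
                                              each = 2))
  f <- fit_tpc(rates, "linear")
  expect_equal(f$params$a, 0.1, tolerance = 1e-10)
  expect_equal(f$params$b, 0.05, tolerance = 1e-10)

  # ctmi noiseless self-recovery to 1e-3
  truth <- list(mu_opt = 2.0, Tmin = 10, Topt = 27, Tmax = 40)
  cfg <- tpc_sim_config(true_model = "ctmi", true_params = truth,
                        noise_sd = 0, seed = 99)
  r <- absolute_growth_rate(gen_radial_growth(cfg))
  f <- fit_tpc(r, "ctmi")
  expect_true(f$converged)
  for (nm in names(truth))
    expect_equal(f$params[[nm]], truth[[nm]], tolerance = 1e-3)

  # lactin1 on its own noiseless output: essentially zero RSS
  lp <- list(a = 5e-5, Tmin = 5, Tmax = 42)
  lr <- data.frame(temperature = rep(c(15, 20, 25, 30, 35, 40), each = 4))
  lr$beta <- eval_tpc("lactin1", lp, lr$temperature)
  fl <- fit_tpc(lr, "lactin1")
  expect_lt(fl$rss, 1e-10)
})

test_that("fit_tpc is deterministic and supports weights", {
  cfg <- tpc_sim_config(noise_sd = 0.1, seed = 13)
  r <- absolute_growth_rate(gen_radial_growth(cfg))
  f1 <- fit_tpc(r, "ctmi")
  f2 <- fit_tpc(r, "ctmi")
  expect_identical(unlist(f1$params), unlist(f2$params))
  fw <- fit_tpc(r, "ctmi", weights = "inverse_variance")
  expect_true(fw$converged)
  expect_error(fit_tpc(r, "ctmi", weights = rep(-1, nrow(r))), "weights")
})

test_that("Gaussian AIC and R2 measures match hand arithmetic", {
  expect_equal(aic_gaussian(6, 24, 4), 24 * log(0.25) + 10,
               tolerance = 1e-12)
  expect_equal(round(aic_gaussian(6, 24, 4), 4), -23.2711)
  # monotone in rss; parameter-count penalty is 2 per parameter
  expect_lt(aic_gaussian(3, 24, 4), aic_gaussian(6, 24, 4))
  expect_equal(aic_gaussian(6, 24, 4) - aic_gaussian(6, 24, 2), 4)
  obs <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  tss <- sum((obs - mean(obs))^2)
  rss <- 0.1 * tss  # pseudo_r2 = 0.9 by construction
  r2 <- r2_measures(rss, obs, k = 3)
  expect_equal(unname(r2["pseudo_r2"]), 0.9, tolerance = 1e-12)
  expect_equal(unname(r2["adj_r2"]), 1 - 0.1 * 9 / 6, tolerance = 1e-12)
  # perfect fit
  expect_equal(unname(r2_measures(0, obs, 3)["pseudo_r2"]), 1)
  expect_equal(unname(r2_measures(0, obs, 3)["adj_r2"]), 1)
  # intercept-only fit at the mean: pseudo_r2 = 0
  expect_equal(unname(r2_measures(tss, obs, 0)["pseudo_r2"]), 0)
})

test_that("Vuong test: antisymmetry, degeneracy, and direct-sum oracle", {
  cfg <- tpc_sim_config(noise_sd = 0.1, seed = 17)
  r <- absolute_growth_rate(gen_radial_growth(cfg))
  fc <- fit_tpc(r, "ctmi")
  fl <- fit_tpc(r, "linear")
  v_ab <- vuong_test(fc, fl)
  v_ba <- vuong_test(fl, fc)
  expect_equal(v_ab$z, -v_ba$z, tolerance = 1e-12)
  expect_equal(v_ab$p, v_ba$p, tolerance = 1e-12)
  # identical fits are indistinguishable with z = 0
  v_same <- vuong_test(fc, fc)
  expect_equal(v_same$z, 0)
  expect_equal(v_same$verdict, "indistinguishable")
  # direct per-observation computation
  z_hand <- vuong_hand(fc$observed, fc$fitted, fc$rss, fl$fitted, fl$rss)
  expect_equal(v_ab$z, z_hand, tolerance = 1e-10)
  # mismatched observations rejected
  r2 <- r[-1, ]
  expect_error(vuong_test(fc, fit_tpc(r2, "linear")), "same observations")
})

test_that("model selection ranks by AIC with adj-R2 tie-breaking", {
  mk <- function(model, aic, adj) {
    structure(list(model = model, aic = aic, adj_r2 = adj, rss = 1,
                   n = 24, k = 2, converged = TRUE,
                   params = list(), temperature = 1:24,
                   observed = rnorm(24), fitted = rnorm(24),
                   weights = rep(1, 24)),
              class = "tpc_fit")
  }
  sel <- select_model(list(mk("a", -5, 0.5), mk("b", -20, 0.9),
                           mk("c", 3, 0.2)))
  expect_equal(sel$best_model, "b")
  # |dAIC| < 2: higher adjusted R2 wins
  sel <- select_model(list(mk("a", -20.0, 0.90), mk("b", -19.5, 0.95)))
  expect_equal(sel$best_model, "b")
  # exact tie on both criteria is flagged for a Vuong test
  sel <- select_model(list(mk("a", -20, 0.9), mk("b", -20, 0.9)))
  expect_setequal(sel$vuong_candidates, c("a", "b"))
})

test_that("cardinal summary collects ranges and ignores strain order", {
  topts <- c(29.5, 30.8, 27.5, 26.7, 31.1)
  per <- lapply(seq_along(topts), function(i)
    list(Tmin = 5 + i, Topt = topts[i], Tmax = 40 + i))
  names(per) <- paste0("s", seq_along(topts))
  cs <- cardinal_summary(per)
  expect_equal(cs$topt_range, c(26.7, 31.1))
  expect_equal(cs$overall_tmin, 6)
  expect_equal(cs$overall_tmax, 45)
  cs_perm <- cardinal_summary(per[c(3, 5, 1, 2, 4)])
  expect_equal(cs_perm$topt_range, cs$topt_range)
  expect_equal(cs_perm$overall_tmin, cs$overall_tmin)
  single <- cardinal_summary(per[1])
  expect_equal(single$topt_range, c(29.5, 29.5))
})
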