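#' Synthetic-data generators for the EPF + SIT analysis pipeline
#'
#' The raw bioassay data behind dual EPF + SIT suppression studies are
#' typically unpublished, so every pipeline input can be generated
#' synthetically with the same designs: 30 flies x 3 replicates observed
#' daily over 15 days for mortality; 100 conidia x 4 coverslips for
#' germination; daily colony radii over 4 quadrants x 14 days at
#' {15, 20, 25, 30, 35, 40} degC x 4 plates; individual survival times with
#' day-15 administrative censoring; and hemocytometer conidia loads at days
#' 1, 3, 5 post-exposure. All generators are deterministic for a fixed seed
#' (RNG state is saved and restored).
#'
#' @name epfsit-simulation
NULL

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg)
}

#' Bioassay simulation configuration
#'
#' @param n_flies_per_replicate flies per replicate cage (default 30).
#' @param n_replicates replicate cages per treatment (default 3).
#' @param lt50_true true median lethal time, days (> 0).
#' @param slope_true logistic steepness of the fungus-induced cumulative
#'   death probability, per day.
#' @param control_daily_hazard daily probability of background (non-fungal)
#'   death, in [0, 1); default 0.005.
#' @param horizon observation window in days (default 15).
#' @param seed integer RNG seed.
#' @return list of class `bioassay_sim_config`.
#' @export
bioassay_sim_config <- function(n_flies_per_replicate = 30, n_replicates = 3,
                                lt50_true, slope_true,
                                control_daily_hazard = 0.005,
                                horizon = 15, seed = 1) {
  check_field(n_flies_per_replicate >= 1, "n_flies_per_replicate", ">= 1")
  check_field(n_replicates >= 1, "n_replicates", ">= 1")
  check_field(is.numeric(lt50_true) && lt50_true > 0, "lt50_true", "> 0")
  check_field(is.numeric(slope_true) && slope_true > 0, "slope_true", "> 0")
  check_field(control_daily_hazard >= 0 && control_daily_hazard < 1,
              "control_daily_hazard", "in [0, 1)")
  check_field(horizon >= 1, "horizon", ">= 1")
  structure(list(n_flies_per_replicate = n_flies_per_replicate,
                 n_replicates = n_replicates, lt50_true = lt50_true,
                 slope_true = slope_true,
                 control_daily_hazard = control_daily_hazard,
                 horizon = horizon, seed = seed),
            class = "bioassay_sim_config")
}

#' Generate cumulative mortality records
#'
#' Each fly's death day is the earlier of two competing processes: a
#' background geometric process with daily hazard `control_daily_hazard`,
#' and a fungus-induced process whose cumulative death probability by
#' integer day t is logistic, `plogis(slope_true * (t - lt50_true))` (the
#' fly dies on the first observation day at which its uniform draw falls
#' below the cumulative curve). Flies alive at the horizon stay alive.
#'
#' @param cfg a [bioassay_sim_config()].
#' @param treatment_id label for the treatment column (default `"treated"`).
#' @return mortality data.frame: `treatment_id`, `replicate`, `day`,
#'   `n_initial`, `n_dead_cum` (cumulative counts, nondecreasing in day).
#' @export
gen_mortality <- function(cfg, treatment_id = "treated") {
  stopifnot(inherits(cfg, "bioassay_sim_config"))
  with_seed(cfg$seed, {
    days <- seq_len(cfg$horizon)
    Fcum <- stats::plogis(cfg$slope_true * (days - cfg$lt50_true))
    out <- lapply(seq_len(cfg$n_replicates), function(rep_i) {
      n <- cfg$n_flies_per_replicate
      u <- stats::runif(n)
      fungus_day <- vapply(u, function(ui) {
        hit <- which(Fcum >= ui)
        if (length(hit)) hit[1] else Inf
      }, numeric(1))
      bg_day <- if (cfg$control_daily_hazard > 0)
        stats::rgeom(n, cfg$control_daily_hazard) + 1 else rep(Inf, n)
      death <- pmin(fungus_day, bg_day)
      dead_cum <- vapply(days, function(d) sum(death <= d), numeric(1))
      data.frame(treatment_id = treatment_id, replicate = paste0("R", rep_i),
                 day = days, n_initial = n, n_dead_cum = dead_cum,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Thermal-growth simulation configuration
#'
#' @param true_model,true_params generating TPC model and parameters
#'   (see [eval_tpc()]).
#' @param temperatures incubation temperatures, degC
#'   (default `c(15, 20, 25, 30, 35, 40)`).
#' @param n_plates plates per temperature (default 4).
#' @param n_days daily measurements (default 14).
#' @param plug_radius starting agar-plug radius, mm (default 4).
#' @param plate_radius_max plate edge, mm (default 45; half a 9 cm dish).
#' @param noise_sd Gaussian measurement noise on each quadrant radius, mm.
#' @param seed integer RNG seed.
#' @return list of class `tpc_sim_config`.
#' @export
tpc_sim_config <- function(true_model = "ctmi",
                           true_params = list(mu_opt = 2, Tmin = 10,
                                              Topt = 27, Tmax = 40),
                           temperatures = c(15, 20, 25, 30, 35, 40),
                           n_plates = 4, n_days = 14, plug_radius = 4,
                           plate_radius_max = 45, noise_sd = 0.1, seed = 1) {
  check_field(true_model %in% c("linear", "lactin1", "ctmi"),
              "true_model", "one of linear, lactin1, ctmi")
  check_field(length(temperatures) >= 1, "temperatures", "nonempty")
  check_field(noise_sd >= 0, "noise_sd", ">= 0")
  check_field(plug_radius < plate_radius_max, "plug_radius",
              "< plate_radius_max")
  eval_tpc(true_model, true_params, temperatures)  # validates params
  structure(list(true_model = true_model, true_params = true_params,
                 temperatures = temperatures, n_plates = n_plates,
                 n_days = n_days, plug_radius = plug_radius,
                 plate_radius_max = plate_radius_max, noise_sd = noise_sd,
                 seed = seed),
            class = "tpc_sim_config")
}

#' Generate radial-growth series
#'
#' Quadrant radius on day d at temperature T is
#' `plug_radius + rate(T) * d + N(0, noise_sd)`, truncated to
#' `[plug_radius, plate_radius_max]` (colonies cannot shrink below the plug
#' or grow past the plate edge); truncation, not resampling, so noisy series
#' need not be monotone.
#'
#' @param cfg a [tpc_sim_config()].
#' @param strain strain label (default `"SIM"`).
#' @return data.frame: `plate_id`, `strain`, `temperature`, `day`,
#'   `q1`..`q4` (mm).
#' @export
gen_radial_growth <- function(cfg, strain = "SIM") {
  stopifnot(inherits(cfg, "tpc_sim_config"))
  with_seed(cfg$seed, {
    rate <- eval_tpc(cfg$true_model, cfg$true_params, cfg$temperatures)
    grid <- expand.grid(day = seq_len(cfg$n_days),
                        plate = seq_len(cfg$n_plates),
                        ti = seq_along(cfg$temperatures))
    m <- nrow(grid)
    mean_r <- cfg$plug_radius + rate[grid$ti] * grid$day
    qs <- matrix(stats::rnorm(4 * m, mean = rep(mean_r, 4),
                              sd = cfg$noise_sd), ncol = 4)
    qs <- pmin(pmax(qs, cfg$plug_radius), cfg$plate_radius_max)
    out <- data.frame(
      plate_id = sprintf("T%g_P%d", cfg$temperatures[grid$ti], grid$plate),
      strain = strain,
      temperature = cfg$temperatures[grid$ti],
      day = grid$day,
      q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3], q4 = qs[, 4],
      stringsAsFactors = FALSE)
    out[order(out$temperature, out$plate_id, out$day), ]
  })
}

#' Generate germination counts
#'
#' Each coverslip scores 100 conidia; the germinated count is
#' `Binomial(n_conidia, p(T))` with `p(T)` a supplied unimodal temperature
#' response, clipped to [0, 1].
#'
#' @param prob_fun function of temperature returning germination probability.
#' @param temperatures numeric vector of temperatures, degC.
#' @param n_plates plates per temperature (default 4).
#' @param n_coverslips coverslips per plate (default 4).
#' @param n_conidia conidia scored per coverslip (default 100).
#' @param seed integer RNG seed.
#' @return data.frame: `temperature`, `plate_id`, `coverslip_index`,
#'   `n_germinated`, `n_scored`.
#' @export
gen_germination <- function(prob_fun, temperatures, n_plates = 4,
                            n_coverslips = 4, n_conidia = 100, seed = 1) {
  stopifnot(is.function(prob_fun), length(temperatures) >= 1)
  with_seed(seed, {
    grid <- expand.grid(coverslip_index = seq_len(n_coverslips),
                        plate = seq_len(n_plates),
                        ti = seq_along(temperatures))
    p <- pmin(pmax(prob_fun(temperatures[grid$ti]), 0), 1)
    data.frame(temperature = temperatures[grid$ti],
               plate_id = sprintf("T%g_P%d", temperatures[grid$ti],
                                  grid$plate),
               coverslip_index = grid$coverslip_index,
               n_germinated = stats::rbinom(nrow(grid), n_conidia, p),
               n_scored = n_conidia, stringsAsFactors = FALSE)
  })
}

#' Survival simulation configuration
#'
#' @param group_hazards named numeric vector/list mapping group label to the
#'   daily death hazard, each in [0, 1].
#' @param n_per_group subjects per group (default 30).
#' @param censor_day administrative censoring day (default 15).
#' @param seed integer RNG seed.
#' @return list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(group_hazards, n_per_group = 30,
                                censor_day = 15, seed = 1) {
  h <- unlist(group_hazards)
  check_field(length(h) >= 1 && !is.null(names(h)) && all(nzchar(names(h))),
              "group_hazards", "named, nonempty")
  check_field(all(h >= 0 & h <= 1), "group_hazards", "hazards in [0, 1]")
  check_field(n_per_group >= 1, "n_per_group", ">= 1")
  check_field(censor_day >= 1, "censor_day", ">= 1")
  structure(list(group_hazards = h, n_per_group = n_per_group,
                 censor_day = censor_day, seed = seed),
            class = "survival_sim_config")
}

#' Generate individual survival records
#'
#' Death days are geometric with the group's daily hazard (support 1, 2,
#' ...); subjects still alive at `censor_day` are censored there
#' (`event = 0`).
#'
#' @param cfg a [survival_sim_config()].
#' @return data.frame: `subject_id`, `group`, `time`, `event`.
#' @export
gen_survival <- function(cfg) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  with_seed(cfg$seed, {
    out <- lapply(names(cfg$group_hazards), function(g) {
      h <- cfg$group_hazards[[g]]
      day <- if (h >= 1) rep(1, cfg$n_per_group)
        else if (h <= 0) rep(Inf, cfg$n_per_group)
        else stats::rgeom(cfg$n_per_group, h) + 1
      event <- as.integer(day <= cfg$censor_day)
      time <- pmin(day, cfg$censor_day)
      data.frame(subject_id = paste0(g, "_", seq_len(cfg$n_per_group)),
                 group = g, time = time, event = event,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Transmission simulation configuration
#'
#' @param initial_load conidia/mL carried immediately after contact (>= 0).
#' @param daily_retention fraction of the load retained per day, in (0, 1].
#' @param sampling_days strictly increasing sampling days
#'   (default `c(1, 3, 5)`).
#' @param n_flies_per_day flies sampled per day per replicate (default 3).
#' @param n_replicates replicates (default 3).
#' @param lognormal_sd SD of the multiplicative log-normal noise
#'   (default 0.3).
#' @param seed integer RNG seed.
#' @return list of class `transmission_sim_config`.
#' @export
transmission_sim_config <- function(initial_load, daily_retention,
                                    sampling_days = c(1, 3, 5),
                                    n_flies_per_day = 3, n_replicates = 3,
                                    lognormal_sd = 0.3, seed = 1) {
  check_field(initial_load >= 0, "initial_load", ">= 0")
  check_field(daily_retention > 0 && daily_retention <= 1,
              "daily_retention", "in (0, 1]")
  check_field(length(sampling_days) >= 1 &&
              all(diff(sampling_days) > 0), "sampling_days",
              "strictly increasing")
  check_field(lognormal_sd >= 0, "lognormal_sd", ">= 0")
  structure(list(initial_load = initial_load,
                 daily_retention = daily_retention,
                 sampling_days = sampling_days,
                 n_flies_per_day = n_flies_per_day,
                 n_replicates = n_replicates, lognormal_sd = lognormal_sd,
                 seed = seed),
            class = "transmission_sim_config")
}

#' Generate per-fly conidia loads
#'
#' The load on day d is `initial_load * daily_retention^d *
#' exp(N(0, lognormal_sd))`: exponential decay of the acquired conidia with
#' multiplicative log-normal noise (loads are positive and right-skewed).
#'
#' @param cfg a [transmission_sim_config()].
#' @param sex,role,irradiated labels attached to every generated fly
#'   (defaults `"F"`, `"receiver"`, `FALSE`).
#' @return data.frame: `fly_id`, `sex`, `role`, `irradiated`,
#'   `day_post_exposure`, `conidia_per_ml`.
#' @export
gen_transmission <- function(cfg, sex = "F", role = "receiver",
                             irradiated = FALSE) {
  stopifnot(inherits(cfg, "transmission_sim_config"))
  with_seed(cfg$seed, {
    grid <- expand.grid(fly = seq_len(cfg$n_flies_per_day),
                        rep = seq_len(cfg$n_replicates),
                        day = cfg$sampling_days)
    noise <- if (cfg$lognormal_sd > 0)
      exp(stats::rnorm(nrow(grid), 0, cfg$lognormal_sd)) else rep(1, nrow(grid))
    data.frame(fly_id = sprintf("D%d_R%d_F%d", grid$day, grid$rep, grid$fly),
               sex = sex, role = role, irradiated = irradiated,
               day_post_exposure = grid$day,
               conidia_per_ml = cfg$initial_load *
                 cfg$daily_retention^grid$day * noise,
               stringsAsFactors = FALSE)
  })
}
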