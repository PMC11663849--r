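#' Default pipeline configuration
#'
#' One configuration object drives the whole synthetic workflow: simulation
#' settings mirroring the study designs plus analysis options. The list can
#' also be written to / read from a YAML file ([yaml::write_yaml()] /
#' [read_pipeline_config()]).
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return nested named list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "bioassay", "thermal", "survival",
               "transmission"),
    bioassay = list(lt50_true = 13, slope_true = 0.5,
                    control_daily_hazard = 0.005,
                    link = "logit", window = c(10, 20)),
    thermal = list(true_model = "ctmi",
                   true_params = list(mu_opt = 2, Tmin = 10, Topt = 27,
                                      Tmax = 40),
                   noise_sd = 0.1,
                   models = c("linear", "lactin1", "ctmi")),
    survival = list(group_hazards = list(donor = 0.08, receiver = 0.06,
                                         control = 0.02),
                    n_per_group = 30, censor_day = 15),
    transmission = list(initial_load = 2e6, daily_retention = 0.8,
                        lognormal_sd = 0.3),
    alpha = 0.05)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys override [default_pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = if (!is.null(user$seed)) user$seed
                                 else 1)
  modifyList(cfg, user)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in order (simulate, then bioassay, thermal,
#' survival and transmission analyses) and writes each stage's tables under
#' `out_dir`. Every run is fully determined by `(config, seed)`; a
#' `manifest.csv` with the seed and a configuration hash is written
#' alongside the outputs.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir output directory (created if needed), or `NULL` to return
#'   results without writing.
#' @param quiet suppress the per-stage progress lines on stderr.
#' @return named list of stage results, invisibly when writing.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[epfsit] ", ...)
  res <- list(seed = config$seed, config_hash = config_hash(config))
  stages <- config$stages
  seed <- config$seed

  if ("simulate" %in% stages || length(intersect(
      c("bioassay", "thermal", "survival", "transmission"), stages))) {
    say("simulate: generating all inputs (seed ", seed, ")")
    bcfg <- config$bioassay
    res$mortality <- gen_mortality(bioassay_sim_config(
      lt50_true = bcfg$lt50_true, slope_true = bcfg$slope_true,
      control_daily_hazard = bcfg$control_daily_hazard, seed = seed))
    res$control_mortality <- gen_mortality(bioassay_sim_config(
      lt50_true = 1000, slope_true = bcfg$slope_true,
      control_daily_hazard = max(bcfg$control_daily_hazard, 1e-6),
      seed = seed + 1L), treatment_id = "control")
    tcfg <- config$thermal
    res$radial_growth <- gen_radial_growth(tpc_sim_config(
      true_model = tcfg$true_model, true_params = tcfg$true_params,
      noise_sd = tcfg$noise_sd, seed = seed + 2L))
    res$survival_records <- gen_survival(survival_sim_config(
      group_hazards = config$survival$group_hazards,
      n_per_group = config$survival$n_per_group,
      censor_day = config$survival$censor_day, seed = seed + 3L))
    xcfg <- config$transmission
    res$conidia_loads <- rbind(
      gen_transmission(transmission_sim_config(
        initial_load = xcfg$initial_load,
        daily_retention = xcfg$daily_retention,
        lognormal_sd = xcfg$lognormal_sd, seed = seed + 4L),
        sex = "F", role = "receiver", irradiated = FALSE),
      gen_transmission(transmission_sim_config(
        initial_load = xcfg$initial_load,
        daily_retention = xcfg$daily_retention,
        lognormal_sd = xcfg$lognormal_sd, seed = seed + 5L),
        sex = "M", role = "receiver", irradiated = TRUE))
  }

  if ("bioassay" %in% stages) {
    say("bioassay: LT50 and SIT compatibility")
    est <- fit_time_mortality(res$mortality, link = config$bioassay$link)
    res$lt50 <- data.frame(treatment_id = res$mortality$treatment_id[1],
                           lt50 = est$lt50, se = est$se, slope = est$slope,
                           slope_se = est$slope_se,
                           converged = est$converged)
    res$compatibility <- classify_sit_compatible(
      est$lt50, window = config$bioassay$window,
      strain = res$mortality$treatment_id[1])
    res$mortality_summary <- cumulative_mortality_pct(res$mortality)
  }

  if ("thermal" %in% stages) {
    say("thermal: growth rates and TPC model selection")
    rates <- absolute_growth_rate(res$radial_growth)
    res$growth_rates <- rates
    fits <- lapply(config$thermal$models, function(m)
      fit_tpc(rates, model = m))
    sel <- select_model(fits)
    res$tpc_fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(strain = rates$strain[1], model = f$model,
                 params = paste(names(f$params),
                                signif(unlist(f$params), 6),
                                sep = "=", collapse = ";"),
                 rss = f$rss, aic = f$aic, pseudo_r2 = f$pseudo_r2,
                 adj_r2 = f$adj_r2, converged = f$converged,
                 stringsAsFactors = FALSE)))
    res$best_model <- sel$best_model
    if (sel$best$model == "ctmi") {
      cs <- cardinal_summary(stats::setNames(list(sel$best),
                                             rates$strain[1]))
      res$cardinal_summary <- cs$per_strain
    }
  }

  if ("survival" %in% stages) {
    say("survival: Kaplan-Meier and log-rank")
    km <- lapply(split(res$survival_records, res$survival_records$group),
                 km_estimate)
    res$km_curves <- do.call(rbind, lapply(names(km), function(g) {
      k <- km[[g]]
      if (length(k$times) == 0) return(NULL)
      data.frame(group = g, time = k$times, n_at_risk = k$n_at_risk,
                 n_events = k$n_events, survival = k$survival,
                 greenwood_se = k$greenwood_se, stringsAsFactors = FALSE)
    }))
    lr <- logrank_test(res$survival_records)
    res$logrank <- data.frame(chi2 = lr$chi2, df = lr$df, p = lr$p)
  }

  if ("transmission" %in% stages) {
    say("transmission: conidia loads and retention")
    rs <- retention_summary(res$conidia_loads)
    res$retention_by_day <- rs$by_day
    res$retention_decay <- rs$decay
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("mortality", "control_mortality", "mortality_summary",
                "lt50", "compatibility", "radial_growth", "growth_rates",
                "tpc_fits", "cardinal_summary", "survival_records",
                "km_curves", "logrank", "conidia_loads",
                "retention_by_day", "retention_decay")
    for (tb in intersect(tables, names(res)))
      if (is.data.frame(res[[tb]]))
        write_table(res[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    write_table(data.frame(seed = res$seed, config_hash = res$config_hash),
                file.path(out_dir, "manifest.csv"))
    say("wrote outputs to ", out_dir, " (config ", res$config_hash, ")")
    return(invisible(res))
  }
  res
}
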