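#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume, mirroring the study
# designs: 30 flies x 3 replicates x 15 days of mortality per treatment,
# radial growth at 15-40 degC x 4 plates x 14 days, germination counts,
# individual survival with day-15 censoring, and conidia loads at days
# 1/3/5 post-exposure. Writes CSVs under results/data/.

suppressPackageStartupMessages(library(epfsit))
seed <- 20260928L
out <- "results/data"

# a small virulence panel: fast, SIT-compatible and slow killers
panel <- list(fast = 8, compatible = 13, slow = 22)
mort <- do.call(rbind, lapply(names(panel), function(s)
  gen_mortality(bioassay_sim_config(lt50_true = panel[[s]],
                                    slope_true = 0.5, seed = seed +
                                      match(s, names(panel))),
                treatment_id = s)))
ctrl <- gen_mortality(bioassay_sim_config(lt50_true = 1000, slope_true = 0.5,
                                          control_daily_hazard = 0.005,
                                          seed = seed + 10L),
                      treatment_id = "control")
write_table(rbind(mort, ctrl), file.path(out, "mortality.csv"))

# two thermally distinct strains
tpc_truth <- list(
  SIM_A = list(mu_opt = 2.1, Tmin = 11, Topt = 28, Tmax = 41),
  SIM_B = list(mu_opt = 1.6, Tmin = 9, Topt = 30, Tmax = 42))
rg <- do.call(rbind, lapply(names(tpc_truth), function(s)
  gen_radial_growth(tpc_sim_config(true_params = tpc_truth[[s]],
                                   noise_sd = 0.1,
                                   seed = seed + match(s, names(tpc_truth))),
                    strain = s)))
write_table(rg, file.path(out, "radial_growth.csv"))

germ <- gen_germination(function(T) eval_tpc("ctmi",
                                             list(mu_opt = 0.95, Tmin = 5,
                                                  Topt = 28, Tmax = 42), T),
                        temperatures = c(15, 20, 25, 30, 35, 40),
                        seed = seed + 20L)
write_table(germ, file.path(out, "germination.csv"))

surv <- gen_survival(survival_sim_config(
  group_hazards = c(donor_M = 0.09, receiver_F = 0.07, control = 0.02),
  seed = seed + 30L))
write_table(surv, file.path(out, "survival.csv"))

loads <- rbind(
  gen_transmission(transmission_sim_config(initial_load = 2.5e6,
                                           daily_retention = 0.8,
                                           seed = seed + 40L),
                   sex = "F", role = "receiver"),
  gen_transmission(transmission_sim_config(initial_load = 1.2e6,
                                           daily_retention = 0.75,
                                           seed = seed + 41L),
                   sex = "M", role = "receiver", irradiated = TRUE))
write_table(loads, file.path(out, "conidia_loads.csv"))

cat("simulated inputs written to", out, "(seed", seed, ")\n")
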