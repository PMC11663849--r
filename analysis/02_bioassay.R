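#!/usr/bin/env Rscript
# Virulence bioassay analysis: germination viability gate, cumulative
# mortality with Abbott control correction, LT50 per treatment, and the
# SIT-compatibility triage (both for the simulated panel and for the
# published LT50 estimates of the eleven-strain ICIPE panel).

suppressPackageStartupMessages(library(epfsit))

mort <- read_table("results/data/mortality.csv", "mortality")
germ <- read_table("results/data/germination.csv", "germination")

# viability gate: the pre-bioassay check is incubated at 25 degC
pg <- percent_germination(germ[germ$temperature == 25, ])
cat(sprintf("viability at 25 degC: %.1f +/- %.2f%% over %d coverslips -> gate %s\n",
            pg$mean_pct, pg$se_pct, pg$n_coverslips,
            if (pg$passes_gate) "PASS" else "FAIL"))
germ_by_temp <- do.call(rbind, lapply(split(germ, germ$temperature),
  function(d) {
    p <- percent_germination(d)
    data.frame(temperature = d$temperature[1], mean_pct = p$mean_pct,
               se_pct = p$se_pct)
  }))
write_table(germ_by_temp, "results/germination_by_temperature.csv")

summ <- cumulative_mortality_pct(mort)
ctrl_pct <- summ$mean_pct[summ$treatment_id == "control"]
summ$abbott_pct <- abbott_correct(summ$mean_pct, ctrl_pct)$corrected_pct
write_table(summ, "results/mortality_summary.csv")

treatments <- setdiff(unique(mort$treatment_id), "control")
ctrl <- mort[mort$treatment_id == "control", ]
lt50 <- do.call(rbind, lapply(treatments, function(tr) {
  est <- fit_time_mortality(mort[mort$treatment_id == tr, ])
  data.frame(treatment_id = tr, lt50 = est$lt50, se = est$se,
             slope = est$slope, converged = est$converged)
}))
write_table(lt50, "results/lt50.csv")
cat("LT50 (days +/- SE), pooled replicates:\n")
print(lt50, row.names = FALSE, digits = 4)

triage <- classify_sit_compatible(lt50$lt50, strain = lt50$treatment_id)
pub <- published_lt50()
pub_triage <- classify_sit_compatible(pub$lt50, strain = pub$strain)
write_table(rbind(cbind(panel = "simulated", triage),
                  cbind(panel = "published", pub_triage)),
            "results/compatibility.csv")
cat("\nSIT compatibility (10-20 day window), published panel:\n")
print(pub_triage, row.names = FALSE)
cat("simulated panel:\n")
print(triage, row.names = FALSE)
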