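#!/usr/bin/env Rscript
# Survival analysis of conidia donors and receivers: Kaplan-Meier curves
# per group, Mantel-Cox log-rank comparison, and the unpaired t-test
# comparing donor vs receiver median lethal times.

suppressPackageStartupMessages(library(epfsit))

surv <- read_table("results/data/survival.csv", "survival")

km_rows <- do.call(rbind, lapply(split(surv, surv$group), function(d) {
  k <- km_estimate(d)
  if (length(k$times) == 0) return(NULL)
  data.frame(group = d$group[1], time = k$times, n_at_risk = k$n_at_risk,
             n_events = k$n_events, survival = k$survival,
             greenwood_se = k$greenwood_se)
}))
write_table(km_rows, "results/km_curves.csv")

lr <- logrank_test(surv)
write_table(data.frame(chi2 = lr$chi2, df = lr$df, p = lr$p),
            "results/logrank.csv")
cat(sprintf("log-rank across %d groups: chi2 = %.3f, df = %d, p = %.4f\n",
            lr$df + 1, lr$chi2, lr$df, lr$p))

# donor vs receiver LT50s: per-replicate estimates feed an unpaired t-test
mort <- read_table("results/data/mortality.csv", "mortality")
donor_lt <- vapply(
  fit_time_mortality(mort[mort$treatment_id == "fast", ],
                     per_replicate = TRUE), `[[`, numeric(1), "lt50")
recv_lt <- vapply(
  fit_time_mortality(mort[mort$treatment_id == "compatible", ],
                     per_replicate = TRUE), `[[`, numeric(1), "lt50")
tt <- t_test_unpaired(donor_lt, recv_lt)
cat(sprintf("donor vs receiver LT50: t = %.3f, df = %d, p = %.4f\n",
            tt$t, tt$df, tt$p))
write_table(data.frame(t = tt$t, df = tt$df, p = tt$p,
                       mean_donor = tt$mean_a, mean_receiver = tt$mean_b),
            "results/donor_receiver_ttest.csv")
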