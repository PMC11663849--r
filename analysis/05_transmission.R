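#!/usr/bin/env Rscript
# Conidia acquisition and retention: per-group load summaries across days
# post-exposure, log-linear decay slopes, and an ANOVA + Tukey HSD with
# compact letters comparing loads across sampling days.

suppressPackageStartupMessages(library(epfsit))

loads <- read_table("results/data/conidia_loads.csv", "conidia_loads")

rs <- retention_summary(loads)
write_table(rs$by_day, "results/retention_by_day.csv")
write_table(rs$decay, "results/retention_decay.csv")
cat("retention by (role, sex, day):\n")
print(rs$by_day, row.names = FALSE, digits = 4)
cat("\nlog-linear decay (daily retention = exp(slope)):\n")
print(rs$decay, row.names = FALSE, digits = 4)

# do loads differ across sampling days? (female receivers)
fem <- loads[loads$sex == "F", ]
groups <- split(log10(fem$conidia_per_ml), paste0("day", fem$day_post_exposure))
an <- oneway_anova(groups)
cat(sprintf("\nANOVA on log10 loads across days: F(%d, %d) = %.2f, p = %.4g\n",
            an$df_between, an$df_within, an$f, an$p))
tk <- tukey_hsd(groups)
cl <- compact_letters(tk)
letters_df <- data.frame(group = names(cl), letters = unname(cl))
print(letters_df, row.names = FALSE)
write_table(cbind(tk$pairs), "results/retention_tukey.csv")
write_table(letters_df, "results/retention_letters.csv")
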