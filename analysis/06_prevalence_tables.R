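#!/usr/bin/env Rscript

# Stage 6 — cohort summaries, prevalence and stratified tables.
#
# Reproduces the descriptive products of a national survey report on the
# synthetic data: per-group summary statistics (ng/mL), prevalence below
# each threshold by group and by urban/rural, prevalence by wealth
# quintile, and the near/far proximity stratification against vertisol
# and water features. Writes results/group_summary.csv,
# results/prevalence*.csv and results/proximity_summary.csv.

suppressPackageStartupMessages(library(segeostat))

survey <- read_survey_csv("results/survey.csv")
th <- threshold_set()

gs <- summarize_groups(survey, c("group", "urban"))
write.csv(gs, "results/group_summary.csv", row.names = FALSE)

prev <- prevalence_below(survey, th, strata = c("group", "urban"))
write.csv(prev, "results/prevalence.csv", row.names = FALSE)
prev_w <- prevalence_below(survey, th, strata = "wealth_quintile")
write.csv(prev_w, "results/prevalence_wealth.csv", row.names = FALSE)

prox <- stratify_by_proximity(survey, vertisol_cutoff = 10,
                              water_cutoff = 30)
write.csv(prox, "results/proximity_summary.csv", row.names = FALSE)

pooled <- prevalence_below(survey, th, strata = NULL)
message(sprintf(
  "pooled prevalence: %.1f%% below GPx3, %.1f%% below IDI, %.1f%% below KD",
  pooled$pct_GPx3, pooled$pct_IDI, pooled$pct_KD))
message(sprintf("near/far proximity means: %.1f vs %.1f ng/mL",
                prox$mean[prox$proximity == "near"],
                prox$mean[prox$proximity == "far"]))
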