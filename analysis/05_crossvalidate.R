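#!/usr/bin/env Rscript

# Stage 5 — leave-one-out cross-validation of the fitted model.
#
# Predicts each observation from the rest with plug-in REML parameters,
# summarizes the standardized squared prediction error (SSPE), checks the
# normality of standardized errors, and simulates a correlation-aware 95%
# reference interval for the median SSPE under a valid model. Writes
# results/cv_table.csv and results/cv_summary.json.

suppressPackageStartupMessages(library(segeostat))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

survey <- read_survey_csv("results/survey.csv")
model <- read_model_json("results/model.json")

cv <- loo_crossvalidate(survey, model)
write.csv(cv, "results/cv_table.csv", row.names = FALSE)

summ <- sspe_summary(cv)
nc <- normality_check(cv)
interval <- median_sspe_interval(survey, model, n_sim = 200, seed = seed)

jsonlite::write_json(
  list(median_theta = summ$median_theta, mean_theta = summ$mean_theta,
       n = summ$n, n_flagged = summ$n_flagged,
       skewness = nc$skewness, excess_kurtosis = nc$excess_kurtosis,
       median_interval = c(interval$lower, interval$upper)),
  "results/cv_summary.json", auto_unbox = TRUE, digits = NA)

message(sprintf("median SSPE = %.3f (mean %.3f, n = %d)",
                summ$median_theta, summ$mean_theta, summ$n))
message(sprintf("95%% reference interval for the median under a valid model: [%.3f, %.3f]",
                interval$lower, interval$upper))
message(sprintf("standardized errors: skewness %.3f, excess kurtosis %.3f",
                nc$skewness, nc$excess_kurtosis))
inside <- summ$median_theta >= interval$lower &
  summ$median_theta <= interval$upper
message("observed median falls ", if (inside) "inside" else "OUTSIDE",
        " the valid-model interval")
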