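#!/usr/bin/env Rscript

# Stage 1 — simulate a national plasma Se survey.
#
# The analysed survey data are not public, so the workflow runs on a
# synthetic survey with the same statistical anatomy: 102 clusters (18
# urban, 84 rural) placed over a 160 x 850 km region, 9 households per
# cluster, 2 women of reproductive age per household, and log plasma Se
# generated from a constant mean plus spatially correlated cluster
# effects (Matern nu = 0.5, phi = 39.4 km, sigma2_c = 0.15), household
# effects (sigma2_h = 0.018) and individual effects (sigma2_e = 0.028).
# Writes results/survey.csv and results/region.geojson.

suppressPackageStartupMessages(library(segeostat))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

region <- region_rectangle()           # 160 x 850 km, Malawi-like aspect
design <- generate_design(region = region, seed = seed)
params <- generative_params(mu = log(80))
survey <- simulate_survey(design, params, seed = seed)

# proximity covariates against a stylised vertisol belt and a lake/river
# line along the eastern edge, for the proximity stratification stage
vertisol <- feature(rbind(c(120, 300), c(160, 300), c(160, 700),
                          c(120, 700)), "polygon")
water <- feature(rbind(c(160, 0), c(160, 850)), "line")
survey <- attach_proximity_covariates(survey, list(vertisol), list(water))

write_survey_csv(survey, "results/survey.csv")
write_region_geojson(region, "results/region.geojson")

message(sprintf("simulated %d individuals in %d households, %d clusters",
                nrow(survey), length(unique(survey$household_id)),
                length(unique(survey$cluster_id))))
message(sprintf("median plasma Se %.1f ng/mL (range %.1f-%.1f)",
                median(survey$plasma_se), min(survey$plasma_se),
                max(survey$plasma_se)))
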