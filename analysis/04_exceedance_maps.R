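#!/usr/bin/env Rscript

# Stage 4 — threshold exceedance probabilities on the verbal scale.
#
# For each grid node, the probability that an individual's plasma Se falls
# below the selenoprotein thresholds (GPx3 84.9, IDI 64.8, KD 30 ng/mL),
# classified on the five-bin calibrated verbal scale for map legends.
# Writes results/exceedance.csv and results/verbal_legend.json.

suppressPackageStartupMessages(library(segeostat))

pred <- read.csv("results/grid_predictions.csv")
th <- threshold_set()
sc <- verbal_scale()

exc <- map_exceedance(pred, th, sc)
write.csv(exc, "results/exceedance.csv", row.names = FALSE)
jsonlite::write_json(list(edges = sc$edges, labels = sc$labels),
                     "results/verbal_legend.json", auto_unbox = TRUE,
                     digits = NA)

for (nm in names(th)) {
  p <- exc[[paste0("p_", nm)]]
  message(sprintf(
    "below %s (%.1f ng/mL): mean probability %.2f; %d%% of nodes 'likely' or worse",
    nm, th[[nm]], mean(p),
    round(100 * mean(p >= 0.66))))
}
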