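#!/usr/bin/env Rscript
# Stage 2: preprocess record-only features and train per-subject recall
# classifiers (L2-penalized logistic regression, C = 2.4e-4, inverse-class
# weighting). Writes per-subject model JSON files and the normalization
# statistics the closed-loop stage will start from.

suppressMessages(library(memloop))

for (arm in c("lateral_temporal", "non_lateral")) {
  out <- file.path("results", arm)
  cfg <- read_config(file.path(out, "config.yaml"))
  run_pipeline(cfg, out, stages = c("preprocess", "train"))
  models <- list.files(out, pattern = "^model_.*json$")
  w <- sapply(models, function(f) sqrt(sum(read_model(file.path(out, f))$W^2)))
  cat(sprintf("%s: %d classifiers trained, median |W| = %.3g\n",
              arm, length(models), median(w)))
}
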