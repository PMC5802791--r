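#!/usr/bin/env Rscript
# Stage 3: replay the closed-loop sessions. Each trained classifier decodes
# every word-encoding event of its subject's closed-loop session online;
# on Stim lists a decoded recall probability below 0.5 triggers simulated
# stimulation, on NoStim lists below-threshold words are flagged as matched
# controls. Normalization statistics update after each NoStim list.

suppressMessages(library(memloop))

for (arm in c("lateral_temporal", "non_lateral")) {
  out <- file.path("results", arm)
  cfg <- read_config(file.path(out, "config.yaml"))
  run_pipeline(cfg, out, stages = "loop")
  log <- read.csv(file.path(out, "loop_log.csv"))
  stim <- log$role == "Stim"
  cat(sprintf("%s: trigger proportion on Stim lists = %.3f (%d of %d words)\n",
              arm, mean(log$trigger[stim]), sum(log$trigger[stim]), sum(stim)))
}
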