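#!/usr/bin/env Rscript
# Stage 4: estimate stimulation effects. Pools stimulated and matched
# control words across arms and fits: the binomial mixed model of recall on
# condition (odds ratio, per arm and with the condition x group
# interaction), the log-binomial relative-risk model, the flanking-word
# model, and the linear mixed model of the post-stimulation change in
# decoded probability. Writes results/effects.csv.

suppressMessages(library(memloop))

tabs <- lapply(c("lateral_temporal", "non_lateral"), function(arm) {
  out <- file.path("results", arm)
  ev <- read_events(file.path(out, "loop_events.csv"))
  lg <- read.csv(file.path(out, "loop_log.csv"))
  prim <- NULL; flank <- NULL; delta <- NULL
  for (id in unique(ev$subject)) {
    sub <- ev[ev$subject == id, ]
    mc <- match_controls(lg[lg$subject == id, ], sub)
    prim <- rbind(prim, mc$primary)
    flank <- rbind(flank, mc$flanking)
    delta <- rbind(delta, delta_classifier_table(NULL, sub))
  }
  prim$group <- arm; flank$group <- arm; delta$group <- arm
  list(prim = prim, flank = flank, delta = delta)
})
prim <- rbind(tabs[[1]]$prim, tabs[[2]]$prim)
prim$group <- factor(prim$group, levels = c("non_lateral", "lateral_temporal"))
flank <- rbind(tabs[[1]]$flank, tabs[[2]]$flank)
flank$group <- factor(flank$group, levels = c("non_lateral", "lateral_temporal"))

res <- rbind(
  cbind(arm = "lateral_temporal", fit_stim_glme(tabs[[1]]$prim),
        percent_change = NA),
  cbind(arm = "non_lateral", fit_stim_glme(tabs[[2]]$prim),
        percent_change = NA),
  cbind(arm = "both", fit_stim_glme(prim, include_group = TRUE),
        percent_change = NA),
  cbind(arm = "lateral_temporal", fit_log_binomial(tabs[[1]]$prim)),
  cbind(arm = "both", fit_flanking_glme(flank, include_group = FALSE),
        percent_change = NA),
  cbind(arm = "lateral_temporal",
        delta_classifier_analysis(tabs[[1]]$delta), percent_change = NA))
write.csv(res, "results/effects.csv", row.names = FALSE)
print(res[, c("arm", "estimand", "estimate", "se", "t", "df", "p")],
      digits = 3)
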