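test_that("the mixed model collapses to ordinary logistic regression without random effects", {
  # data generated with zero random-effect variance: the GLME estimate must
  # agree with the plain GLM on the same rows
  tr <- simulate_trials(12, 200, 0.26, log(1.3), subject_sd = 0, site_sd = 0,
                        subject_int_sd = 0, site_int_sd = 0, seed = 2)
  mixed <- fit_stim_glme(tr)
  plain <- fit_stim_glme(tr, random_effects = FALSE)
  ref <- glm(recalled ~ condition, binomial(), tr)
  expect_equal(plain$log_estimate, unname(coef(ref)["conditionStim"]),
               tolerance = 1e-8)
  # with no generating heterogeneity the mixed estimate sits close by
  expect_lt(abs(mixed$log_estimate - plain$log_estimate), 0.05)
})

test_that("mixed-model estimates are invariant to row order and id relabeling", {
  tr <- simulate_trials(10, 80, 0.26, log(1.2), seed = 3)
  a <- fit_stim_glme(tr)
  perm <- sample(nrow(tr))
  b <- fit_stim_glme(tr[perm, ])
  expect_equal(a$log_estimate, b$log_estimate, tolerance = 1e-3)
  relab <- tr
  relab$subject <- paste0("X", relab$subject)
  relab$site <- rev(sort(unique(relab$site)))[match(relab$site, sort(unique(relab$site)))]
  d <- fit_stim_glme(relab)
  expect_equal(a$log_estimate, d$log_estimate, tolerance = 1e-3)
})

test_that("stimulation odds ratio is recovered at the study design scale", {
  ors <- vapply(1:10, function(i) {
    tr <- simulate_trials(29, 130, 0.261, log(1.18), seed = 700 + i)
    fit_stim_glme(tr)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ors) - 1.18), 0.08)
})

test_that("the group interaction contrasts the two stimulation arms", {
  tr1 <- simulate_trials(15, 130, 0.261, log(1.18), group = "lateral_temporal",
                         seed = 11)
  tr2 <- simulate_trials(11, 130, 0.298, log(0.87), group = "non_lateral",
                         seed = 12)
  tr2$subject <- paste0("N", tr2$subject)
  tr2$site <- paste0("N", tr2$site)
  both <- rbind(tr1, tr2)
  both$group <- factor(both$group, levels = c("non_lateral", "lateral_temporal"))
  est <- fit_stim_glme(both, include_group = TRUE)
  expect_setequal(est$estimand, c("stimulation_OR", "condition_x_group"))
  # interaction OR should exceed 1: lateral temporal stimulation helps more
  expect_gt(est$estimate[est$estimand == "condition_x_group"], 1)
})

test_that("log-binomial relative risk equals the 2x2 contingency ratio exactly", {
  tr <- data.frame(
    recalled = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 24, 76)),
    condition = factor(rep(c("Stim", "Stim", "NoStim", "NoStim"),
                           c(30, 70, 24, 76)), levels = c("NoStim", "Stim")),
    subject = "S001", site = "T001")
  est <- fit_log_binomial(tr)
  expect_equal(est$estimate, (30 / 100) / (24 / 100), tolerance = 1e-8)
  expect_equal(est$percent_change, 100 * (30 / 24 - 1), tolerance = 1e-6)
})

test_that("log-binomial recovery and null behaviour are calibrated", {
  pct <- vapply(1:10, function(i) {
    tr <- simulate_trials(29, 130, 0.261, log(1.15), link = "log",
                          subject_int_sd = 0.1, site_int_sd = 0.05,
                          subject_sd = 0.05, site_sd = 0.05, seed = 800 + i)
    fit_log_binomial(tr)$percent_change
  }, numeric(1))
  expect_gt(mean(pct), 12)
  expect_lt(mean(pct), 18)
  null <- simulate_trials(4, 30000, 0.26, 0, subject_sd = 0, site_sd = 0,
                          subject_int_sd = 0, site_int_sd = 0, seed = 5)
  est0 <- fit_log_binomial(null)
  expect_gt(est0$estimate, 0.95)
  expect_lt(est0$estimate, 1.05)
})

test_that("flanking model rejects stimulated rows and recovers effect signs", {
  tr <- simulate_trials(8, 40, 0.26, log(1.4), seed = 6)
  tr$stimulated <- tr$condition == "Stim"
  expect_error(fit_flanking_glme(tr), class = "memloop_model_error")
  signs <- vapply(1:20, function(i) {
    fl <- simulate_trials(18, 60, 0.26, log(1.5), seed = 900 + i)
    fl$stimulated <- FALSE   # flanking words are never stimulated
    sign(fit_flanking_glme(fl)$log_estimate)
  }, numeric(1))
  expect_gte(sum(signs > 0), 18)
})

test_that("flanking tables from the closed loop feed the model cleanly", {
  cfg <- tiny_cfg(flank_log_odds = 0.4)
  prim <- NULL
  flk <- NULL
  for (i in 1:4) {
    s <- simulate_subject(cfg, sprintf("S%02d", i), sprintf("S%02d-T1", i),
                          seed = 40 + i)
    r <- run_subject(s, cfg)
    flk <- rbind(flk, r$matched$flanking)
    prim <- rbind(prim, r$matched$primary)
  }
  expect_false(any(flk$stimulated))
  est <- fit_flanking_glme(flk)
  expect_equal(est$estimand, "flanking_OR")
  expect_true(is.finite(est$p))
})

test_that("delta-classifier analysis matches a balanced two-level oracle", {
  # balanced fixture: the mixed-model condition estimate equals the average
  # of the per-subject condition mean differences
  set.seed(44)
  tab <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(delta_prob = c(rnorm(20, 0.02 * s, 0.05), rnorm(20, 0, 0.05)),
               condition = factor(rep(c("Stim", "NoStim"), each = 20),
                                  levels = c("NoStim", "Stim")),
               subject = sprintf("S%02d", s), site = sprintf("T%02d", s))
  }))
  est <- delta_classifier_analysis(tab)
  oracle <- mean(vapply(split(tab, tab$subject), function(d)
    mean(d$delta_prob[d$condition == "Stim"]) -
      mean(d$delta_prob[d$condition == "NoStim"]), numeric(1)))
  expect_lt(abs(est$estimate - oracle), 1e-3)
})

test_that("delta-classifier estimates are null-calibrated and recover the shift", {
  est0 <- delta_classifier_analysis(
    simulate_delta_table(18, 78, delta = 0, seed = 7))
  expect_lt(abs(est0$estimate), 2 * est0$se)
  ds <- vapply(1:20, function(i)
    delta_classifier_analysis(
      simulate_delta_table(18, 78, delta = 0.01, seed = 1000 + i))$estimate,
    numeric(1))
  expect_gt(mean(ds), 0.005)
  expect_lt(mean(ds), 0.015)
  expect_error(delta_classifier_analysis(simulate_delta_table(2, 2, 0)[0, ]),
               class = "memloop_empty_error")
})

test_that("balance checks find no group differences under identical generators", {
  make_group <- function(group, seed, baseline = 0.27) {
    cfg <- tiny_cfg(baseline_recall_prob = baseline, stim_log_odds = 0,
                    flank_log_odds = 0, stim_feature_delta = 0)
    loop <- NULL
    rec <- NULL
    for (i in 1:6) {
      s <- simulate_subject(cfg, sprintf("%s%02d", substr(group, 1, 1), i),
                            sprintf("%s%02d-T1", substr(group, 1, 1), i),
                            seed = seed + i)
      r <- run_subject(s, cfg)
      le <- r$loop$events
      le$group <- group
      re <- s$record$events
      re$group <- group
      loop <- rbind(loop, le)
      rec <- rbind(rec, re)
    }
    list(loop = loop, rec = rec)
  }
  a <- make_group("lateral_temporal", 100)
  b <- make_group("non_lateral", 200)
  bc <- balance_checks(rbind(a$loop, b$loop), rbind(a$rec, b$rec))
  expect_setequal(bc$effects$estimand,
                  c("trigger_prop_group_diff", "trigger_position_x_group",
                    "record_only_recall_group_diff"))
  expect_true(all(is.finite(bc$effects$p)))
  expect_gt(min(bc$effects$p), 0.01)
  expect_lt(max(abs(bc$recall_means$recall_pct - 27)), 5)
})

test_that("null SME t-maps exceed |t| = 2 at few frequency bins", {
  cfg <- tiny_cfg(sme_effect = 0)
  hits <- 0
  bins <- 0
  for (i in 1:10) {
    fx <- feat_fixture(n_events = 200, sme = 0, seed = 2000 + i, cfg = cfg)
    tm <- sme_tmap(fx$zfeats, fx$events$recalled, pair_index = 1)
    hits <- hits + sum(abs(tm) > 2)
    bins <- bins + length(tm)
  }
  expect_lte(hits / bins, 0.10)
})
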