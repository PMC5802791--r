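test_that("target selection prioritizes lateral temporal cortex", {
  n <- 100
  y <- rep(c(TRUE, FALSE), each = 50)
  x <- matrix(rnorm(n * 16, sd = 1e-3), n, 16)
  # pair 1 (lateral temporal): tiny SME; pair 2 (other): huge SME
  hf <- function(pair) (pair - 1) * 8 + 7:8
  x[y, hf(1)] <- x[y, hf(1)] + 0.01
  x[y, hf(2)] <- x[y, hf(2)] + 5
  pf <- manual_feats(x, n_pairs = 2)
  lay <- list(pairs = data.frame(anode = c("a1", "a2"), cathode = c("c1", "c2"),
                                 region = c("temporal", "frontal"),
                                 anatomy_class = c("lateral_temporal", "other"),
                                 loading = 1))
  sel <- select_target(pf, y, lay)
  expect_equal(sel$pair_index, 1L)
  expect_equal(sel$anatomy_class, "lateral_temporal")
  expect_gt(sel$sme_t[2], sel$sme_t[1])
  # without lateral temporal pairs the global maximum wins
  lay2 <- lay
  lay2$pairs$anatomy_class <- "other"
  expect_equal(select_target(pf, y, lay2)$pair_index, 2L)
  # identical statistics: lowest index is the documented tie-break
  x[, hf(2)] <- x[, hf(1)]
  expect_equal(select_target(manual_feats(x, 2), y, lay2)$pair_index, 1L)
  expect_error(select_target(pf, rep(TRUE, n), lay),
               class = "memloop_selection_error")
})

test_that("stimulation parameter choice is the capped argmax with documented ties", {
  one <- data.frame(frequency = 100, amplitude = 1.0, delta_output = 0.003)
  expect_equal(choose_stim_params(one), one)
  pt <- data.frame(frequency = c(10, 50, 200), amplitude = c(0.5, 1.0, 1.5),
                   delta_output = c(0.001, 0.02, 0.005))
  expect_equal(choose_stim_params(pt)$frequency, 50)
  tie <- data.frame(frequency = c(200, 50, 50), amplitude = c(0.5, 1.0, 0.5),
                    delta_output = 0.01)
  pick <- choose_stim_params(tie)
  expect_equal(pick$amplitude, 0.5)
  expect_equal(pick$frequency, 50)
  expect_error(choose_stim_params(data.frame(frequency = 10, amplitude = 3,
                                             delta_output = 1), amp_cap = 1.5),
               class = "memloop_param_error")
})

test_that("symmetric decoded scores trigger about half of Stim-list words", {
  fr <- vapply(1:6, function(s) {
    res <- sym_session(s * 50)
    stim <- res$log$role == "Stim"
    mean(res$log$trigger[stim])
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("threshold boundaries disable or saturate triggering", {
  res0 <- sym_session(10, threshold = 0)
  expect_equal(sum(res0$log$trigger), 0L)
  res1 <- sym_session(10, threshold = 1)
  stim <- res1$log$role == "Stim"
  expect_true(all(res1$log$trigger[stim]))
  expect_false(any(res1$log$trigger[!stim]))
})

test_that("no trigger ever occurs off Stim lists and stats versions are monotone", {
  for (s in c(3, 17)) {
    res <- sym_session(s * 31)
    off <- res$log$role != "Stim"
    expect_false(any(res$log$trigger[off]))
    v <- res$log$stats_version[!is.na(res$log$stats_version)]
    expect_true(all(diff(v) >= 0))
    # version on list L = 1 + number of NoStim lists completed before L
    lists <- res$log[res$log$list_index >= 4 & res$log$serial_pos == 1, ]
    nostim_before <- cumsum(c(0, head(lists$role == "NoStim", -1)))
    expect_equal(lists$stats_version, 1L + nostim_before)
  }
})

test_that("NoStim decoding is a pure observation: stim hooks leave it unchanged", {
  cfg_on <- tiny_cfg(stim_log_odds = 2, stim_feature_delta = 0.3)
  cfg_off <- tiny_cfg(stim_log_odds = 0, stim_feature_delta = 0)
  lay <- make_layout(cfg_on, 9)
  sch <- make_schedule(cfg_on, 10)
  ev <- simulate_recall(sch, cfg_on, seed = 11)
  ft <- simulate_features(ev, cfg_on, 12, lay)
  set.seed(13)
  model <- structure(list(W = rnorm(ncol(ft$x), 0, 0.2), b = 0,
                          feature_names = colnames(ft$x)),
                     class = "classifier_model")
  a <- run_closed_loop_session(model, ft, ev, sch, loop_policy(), cfg_on)
  b <- run_closed_loop_session(model, ft, ev, sch, loop_policy(), cfg_off)
  ns <- a$log$role == "NoStim"
  expect_identical(a$log$prob[ns], b$log$prob[ns])
  expect_identical(a$log$matched_control[ns], b$log$matched_control[ns])
})

test_that("matched controls recount below-threshold NoStim events exactly", {
  res <- sym_session(123)
  log <- res$log
  for (li in unique(log$list_index[log$role == "NoStim"])) {
    rows <- log$list_index == li
    k <- sum(log$prob[rows] < 0.5)
    expect_equal(sum(res$events$matched_control[rows]), k)
  }
  mc <- match_controls(res$log, res$events)
  expect_setequal(which(res$events$stimulated | res$events$matched_control),
                  which(res$events$word %in% mc$primary$word))
})

test_that("stimulated words can only gain recall and intervals match the schedule", {
  cfg <- tiny_cfg(stim_log_odds = 3, stim_feature_delta = 0)
  lay <- make_layout(cfg, 21)
  sch <- make_schedule(cfg, 22)
  ev <- simulate_recall(sch, cfg, seed = 23)
  ft <- simulate_features(ev, cfg, 24, lay)
  m <- train_classifier(simulate_features(ev, cfg, 25, lay), ev$recalled)
  res <- run_closed_loop_session(m, ft, ev, sch, loop_policy(), cfg)
  flipped <- which(res$events$recalled != ev$recalled &
                     res$events$list_index >= 4)
  expect_true(all(res$events$stimulated[flipped] |
                    res$events$flanking[flipped]))
  iv <- res$log$interval_ms[res$log$trigger & res$log$serial_pos < 12]
  # word duration 1600 + jitter 750-1000 - epoch 1366 - latency 150
  expect_true(all(iv >= 1600 + 750 - 1366 - 150 - 1e-9))
  expect_true(all(iv <= 1600 + 1000 - 1366 - 150 + 1e-9))
})

test_that("hand-built two-list fixture matches manual matched/flanking enumeration", {
  ev <- data.frame(
    subject = "S01", site = "S01-T1", session = 4, session_kind = "closed_loop",
    list_index = rep(c(4L, 5L), each = 6), role = rep(c("Stim", "NoStim"), each = 6),
    serial_pos = rep(1:6, 2), word = sprintf("w%02d", 1:12),
    onset_ms = seq(0, by = 3000, length.out = 12),
    stimulated = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, rep(FALSE, 6)),
    flanking = FALSE,
    recalled = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    classifier_prob = c(0.6, 0.3, 0.7, 0.8, 0.2, 0.9,
                        0.7, 0.25, 0.55, 0.45, 0.35, 0.8),
    matched_control = FALSE, u_latent = 0.5)
  ev$matched_control <- ev$role == "NoStim" & ev$classifier_prob < 0.5
  mc <- match_controls(NULL, ev)
  expect_setequal(mc$primary$word,
                  c("w02", "w05", "w08", "w10", "w11"))
  # centres: unrecalled stim/matched words with clean neighbours on both sides
  # w02 (stim, pos 2): neighbours w01, w03 unstim -> flankers
  # w05 (stim, pos 5): neighbours w04, w06 unstim -> flankers
  # w08 (matched, pos 2): neighbour w07 ok, w09 ok -> flankers (NoStim)
  # w11 (matched, pos 5): neighbour w10 is matched -> excluded
  expect_setequal(mc$flanking$word, c("w01", "w03", "w04", "w06", "w07", "w09"))
  expect_false(any(mc$flanking$stimulated))
  expect_equal(sort(unique(as.character(mc$flanking$condition))),
               c("NoStim", "Stim"))
})

test_that("closed-loop sessions are reproducible end to end", {
  a <- sym_session(77)
  b <- sym_session(77)
  expect_identical(a$log, b$log)
  expect_identical(a$events, b$events)
})
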