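# Shared fixture builders: everything is generated in code at test time.

tiny_cfg <- function(...) {
  args <- list(n_subjects = 1L, electrodes_per_subject = 8L,
               contacts_per_probe = 4L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(study_config, args)
}

# events + z-scale features with a known SME, for decoder tests
feat_fixture <- function(n_events = 300L, sme = 0.125, seed = 1L, cfg = NULL) {
  cfg <- cfg %||% tiny_cfg(sme_effect = sme)
  lay <- make_layout(cfg, seed)
  sch <- make_schedule(cfg, seed + 1L, kind = "record_only")
  ev <- simulate_recall(sch, cfg, seed = seed + 2L)
  ev <- ev[seq_len(min(n_events, nrow(ev))), ]
  ft <- simulate_features(ev, cfg, seed + 3L, lay)
  list(cfg = cfg, layout = lay, events = ev, feats = ft,
       zfeats = normalize_features(ft, "within_session"))
}

# hand-assembled power_features with given column matrix
manual_feats <- function(x, n_pairs, freqs = morlet_freqs()) {
  stopifnot(ncol(x) == n_pairs * length(freqs))
  structure(list(
    x = x, pairs = data.frame(label = paste0("pr", seq_len(n_pairs))),
    freqs = freqs,
    feature_pair = rep(seq_len(n_pairs), each = length(freqs)),
    feature_freq = rep(seq_along(freqs), n_pairs),
    norm = NULL), class = "power_features")
}

sine_signal <- function(freq, fs = 500, dur_s = 3, amp = 1, labels = "A") {
  n <- fs * dur_s
  structure(list(
    data = matrix(rep(amp * sin(2 * pi * freq * (1:n) / fs),
                      length(labels)), length(labels), n, byrow = TRUE),
    sampling_rate = fs, labels = labels, montage = "monopolar", t0_ms = 0),
    class = "raw_signal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# helper: run one simulated closed-loop session with a fixed random model
# whose decision scores are symmetric about 0 (prob symmetric about 0.5)
sym_session <- function(seed, cfg = NULL, threshold = 0.5) {
  cfg <- cfg %||% tiny_cfg(sme_effect = 0, stim_log_odds = 0,
                           flank_log_odds = 0, stim_feature_delta = 0)
  lay <- make_layout(cfg, seed)
  sch <- make_schedule(cfg, seed + 1L)
  ev <- simulate_recall(sch, cfg, seed = seed + 2L)
  ft <- simulate_features(ev, cfg, seed + 3L, lay)
  set.seed(seed + 4L)
  model <- structure(list(W = rnorm(ncol(ft$x), 0, 0.2), b = 0,
                          feature_names = colnames(ft$x)),
                     class = "classifier_model")
  res <- run_closed_loop_session(model, ft, ev, sch,
                                 loop_policy(threshold = threshold), cfg)
  res
}
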