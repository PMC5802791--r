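#' Synthetic electrode layout for one subject
#'
#' Contacts are arranged on probes (strips/depths) of `contacts_per_probe`
#' adjacent contacts; bipolar pairs are formed between immediately adjacent
#' contacts within a probe, so a probe of k contacts yields k - 1 virtual
#' channels. Each probe is assigned a lobe-level region; pairs on a temporal
#' probe carry the `lateral_temporal` anatomy class used for stimulation
#' target prioritisation. Every pair gets an SME loading drawn from
#' `config$loading_range`: electrodes differ in how strongly they express the
#' subsequent-memory effect.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return a list of class `electrode_layout` with `contacts` (label, probe,
#'   region) and `pairs` (anode, cathode, probe, region, anatomy_class,
#'   loading).
#' @export
make_layout <- function(config, seed) {
  with_seed(seed, {
    n_probe <- config$electrodes_per_subject %/% config$contacts_per_probe
    regions <- c("temporal",
                 sample(c("frontal", "parietal", "occipital", "MTL", "temporal"),
                        n_probe - 1L, replace = TRUE))
    contacts <- data.frame(
      label = sprintf("P%02dC%02d", rep(seq_len(n_probe), each = config$contacts_per_probe),
                      rep(seq_len(config$contacts_per_probe), n_probe)),
      probe = rep(seq_len(n_probe), each = config$contacts_per_probe),
      region = rep(regions, each = config$contacts_per_probe),
      stringsAsFactors = FALSE)
    pairs <- do.call(rbind, lapply(seq_len(n_probe), function(p) {
      lab <- contacts$label[contacts$probe == p]
      data.frame(anode = lab[-length(lab)], cathode = lab[-1L],
                 probe = p, region = regions[p],
                 stringsAsFactors = FALSE)
    }))
    pairs$anatomy_class <- ifelse(pairs$region == "temporal",
                                  "lateral_temporal", "other")
    pairs$loading <- stats::runif(nrow(pairs), config$loading_range[1],
                                  config$loading_range[2])
    structure(list(contacts = contacts, pairs = pairs), class = "electrode_layout")
  })
}

#' Draw subject- and site-level random effects of the recall model
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return list with `subject_int`, `subject_slope`, `site_int`, `site_slope`
#'   (log-odds scale).
#' @export
draw_random_effects <- function(config, seed) {
  with_seed(seed, list(
    subject_int = stats::rnorm(1, 0, config$intercept_sd),
    subject_slope = stats::rnorm(1, 0, config$subject_sd),
    site_int = stats::rnorm(1, 0, config$intercept_sd / 2),
    site_slope = stats::rnorm(1, 0, config$subject_sd)))
}

#' Simulate trial-level recall for one session
#'
#' Recall is drawn from the logistic generating model
#' `logit(p) = logit(baseline) + stim_log_odds * stimulated +
#' flank_log_odds * flanking + u_int + u_slope * stimulated`,
#' where `u` collects the subject and site random effects. Each word also
#' stores its latent uniform draw, so a later change of stimulation status
#' (when the closed-loop simulator triggers) re-derives recall from the same
#' latent variable: stimulation with positive log-odds can only flip a word
#' from forgotten to recalled, never the reverse.
#'
#' @param schedule a [make_schedule()] result.
#' @param config a [study_config()].
#' @param stim_assignment logical vector over `schedule$words` rows marking
#'   words stimulated at encoding; `NULL` for none. May only be `TRUE` on
#'   Stim lists.
#' @param seed integer seed.
#' @param re random effects from [draw_random_effects()] (default all zero).
#' @param subject,site,session identifiers stamped on the rows.
#' @return a data.frame event table, one row per word-encoding event, with
#'   columns `subject`, `site`, `session`, `session_kind`, `list_index`,
#'   `role`, `serial_pos`, `word`, `onset_ms`, `stimulated`, `flanking`,
#'   `recalled`, `classifier_prob`, `matched_control`, `u_latent`.
#' @export
simulate_recall <- function(schedule, config, stim_assignment = NULL, seed = 1L,
                            re = NULL, subject = "S01", site = "S01-T1",
                            session = 1L) {
  w <- schedule$words
  n <- nrow(w)
  if (is.null(stim_assignment)) stim_assignment <- rep(FALSE, n)
  stopifnot(length(stim_assignment) == n)
  if (any(stim_assignment & w$role != "Stim"))
    stop_memloop("stim_assignment is TRUE on a non-Stim list (rows %s)",
                 paste(utils::head(which(stim_assignment & w$role != "Stim"), 3),
                       collapse = ","),
                 class = "memloop_assignment_error")
  if (is.null(re)) re <- list(subject_int = 0, subject_slope = 0,
                              site_int = 0, site_slope = 0)
  flanking <- flanking_indicator(w$list_index, w$serial_pos, stim_assignment)
  u <- with_seed(seed, stats::runif(n))
  events <- data.frame(
    subject = subject, site = site, session = session,
    session_kind = if (schedule$kind == "closed_loop") "closed_loop" else "record_only",
    list_index = w$list_index, role = w$role, serial_pos = w$serial_pos,
    word = sprintf("%s-L%02dW%02d", subject, w$list_index, w$serial_pos),
    onset_ms = w$onset_ms,
    stimulated = stim_assignment, flanking = flanking,
    u_latent = u, stringsAsFactors = FALSE)
  events$recalled <- recall_from_latent(events, config, re)
  events$classifier_prob <- NA_real_
  events$matched_control <- FALSE
  events[, c("subject", "site", "session", "session_kind", "list_index", "role",
             "serial_pos", "word", "onset_ms", "stimulated", "flanking",
             "recalled", "classifier_prob", "matched_control", "u_latent")]
}

#' Intercept of a logistic model with a Gaussian random intercept
#'
#' Solves for the intercept `a` such that the marginal (random-effect
#' averaged) response rate `E[plogis(a + sigma Z)]` equals `p`. The group
#' profiles state marginal recall rates (grand means over subjects), so the
#' generating intercept must absorb the logit-normal marginalization shift.
#'
#' @param p target marginal probability.
#' @param sigma SD of the Gaussian random intercept (log-odds scale).
#' @return the intercept on the log-odds scale.
#' @export
marginal_intercept <- function(p, sigma) {
  if (sigma == 0) return(logit(p))
  marg <- function(a) stats::integrate(function(z)
    inv_logit(a + sigma * z) * stats::dnorm(z), -8, 8)$value - p
  stats::uniroot(marg, logit(p) + c(-2, 1), tol = 1e-10)$root
}

# Recall status implied by the latent uniforms under current stim/flank status.
recall_from_latent <- function(events, config, re) {
  sigma_int <- config$intercept_sd * sqrt(1 + 0.25)  # subject + site intercepts
  eta <- marginal_intercept(config$baseline_recall_prob, sigma_int) +
    re$subject_int + re$site_int +
    (config$stim_log_odds + re$subject_slope + re$site_slope) * events$stimulated +
    config$flank_log_odds * events$flanking
  events$u_latent < inv_logit(eta)
}

# A word flanks a stimulated word if it is immediately adjacent (serial
# position +/- 1 on the same list) to one and is not itself stimulated.
flanking_indicator <- function(list_index, serial_pos, stimulated) {
  key <- paste(list_index, serial_pos)
  prev_stim <- stimulated[match(paste(list_index, serial_pos - 1L), key)]
  next_stim <- stimulated[match(paste(list_index, serial_pos + 1L), key)]
  prev_stim[is.na(prev_stim)] <- FALSE
  next_stim[is.na(next_stim)] <- FALSE
  (prev_stim | next_stim) & !stimulated
}

#' Simulate normalized spectral power features for an event table
#'
#' Each event gets one feature per (bipolar pair, analysis frequency):
#' unit-variance Gaussian noise plus the class-conditional subsequent-memory
#' shift. Later-recalled words sit `loading * sme_effect` standardized units
#' above forgotten words at the two highest frequencies and the same amount
#' below at the three lowest ([sme_profile()]), centred so the marginal
#' column mean stays near zero.
#'
#' @param events event table from [simulate_recall()].
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param layout an [make_layout()] result.
#' @return a `power_features` object: list with `x` (events x features
#'   matrix), `pairs`, `freqs`, `feature_pair`, `feature_freq`, `norm`.
#' @export
simulate_features <- function(events, config, seed, layout) {
  stopifnot(nrow(events) > 0)
  freqs <- morlet_freqs()
  prof <- sme_profile(config$sme_effect, length(freqs))
  pairs <- layout$pairs
  n <- nrow(events)
  p <- nrow(pairs) * length(freqs)
  x <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  # pair-major, frequency-minor column order (documented feature layout)
  shift <- rep(pairs$loading, each = length(freqs)) *
    rep(prof, times = nrow(pairs))
  cls <- events$recalled - mean(events$recalled)
  x <- x + outer(cls, shift)
  colnames(x) <- paste0(rep(paste0(pairs$anode, "-", pairs$cathode),
                            each = length(freqs)),
                        "@", rep(sprintf("%.1fHz", freqs), nrow(pairs)))
  structure(list(
    x = x,
    pairs = pairs,
    freqs = freqs,
    feature_pair = rep(seq_len(nrow(pairs)), each = length(freqs)),
    feature_freq = rep(seq_along(freqs), nrow(pairs)),
    norm = NULL), class = "power_features")
}

#' @export
print.power_features <- function(x, ...) {
  cat(sprintf("power_features: %d events x %d features (%d pairs x %d freqs), %s\n",
              nrow(x$x), ncol(x$x), nrow(x$pairs), length(x$freqs),
              if (is.null(x$norm)) "un-normalized" else x$norm$provenance))
  invisible(x)
}

#' Simulate raw multichannel iEEG for one session
#'
#' Monopolar channels are built as a shared reference drift plus pink (1/f^2)
#' background noise, 60 Hz line noise (a large common-mode component plus a
#' small per-channel differential component) and event-locked oscillatory
#' bursts during each word-encoding epoch. Burst amplitude at the informative
#' frequencies is modulated by the word's later recall status, carrying the
#' subsequent-memory effect into the spectral domain; bursts are injected
#' into the anode contact of each bipolar pair so they survive bipolar
#' re-referencing.
#'
#' @param events event table from [simulate_recall()] (one session).
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param layout an [make_layout()] result.
#' @param sme_gain log-amplitude modulation per unit loading separating
#'   recalled from forgotten bursts.
#' @return a `raw_signal` object: list with `data` (channels x samples),
#'   `sampling_rate`, `labels`, `montage`, `t0_ms`.
#' @export
simulate_raw <- function(events, config, seed, layout, sme_gain = 0.05) {
  stopifnot(!is.null(config$sampling_rate))
  fs <- config$sampling_rate
  freqs <- morlet_freqs()
  informative <- c(1:3, 7:8)
  sgn <- sign(sme_profile(1)[informative])
  with_seed(seed, {
    t_end_ms <- max(events$onset_ms) + 1366 + 2000
    ns <- ceiling(t_end_ms / 1000 * fs)
    labels <- layout$contacts$label
    nch <- length(labels)
    tt <- seq_len(ns) / fs

    # shared reference drift: low-pass random walk, identical on all channels
    drift <- stats::filter(stats::rnorm(ns, 0, 2), rep(1 / 200, 200),
                           sides = 1)
    drift[is.na(drift)] <- 0
    common_line <- 8 * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))

    data <- matrix(0, nch, ns)
    for (ch in seq_len(nch)) {
      data[ch, ] <- pink_noise(ns, alpha = 2) +
        as.numeric(drift) + common_line +
        stats::runif(1, 0.5, 1.5) * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
    }

    # event-locked bursts on anode contacts
    epoch_n <- floor(1.366 * fs)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(epoch_n) / (epoch_n + 1))  # Hann
    anode_idx <- match(layout$pairs$anode, labels)
    for (e in seq_len(nrow(events))) {
      i0 <- floor(events$onset_ms[e] / 1000 * fs) + 1L
      idx <- i0:(i0 + epoch_n - 1L)
      te <- tt[idx]
      for (j in seq_len(nrow(layout$pairs))) {
        ld <- layout$pairs$loading[j]
        for (k in seq_along(informative)) {
          f <- freqs[informative[k]]
          base_amp <- 3 / sqrt(f)
          lamp <- log(base_amp) +
            sme_gain * ld * sgn[k] * (events$recalled[e] - 0.5) +
            stats::rnorm(1, 0, 0.2)
          burst <- exp(lamp) * env *
            sin(2 * pi * f * te + stats::runif(1, 0, 2 * pi))
          data[anode_idx[j], idx] <- data[anode_idx[j], idx] + burst
        }
      }
    }
    structure(list(data = data, sampling_rate = fs, labels = labels,
                   montage = "monopolar", t0_ms = 0),
              class = "raw_signal")
  })
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("raw_signal [%s]: %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$montage, nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate / 60))
  invisible(x)
}

# 1/f^alpha background noise via spectral shaping, unit SD.
pink_noise <- function(n, alpha = 2) {
  nfft <- 2^ceiling(log2(n))
  f <- c(1, seq_len(nfft / 2))  # avoid DC blow-up
  mag <- c(0, f[-1]^(-alpha / 2), rev(f[2:(nfft / 2)]^(-alpha / 2)))
  ph <- stats::runif(nfft, 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

#' Generate trial-level data for effect-recovery designs
#'
#' Draws a table of analyzed words (stimulated words and matched unstimulated
#' controls) directly from the logistic generating model at a chosen design
#' scale, with crossed subject and site random intercepts and
#' condition slopes. Mirrors the rows that enter the stimulation-effect
#' mixed model, without running the full closed-loop simulation.
#'
#' @param n_sites number of unique stimulation target sites.
#' @param words_per_site analyzed words per site (split ~evenly Stim/NoStim).
#' @param baseline_prob recall probability of a control word at the
#'   random-effect mean.
#' @param stim_log_odds generating condition effect (log-odds).
#' @param subject_sd,site_sd SD of the random condition slopes.
#' @param subject_int_sd,site_int_sd SD of the random intercepts.
#' @param n_two_site_subjects how many subjects carry two sites.
#' @param group group label stamped on rows.
#' @param link `"logit"` draws from the logistic model; `"log"` draws from a
#'   log-link binomial model so `exp(stim_log_odds)` is a relative risk.
#' @param seed integer seed.
#' @return a `trial_table` data.frame: `recalled`, `condition` (Stim/NoStim),
#'   `group`, `subject`, `site`, `serial_pos`, `flanking`.
#' @export
simulate_trials <- function(n_sites, words_per_site, baseline_prob,
                            stim_log_odds, subject_sd = 0.15, site_sd = 0.15,
                            subject_int_sd = 0.30, site_int_sd = 0.15,
                            n_two_site_subjects = min(3L, n_sites %/% 4L),
                            group = "lateral_temporal", link = "logit",
                            seed = 1L) {
  stopifnot(n_sites >= 1, words_per_site >= 2)
  with_seed(seed, {
    n_subjects <- n_sites - n_two_site_subjects
    subj_of_site <- c(seq_len(n_subjects),
                      seq_len(n_two_site_subjects))  # first subjects get 2nd site
    u_int <- stats::rnorm(n_subjects, 0, subject_int_sd)
    u_slp <- stats::rnorm(n_subjects, 0, subject_sd)
    v_int <- stats::rnorm(n_sites, 0, site_int_sd)
    v_slp <- stats::rnorm(n_sites, 0, site_sd)
    rows <- lapply(seq_len(n_sites), function(t) {
      s <- subj_of_site[t]
      n_stim <- round(words_per_site / 2)
      stim <- sample(rep(c(1L, 0L), c(n_stim, words_per_site - n_stim)))
      sig_int <- sqrt(subject_int_sd^2 + site_int_sd^2)
      # baseline_prob is the marginal control-condition rate
      eta0 <- if (link == "log") log(baseline_prob) - sig_int^2 / 2
              else marginal_intercept(baseline_prob, sig_int)
      eta <- eta0 + u_int[s] + v_int[t] +
        (stim_log_odds + u_slp[s] + v_slp[t]) * stim
      p <- if (link == "log") pmin(exp(eta), 0.99) else inv_logit(eta)
      data.frame(recalled = stats::runif(words_per_site) < p,
                 condition = factor(ifelse(stim == 1L, "Stim", "NoStim"),
                                    levels = c("NoStim", "Stim")),
                 group = group,
                 subject = sprintf("S%03d", s),
                 site = sprintf("T%03d", t),
                 serial_pos = sample(1:12, words_per_site, replace = TRUE),
                 flanking = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Generate a consecutive-word classifier-output change table
#'
#' Draws per-pair changes in decoded probability (word following a stimulated
#' or matched word minus the word itself) from a Gaussian model with a fixed
#' condition effect and subject/site random intercepts and condition slopes,
#' at a chosen design scale. Mirrors the rows analyzed by
#' [delta_classifier_analysis()].
#'
#' @param n_sites number of subject-sites.
#' @param pairs_per_site consecutive-word pairs per site.
#' @param delta generating mean difference (Stim - NoStim) in decoded
#'   probability.
#' @param resid_sd residual SD of the per-pair change.
#' @param re_sd SD of the random intercepts and slopes.
#' @param seed integer seed.
#' @return data.frame with `delta_prob`, `condition`, `subject`, `site`.
#' @export
simulate_delta_table <- function(n_sites, pairs_per_site, delta,
                                 resid_sd = 0.09, re_sd = 0.01, seed = 1L) {
  with_seed(seed, {
    n_two <- min(3L, n_sites %/% 4L)
    subj_of_site <- c(seq_len(n_sites - n_two), seq_len(n_two))
    u_int <- stats::rnorm(max(subj_of_site), 0, re_sd)
    u_slp <- stats::rnorm(max(subj_of_site), 0, re_sd)
    v_int <- stats::rnorm(n_sites, 0, re_sd)
    v_slp <- stats::rnorm(n_sites, 0, re_sd)
    rows <- lapply(seq_len(n_sites), function(t) {
      s <- subj_of_site[t]
      n_stim <- round(pairs_per_site / 2)
      stim <- sample(rep(c(1L, 0L), c(n_stim, pairs_per_site - n_stim)))
      mu <- u_int[s] + v_int[t] + (delta + u_slp[s] + v_slp[t]) * stim
      data.frame(delta_prob = stats::rnorm(pairs_per_site, mu, resid_sd),
                 condition = factor(ifelse(stim == 1L, "Stim", "NoStim"),
                                    levels = c("NoStim", "Stim")),
                 subject = sprintf("S%03d", s),
                 site = sprintf("T%03d", t), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
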