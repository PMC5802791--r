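#' Study configuration for the synthetic closed-loop experiment
#'
#' A `study_config` collects every generating parameter of the synthetic
#' experiment: cohort size, montage size, sampling rate, the behavioural
#' generating model (baseline recall probability, stimulation and flanking
#' effects on the log-odds scale, random-effect spread across subjects and
#' stimulation sites) and the neural generating model (per-frequency
#' subsequent-memory effect, post-stimulation shift of decoded probability).
#'
#' Two shipped group profiles mirror the two study arms:
#' \describe{
#'   \item{`lateral_temporal`}{baseline recall 0.261, stimulation odds ratio
#'     1.18, positive flanking effect, post-stimulation decoded-probability
#'     shift +0.01.}
#'   \item{`non_lateral`}{baseline recall 0.298, stimulation odds ratio 0.87,
#'     no flanking or post-stimulation effect.}
#' }
#'
#' @param profile `"lateral_temporal"` or `"non_lateral"`; selects the shipped
#'   defaults for the behavioural parameters, each overridable below.
#' @param n_subjects number of synthetic subjects.
#' @param n_record_sessions record-only sessions per subject (default 3).
#' @param electrodes_per_subject number of implanted contacts (monopolar).
#' @param contacts_per_probe contacts on each strip/depth probe; bipolar
#'   pairs are formed between immediately adjacent contacts within a probe.
#' @param sampling_rate sampling rate in Hz (>= 500).
#' @param baseline_recall_prob probability of recall for an unstimulated,
#'   non-flanking word at the random-effect mean.
#' @param sme_effect standardized mean difference (recalled - forgotten) in
#'   z-scored log power applied at the two highest analysis frequencies and,
#'   negated, at the three lowest. Scalar.
#' @param stim_log_odds generating effect of stimulation on recall log-odds.
#' @param flank_log_odds generating effect on the log-odds of recalling a word
#'   adjacent to a stimulated word.
#' @param stim_feature_delta mean shift in decoded recall probability for the
#'   word following a stimulated word.
#' @param subject_sd SD of the random stimulation slope across subjects and
#'   across stimulation sites (log-odds scale).
#' @param intercept_sd SD of the random intercept across subjects/sites
#'   (log-odds scale).
#' @param loading_range range of the per-pair SME loading (uniform draw);
#'   pairs differ in how strongly they express the subsequent-memory effect.
#' @param seed integer master seed for the generators.
#' @return an object of class `study_config` (a validated named list).
#' @examples
#' cfg <- study_config("lateral_temporal", n_subjects = 2)
#' cfg$baseline_recall_prob
#' @export
study_config <- function(profile = c("lateral_temporal", "non_lateral"),
                         n_subjects = 25L,
                         n_record_sessions = 3L,
                         electrodes_per_subject = 16L,
                         contacts_per_probe = 4L,
                         sampling_rate = 500,
                         baseline_recall_prob = NULL,
                         sme_effect = 0.125,
                         stim_log_odds = NULL,
                         flank_log_odds = NULL,
                         stim_feature_delta = NULL,
                         subject_sd = 0.15,
                         intercept_sd = 0.30,
                         loading_range = c(0.3, 1),
                         seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    lateral_temporal = list(baseline_recall_prob = 0.261,
                            stim_log_odds = log(1.18),
                            flank_log_odds = 0.20,
                            stim_feature_delta = 0.01),
    non_lateral = list(baseline_recall_prob = 0.298,
                       stim_log_odds = log(0.87),
                       flank_log_odds = 0,
                       stim_feature_delta = 0))
  cfg <- list(
    profile = profile,
    n_subjects = as.integer(n_subjects),
    n_record_sessions = as.integer(n_record_sessions),
    electrodes_per_subject = as.integer(electrodes_per_subject),
    contacts_per_probe = as.integer(contacts_per_probe),
    sampling_rate = sampling_rate,
    baseline_recall_prob = baseline_recall_prob %||% defaults$baseline_recall_prob,
    sme_effect = sme_effect,
    stim_log_odds = stim_log_odds %||% defaults$stim_log_odds,
    flank_log_odds = flank_log_odds %||% defaults$flank_log_odds,
    stim_feature_delta = stim_feature_delta %||% defaults$stim_feature_delta,
    subject_sd = subject_sd,
    intercept_sd = intercept_sd,
    loading_range = loading_range,
    seed = as.integer(seed),
    schema_version = "1")
  validate_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_config <- function(cfg) {
  with_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop_memloop("%s must be a probability in (0, 1), got %s", what,
                   paste(p, collapse = ","), class = "memloop_config_error")
  }
  with_prob(cfg$baseline_recall_prob, "baseline_recall_prob")
  for (f in c("n_subjects", "n_record_sessions", "electrodes_per_subject",
              "contacts_per_probe")) {
    if (cfg[[f]] < 1L)
      stop_memloop("%s must be a count >= 1", f, class = "memloop_config_error")
  }
  if (cfg$sampling_rate < 500)
    stop_memloop("sampling_rate must be >= 500 Hz, got %g", cfg$sampling_rate,
                 class = "memloop_config_error")
  if (cfg$electrodes_per_subject %% cfg$contacts_per_probe != 0L)
    stop_memloop("electrodes_per_subject must be a multiple of contacts_per_probe",
                 class = "memloop_config_error")
  if (cfg$subject_sd < 0 || cfg$intercept_sd < 0)
    stop_memloop("random-effect SDs must be non-negative",
                 class = "memloop_config_error")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config [%s profile, schema v%s]\n", x$profile,
              x$schema_version))
  cat(sprintf("  %d subjects x %d record sessions, %d contacts (%d/probe), %g Hz\n",
              x$n_subjects, x$n_record_sessions, x$electrodes_per_subject,
              x$contacts_per_probe, x$sampling_rate))
  cat(sprintf("  recall: base %.3f, stim OR %.3f, flank OR %.3f, RE sd (int %.2f, slope %.2f)\n",
              x$baseline_recall_prob, exp(x$stim_log_odds), exp(x$flank_log_odds),
              x$intercept_sd, x$subject_sd))
  cat(sprintf("  neural: sme_effect %.3f, stim_feature_delta %.3f, seed %d\n",
              x$sme_effect, x$stim_feature_delta, x$seed))
  invisible(x)
}

#' Per-frequency subsequent-memory profile
#'
#' Expands the scalar SME magnitude into the per-frequency vector of
#' standardized mean differences used by the feature generator: `+d` at the
#' two highest analysis frequencies (high-frequency activity increases for
#' later-recalled words), `-d` at the three lowest (low-frequency power
#' decreases), zero in between.
#'
#' @param d scalar SME magnitude (standardized units).
#' @param n_freqs number of analysis frequencies (default 8).
#' @return numeric vector of length `n_freqs`.
#' @export
sme_profile <- function(d, n_freqs = 8L) {
  prof <- numeric(n_freqs)
  prof[seq_len(3L)] <- -d
  prof[(n_freqs - 1L):n_freqs] <- d
  prof
}

#' Read / write a study configuration as YAML
#'
#' Configurations serialize to a versioned YAML document; reading validates
#' against the schema and restores the `study_config` class.
#'
#' @param cfg a `study_config`.
#' @param path file path.
#' @return `read_config` returns a `study_config`; `write_config` its path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop_memloop("config file %s has no schema_version", path,
                 class = "memloop_config_error")
  for (f in c("n_subjects", "n_record_sessions", "electrodes_per_subject",
              "contacts_per_probe", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cfg$loading_range <- as.numeric(cfg$loading_range)
  validate_config(cfg)
  class(cfg) <- "study_config"
  cfg
}
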