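#' Closed-loop trigger policy
#'
#' @param threshold trigger when decoded recall probability falls strictly
#'   below this value (a probability of exactly `threshold` does not
#'   trigger).
#' @param stim_duration_ms stimulation train length.
#' @param decode_latency_ms processing latency between the end of the
#'   decoding epoch and stimulation onset.
#' @return a `loop_policy` list.
#' @export
loop_policy <- function(threshold = 0.5, stim_duration_ms = 500,
                        decode_latency_ms = 150) {
  if (threshold < 0 || threshold > 1)
    stop_memloop("threshold must lie in [0, 1]", class = "memloop_policy_error")
  structure(list(threshold = threshold, stim_duration_ms = stim_duration_ms,
                 decode_latency_ms = decode_latency_ms), class = "loop_policy")
}

#' Select the stimulation target pair
#'
#' Scores every virtual-electrode pair by its high-frequency subsequent-
#' memory effect: the two-sample t statistic (recalled vs forgotten) of mean
#' z-power over analysis frequencies at or above 70 Hz, from record-only
#' data. Pairs in lateral temporal cortex are prioritised: the largest-SME
#' lateral-temporal pair is chosen when any exists, otherwise the global
#' maximum. Ties break to the lowest pair index.
#'
#' @param record_feats normalized record-only `power_features`.
#' @param labels logical recall labels aligned to the feature rows.
#' @param layout the subject's `electrode_layout`.
#' @param hf_min lower bound of the high-frequency range (Hz).
#' @return a `target_selection`: list with `pair_index`, `pair`,
#'   `anatomy_class`, `sme_t` (per-pair t statistics).
#' @export
select_target <- function(record_feats, labels, layout, hf_min = 70) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop_memloop("target selection needs both recall classes",
                 class = "memloop_selection_error")
  hf_cols <- which(record_feats$freqs[record_feats$feature_freq] >= hf_min)
  np <- nrow(layout$pairs)
  sme_t <- vapply(seq_len(np), function(j) {
    cols <- intersect(hf_cols, which(record_feats$feature_pair == j))
    hf <- rowMeans(record_feats$x[, cols, drop = FALSE])
    stats::t.test(hf[labels], hf[!labels])$statistic
  }, numeric(1))
  lt <- which(layout$pairs$anatomy_class == "lateral_temporal")
  cand <- if (length(lt)) lt else seq_len(np)
  best <- cand[which.max(sme_t[cand])]  # which.max ties -> lowest index
  structure(list(pair_index = best, pair = layout$pairs[best, ],
                 anatomy_class = layout$pairs$anatomy_class[best],
                 sme_t = sme_t), class = "target_selection")
}

#' Choose stimulation frequency and amplitude from a pre-test
#'
#' Picks the (frequency, amplitude) combination that maximized the change in
#' classifier output during the stimulation pre-test, subject to the safety
#' amplitude cap. Ties break to the lower amplitude, then the lower
#' frequency.
#'
#' @param pretest data.frame with columns `frequency` (Hz), `amplitude` (mA),
#'   `delta_output` (change in classifier output).
#' @param amp_cap safety amplitude cap in mA (1.5 for depth contacts, 3.5
#'   for cortical surface contacts).
#' @return one-row data.frame (the chosen combination).
#' @export
choose_stim_params <- function(pretest, amp_cap = 1.5) {
  stopifnot(nrow(pretest) >= 1)
  ok <- pretest[pretest$amplitude <= amp_cap, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop_memloop("no pre-test row within the %.2f mA amplitude cap", amp_cap,
                 class = "memloop_param_error")
  ok <- ok[order(-ok$delta_output, ok$amplitude, ok$frequency), , drop = FALSE]
  ok[1L, ]
}

#' Run one simulated closed-loop session
#'
#' Replays a closed-loop session against a trained classifier:
#' \enumerate{
#'   \item Normalization statistics are fit on the practice and baseline
#'     (1-3) lists.
#'   \item Every event on lists 4-25 is normalized with the current
#'     statistics version and decoded.
#'   \item On Stim lists, a decoded probability strictly below the threshold
#'     triggers stimulation: the word's stimulated flag is set, its recall is
#'     re-derived from its latent draw under the generating stimulation
#'     effect, and the following word's decoded probability is shifted by the
#'     generating post-stimulation effect (`stim_feature_delta`, back-solved
#'     through the classifier to a feature-space shift).
#'   \item On NoStim lists stimulation is disabled; below-threshold events
#'     are flagged as matched controls.
#'   \item After each completed NoStim list the statistics are refit on all
#'     unstimulated-list events so far (practice, baseline and completed
#'     NoStim lists; Stim-list events never enter the normalization set).
#' }
#'
#' @param model trained `classifier_model`.
#' @param feats un-normalized `power_features` aligned row-for-row with
#'   `events`.
#' @param events event table for the session (from [simulate_recall()], no
#'   stimulation assigned yet).
#' @param schedule the session's `task_schedule`.
#' @param policy a [loop_policy()].
#' @param config the generating [study_config()] (stimulation effect hooks).
#' @param re the subject/site random effects used to generate `events`.
#' @return list with `log` (per-event decoded probability, trigger decision,
#'   statistics version, stim-to-next-word interval) and `events` (the input
#'   table with `classifier_prob`, `stimulated`, `recalled`,
#'   `matched_control` updated).
#' @export
run_closed_loop_session <- function(model, feats, events, schedule, policy,
                                    config, re = NULL) {
  stopifnot(inherits(policy, "loop_policy"),
            nrow(feats$x) == nrow(events),
            schedule$kind == "closed_loop")
  if (!is.null(model$feature_names) && !is.null(colnames(feats$x)) &&
      length(model$W) != ncol(feats$x))
    stop_memloop("model feature map does not match the montage",
                 class = "memloop_shape_error")
  if (is.null(re)) re <- list(subject_int = 0, subject_slope = 0,
                              site_int = 0, site_slope = 0)

  base_rows <- which(events$role %in% c("practice", "baseline"))
  if (!length(base_rows))
    stop_memloop("session has no baseline lists; statistics unavailable",
                 class = "memloop_sequencing_error")
  stats_cur <- feature_stats(feats, base_rows)
  norm_rows <- base_rows
  version <- 1L

  w2 <- sum(model$W^2)
  task_lists <- sort(unique(events$list_index[events$list_index >= 4L]))
  n <- nrow(events)
  log <- data.frame(event = seq_len(n), list_index = events$list_index,
                    role = events$role, serial_pos = events$serial_pos,
                    prob = NA_real_, trigger = FALSE,
                    stats_version = NA_integer_, interval_ms = NA_real_,
                    matched_control = FALSE)

  for (li in task_lists) {
    rows <- which(events$list_index == li)
    role <- events$role[rows[1]]
    prev_triggered <- FALSE
    for (r in rows) {
      xr <- (feats$x[r, ] - stats_cur$mean) / stats_cur$sd
      s <- sum(xr * model$W) + model$b
      if (prev_triggered && config$stim_feature_delta != 0 && w2 > 0) {
        # post-stimulation shift along the classifier-favorable direction,
        # back-solved so the decoded probability moves by stim_feature_delta
        p_target <- min(max(inv_logit(s) + config$stim_feature_delta, 1e-6),
                        1 - 1e-6)
        s <- logit(p_target)
      }
      prob <- inv_logit(s)
      events$classifier_prob[r] <- prob
      log$prob[r] <- prob
      log$stats_version[r] <- version
      trig <- role == "Stim" && prob < policy$threshold
      if (trig) {
        events$stimulated[r] <- TRUE
        log$trigger[r] <- TRUE
        sp <- events$serial_pos[r]
        nxt <- rows[events$serial_pos[rows] == sp + 1L]
        if (length(nxt)) {
          stim_onset <- events$onset_ms[r] + 1366 + policy$decode_latency_ms
          log$interval_ms[r] <- events$onset_ms[nxt] - stim_onset
        }
      }
      if (role == "NoStim" && prob < policy$threshold) {
        events$matched_control[r] <- TRUE
        log$matched_control[r] <- TRUE
      }
      prev_triggered <- trig
    }
    if (role == "Stim" && any(events$stimulated[rows])) {
      # re-derive flanking and recall under the realized stimulation pattern
      events$flanking <- flanking_indicator(events$list_index,
                                            events$serial_pos,
                                            events$stimulated)
      events$recalled[rows] <- recall_from_latent(events[rows, ], config, re)
    }
    if (role == "NoStim") {
      norm_rows <- c(norm_rows, rows)
      stats_cur <- feature_stats(feats, norm_rows)
      version <- version + 1L
    }
  }
  list(log = log, events = events)
}

#' Build the matched-control analysis tables
#'
#' Returns the rows that enter the stimulation-effect models: stimulated
#' words plus NoStim-list words whose decoded probability fell below the
#' trigger threshold (words that would have been stimulated on a Stim list),
#' with `condition` = list role. Also builds the flanking table: for every
#' unrecalled stimulated (or matched) word whose immediate forward and
#' reverse neighbours are both unstimulated (or, on NoStim lists, would have
#' been unstimulated), the two neighbouring words, labelled with the centre
#' word's condition. A flanking row is never itself a stimulated word.
#'
#' @param log closed-loop log from [run_closed_loop_session()].
#' @param events the updated event table from the same run.
#' @return list with `primary` and `flanking` data.frames (each an event
#'   table subset with a `condition` column).
#' @export
match_controls <- function(log, events) {
  primary <- events[events$stimulated | events$matched_control, , drop = FALSE]
  if (nrow(primary)) primary$condition <- factor(
    ifelse(primary$stimulated, "Stim", "NoStim"), levels = c("NoStim", "Stim"))

  # centre words: unrecalled and stimulated / matched
  key <- paste(events$list_index, events$serial_pos)
  below <- events$stimulated | events$matched_control
  flank_rows <- integer(0)
  centers <- which(below & !events$recalled)
  for (ctr in centers) {
    nb <- match(paste(events$list_index[ctr],
                      events$serial_pos[ctr] + c(-1L, 1L)), key)
    if (anyNA(nb)) next                       # needs both neighbours
    if (any(below[nb])) next                  # neighbours must be unstimulated
    flank_rows <- c(flank_rows, stats::setNames(nb, rep(ctr, 2)))
  }
  if (length(flank_rows)) {
    cond <- ifelse(events$stimulated[as.integer(names(flank_rows))],
                   "Stim", "NoStim")
    flanking <- events[flank_rows, , drop = FALSE]
    flanking$condition <- factor(cond, levels = c("NoStim", "Stim"))
    dup <- duplicated(paste(flanking$list_index, flanking$serial_pos))
    flanking <- flanking[!dup, , drop = FALSE]
  } else {
    flanking <- events[0, , drop = FALSE]
    flanking$condition <- factor(character(0), levels = c("NoStim", "Stim"))
  }
  list(primary = primary, flanking = flanking)
}

#' Consecutive-word classifier-output changes
#'
#' For every stimulated (or matched NoStim) word `w_i` with a following word
#' `w_{i+1}` on the same list, computes the change in decoded probability
#' `prob(w_{i+1}) - prob(w_i)`.
#'
#' @param log closed-loop log.
#' @param events updated event table.
#' @return data.frame with `delta_prob`, `condition`, `subject`, `site`,
#'   `list_index`, `serial_pos`.
#' @export
delta_classifier_table <- function(log, events) {
  key <- paste(events$list_index, events$serial_pos)
  idx <- which(events$stimulated | events$matched_control)
  nxt <- match(paste(events$list_index[idx], events$serial_pos[idx] + 1L), key)
  keep <- !is.na(nxt)
  idx <- idx[keep]
  nxt <- nxt[keep]
  data.frame(
    delta_prob = events$classifier_prob[nxt] - events$classifier_prob[idx],
    condition = factor(ifelse(events$stimulated[idx], "Stim", "NoStim"),
                       levels = c("NoStim", "Stim")),
    subject = events$subject[idx], site = events$site[idx],
    list_index = events$list_index[idx], serial_pos = events$serial_pos[idx],
    stringsAsFactors = FALSE)
}
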