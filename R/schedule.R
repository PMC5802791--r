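#' Build a task schedule for one free-recall session
#'
#' A closed-loop session consists of one practice list followed by 25 task
#' lists of 12 words each: lists 1-3 are unstimulated baseline lists used to
#' collect normalization statistics, and lists 4-25 are 11 Stim and 11 NoStim
#' lists in random interleave. A record-only session is 25 unstimulated lists
#' (no trigger policy armed). Each word stays on screen for 1,600 ms followed
#' by a 750-1,000 ms jittered inter-stimulus interval; each list ends with a
#' 20 s arithmetic distractor and a 30 s recall period.
#'
#' @param config a [study_config()].
#' @param seed integer seed controlling the Stim/NoStim interleave and the
#'   ISI jitter.
#' @param kind `"closed_loop"` or `"record_only"`.
#' @return an object of class `task_schedule`: a list with `kind`, `lists`
#'   (one row per list: `list_index`, `role`, `distractor_onset_ms`,
#'   `recall_onset_ms`) and `words` (one row per word slot: `list_index`,
#'   `role`, `serial_pos`, `onset_ms`, `duration_ms`, `isi_ms`). The practice
#'   list has `list_index = 0`.
#' @examples
#' sch <- make_schedule(study_config(n_subjects = 1), seed = 7)
#' table(sch$lists$role)
#' @export
make_schedule <- function(config, seed, kind = c("closed_loop", "record_only")) {
  kind <- match.arg(kind)
  with_seed(seed, {
    word_ms <- 1600
    distractor_ms <- 20000
    recall_ms <- 30000
    inter_list_ms <- 3000

    if (kind == "closed_loop") {
      roles <- c("practice", rep("baseline", 3L),
                 sample(rep(c("Stim", "NoStim"), each = 11L)))
      idx <- 0:25
    } else {
      roles <- rep("record", 25L)
      idx <- 1:25
    }

    t <- 2000  # session lead-in
    lists <- vector("list", length(roles))
    words <- vector("list", length(roles))
    for (k in seq_along(roles)) {
      isi <- stats::runif(12L, 750, 1000)
      onsets <- t + c(0, cumsum((word_ms + isi)[-12L]))
      words[[k]] <- data.frame(
        list_index = idx[k], role = roles[k], serial_pos = 1:12,
        onset_ms = onsets, duration_ms = word_ms, isi_ms = isi)
      t_end <- onsets[12L] + word_ms + isi[12L]
      lists[[k]] <- data.frame(
        list_index = idx[k], role = roles[k],
        distractor_onset_ms = t_end,
        recall_onset_ms = t_end + distractor_ms)
      t <- t_end + distractor_ms + recall_ms + inter_list_ms
    }
    out <- list(kind = kind,
                lists = do.call(rbind, lists),
                words = do.call(rbind, words),
                duration_ms = t)
    class(out) <- "task_schedule"
    out
  })
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("task_schedule [%s]: %d lists, %d word slots, %.1f min\n",
              x$kind, nrow(x$lists), nrow(x$words), x$duration_ms / 60000))
  print(table(x$lists$role))
  invisible(x)
}
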