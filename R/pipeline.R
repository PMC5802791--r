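#' Simulate one subject-site: record-only sessions plus a closed-loop session
#'
#' Convenience generator bundling the per-subject pieces: an electrode
#' layout, subject/site random effects, `n_record_sessions` record-only
#' sessions (events plus within-session normalized features) and one
#' closed-loop session (schedule, events with no stimulation yet, and
#' un-normalized features for the online pipeline). All child seeds derive
#' deterministically from `seed`.
#'
#' @param config a [study_config()].
#' @param subject subject identifier.
#' @param site site identifier.
#' @param seed integer seed.
#' @return list with `layout`, `re`, `record` (`events`, `feats`) and `loop`
#'   (`schedule`, `events`, `feats`).
#' @export
simulate_subject <- function(config, subject = "S01", site = "S01-T1",
                             seed = 1L) {
  sd <- derive_seeds(seed, 4L + 3L * config$n_record_sessions)
  layout <- make_layout(config, sd[1])
  re <- draw_random_effects(config, sd[2])
  rec_events <- list()
  rec_x <- list()
  for (s in seq_len(config$n_record_sessions)) {
    base <- 4L + 3L * (s - 1L)
    sch <- make_schedule(config, sd[base], kind = "record_only")
    ev <- simulate_recall(sch, config, NULL, sd[base + 1L], re = re,
                          subject = subject, site = site, session = s)
    ft <- simulate_features(ev, config, sd[base + 2L], layout)
    ft <- normalize_features(ft, "within_session")
    rec_events[[s]] <- ev
    rec_x[[s]] <- ft$x
  }
  feats <- structure(list(x = do.call(rbind, rec_x), pairs = layout$pairs,
                          freqs = morlet_freqs(),
                          feature_pair = rep(seq_len(nrow(layout$pairs)), each = 8L),
                          feature_freq = rep(1:8, nrow(layout$pairs)),
                          norm = list(provenance = "z-scored within session")),
                     class = "power_features")
  loop_sch <- make_schedule(config, sd[3], kind = "closed_loop")
  loop_ev <- simulate_recall(loop_sch, config, NULL, sd[4], re = re,
                             subject = subject, site = site,
                             session = config$n_record_sessions + 1L)
  loop_ft <- simulate_features(loop_ev, config, sd[4] + 1L, layout)
  list(layout = layout, re = re,
       record = list(events = do.call(rbind, rec_events), feats = feats),
       loop = list(schedule = loop_sch, events = loop_ev, feats = loop_ft))
}

#' Train, decode and analyze one subject-site end to end
#'
#' Runs the per-subject workflow: train the recall classifier on the
#' record-only sessions, replay the closed-loop session, and return the
#' matched-control tables together with the held-out NoStim-list AUC.
#'
#' @param subj output of [simulate_subject()].
#' @param config the same [study_config()].
#' @param policy a [loop_policy()].
#' @param C classifier penalty constant.
#' @return list with `model`, `loop` (log + updated events), `matched`,
#'   `nostim_auc`.
#' @export
run_subject <- function(subj, config, policy = loop_policy(), C = 2.4e-4) {
  model <- train_classifier(subj$record$feats, subj$record$events$recalled,
                            C = C)
  loop <- run_closed_loop_session(model, subj$loop$feats, subj$loop$events,
                                  subj$loop$schedule, policy, config,
                                  re = subj$re)
  matched <- match_controls(loop$log, loop$events)
  ns <- loop$events[loop$events$role == "NoStim", ]
  nostim_auc <- if (length(unique(ns$recalled)) == 2L)
    auc_score(ns$classifier_prob, ns$recalled) else NA_real_
  list(model = model, loop = loop, matched = matched, nostim_auc = nostim_auc)
}

PIPELINE_STAGES <- c("simulate", "preprocess", "train", "loop", "stats")

#' Run the full analysis pipeline
#'
#' Executes the staged workflow `simulate -> preprocess -> train -> loop ->
#' stats` (or a requested subset whose dependencies are already on disk)
#' against a configuration, writing every artifact under `out_dir` along
#' with a run manifest (config snapshot, derived stage seeds, file digests,
#' timestamps). Outputs are deterministic: rerunning with the same config
#' and seed reproduces bit-identical CSV and JSON artifacts.
#'
#' @param config a [study_config()] or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "preprocess", "train", "loop",
#'   "stats")`.
#' @param seed master seed; defaults to `config$seed`.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES,
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "study_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))
  need <- function(stage, f) {
    if (!file.exists(f))
      stop_memloop("stage '%s' needs missing artifact %s", stage, f,
                   class = "memloop_dependency_error")
    f
  }
  subj_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  seeds <- derive_seeds(seed, config$n_subjects)
  log_line <- function(...) message(sprintf(...))

  if ("simulate" %in% stages || "preprocess" %in% stages ||
      "train" %in% stages || "loop" %in% stages) {
    # per-subject simulation is regenerated from seeds (cheap and exact);
    # the simulate stage persists the record-only event tables
    subjects <- lapply(seq_along(subj_ids), function(i)
      simulate_subject(config, subj_ids[i], paste0(subj_ids[i], "-T1"),
                       seeds[i]))
    names(subjects) <- subj_ids
  }
  if ("simulate" %in% stages) {
    write_events(do.call(rbind, lapply(subjects, function(s) s$record$events)),
                 path("record_events.csv"))
    log_line("simulate: %d subjects, %d record events", length(subjects),
             sum(vapply(subjects, function(s) nrow(s$record$events), 0)))
  }
  if ("preprocess" %in% stages) {
    need("preprocess", path("record_events.csv"))
    stats_tab <- do.call(rbind, lapply(subj_ids, function(id) {
      st <- feature_stats(subjects[[id]]$record$feats)
      data.frame(subject = id, feature = colnames(subjects[[id]]$record$feats$x),
                 mean = st$mean, sd = st$sd, stringsAsFactors = FALSE)
    }))
    utils::write.csv(stats_tab, path("feature_stats.csv"), row.names = FALSE)
    log_line("preprocess: normalization statistics for %d subjects",
             length(subj_ids))
  }
  if ("train" %in% stages) {
    need("train", path("record_events.csv"))
    for (id in subj_ids) {
      m <- train_classifier(subjects[[id]]$record$feats,
                            subjects[[id]]$record$events$recalled)
      write_model(m, path("model_", id, ".json"))
    }
    log_line("train: %d classifiers", length(subj_ids))
  }
  if ("loop" %in% stages) {
    for (id in subj_ids) need("loop", path("model_", id, ".json"))
    all_logs <- list()
    all_events <- list()
    for (id in subj_ids) {
      m <- read_model(path("model_", id, ".json"))
      res <- run_closed_loop_session(m, subjects[[id]]$loop$feats,
                                     subjects[[id]]$loop$events,
                                     subjects[[id]]$loop$schedule,
                                     loop_policy(), config,
                                     re = subjects[[id]]$re)
      res$log$subject <- id
      all_logs[[id]] <- res$log
      all_events[[id]] <- res$events
    }
    utils::write.csv(do.call(rbind, all_logs), path("loop_log.csv"),
                     row.names = FALSE)
    write_events(do.call(rbind, all_events), path("loop_events.csv"))
    log_line("loop: %d sessions, %d triggers", length(subj_ids),
             sum(vapply(all_logs, function(l) sum(l$trigger), 0)))
  }
  if ("stats" %in% stages) {
    need("stats", path("loop_events.csv"))
    ev <- read_events(path("loop_events.csv"))
    lg <- utils::read.csv(path("loop_log.csv"))
    primary <- NULL
    deltas <- NULL
    for (id in unique(ev$subject)) {
      sub <- ev[ev$subject == id, ]
      mc <- match_controls(lg[lg$subject == id, ], sub)
      primary <- rbind(primary, mc$primary)
      deltas <- rbind(deltas, delta_classifier_table(NULL, sub))
    }
    primary$condition <- factor(ifelse(primary$stimulated, "Stim", "NoStim"),
                                levels = c("NoStim", "Stim"))
    results <- rbind(
      cbind(fit_stim_glme(primary), percent_change = NA_real_),
      fit_log_binomial(primary),
      cbind(delta_classifier_analysis(deltas), percent_change = NA_real_))
    utils::write.csv(results, path("stats_results.csv"), row.names = FALSE)
    log_line("stats: %d estimands on %d analyzed words", nrow(results),
             nrow(primary))
  }

  arts <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  arts <- setdiff(arts, path("manifest.json"))
  manifest <- list(config = unclass(config), master_seed = seed,
                   stage_seeds = seeds, stages = stages,
                   digests = as.list(tools::md5sum(arts)),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("memloop")))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
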