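# Batch orchestration: simulate -> classify -> kinematics -> imaging ->
# report over a (genotype x mouse x day) cohort, driven by a single config
# and a single seed. Each stage reads the previous stage's files, so stages
# can be re-run individually; everything is deterministic given the config.

#' Build a cohort run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed global seed; all session seeds are derived from it.
#' @param days training days to simulate (labels only; each day is an
#'   independent session).
#' @param n_trials trials per session.
#' @param cohort named list: genotype -> number of mice.
#' @param success_by_day named list: genotype -> numeric vector (same
#'   length as `days`) of rewarded-trial success probabilities; remaining
#'   probability is split among the other categories in their default
#'   proportions. Defaults to the simulator's default for every cell.
#' @param trajectory_by_day named list: genotype -> list with numeric
#'   vectors `mean` and `sd` (same length as `days`) of reach path-length
#'   target parameters in spout-distance multiples; NULL keeps the
#'   simulator defaults.
#' @param synth named list of [synth_config()] overrides applied to every
#'   session (e.g. `image_shape`, noise levels).
#' @param imaging list: `enabled`, `n_trials` (successful trials imaged per
#'   session); image shape etc. come from `synth`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, days = c(8L, 45L), n_trials = 40L,
                       cohort = list(WT = 2L, HD = 3L),
                       success_by_day = NULL,
                       trajectory_by_day = NULL,
                       synth = list(),
                       imaging = list(enabled = FALSE, n_trials = 3L)) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), days = days,
              n_trials = as.integer(n_trials), cohort = cohort,
              success_by_day = success_by_day,
              trajectory_by_day = trajectory_by_day, synth = synth,
              imaging = utils::modifyList(list(enabled = FALSE, n_trials = 3L),
                                          imaging))
  stopifnot(length(cfg$cohort) >= 1, !is.null(names(cfg$cohort)),
            cfg$n_trials %% 2 == 0)
  if (!is.null(cfg$success_by_day)) {
    for (g in names(cfg$success_by_day)) {
      stopifnot(length(cfg$success_by_day[[g]]) == length(cfg$days))
    }
  }
  if (!is.null(cfg$trajectory_by_day)) {
    for (g in names(cfg$trajectory_by_day)) {
      stopifnot(length(cfg$trajectory_by_day[[g]]$mean) == length(cfg$days),
                length(cfg$trajectory_by_day[[g]]$sd) == length(cfg$days))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synth <- raw$synth %||% list()
  if (!is.null(raw$synth$image_shape)) {
    raw$synth$image_shape <- as.integer(unlist(raw$synth$image_shape))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Rewarded-category probabilities for a given success probability: the
# non-success mass is split in the default proportions.
category_probs_for <- function(success_p) {
  base <- eval(formals(synth_config)$category_probabilities)
  resid <- base[setdiff(names(base), "success")]
  p <- c(success = success_p, resid / sum(resid) * (1 - success_p))
  p[names(base)]
}

# Enumerate cohort sessions with per-session derived seeds and synth configs.
cohort_sessions <- function(config) {
  rows <- list()
  g_idx <- 0L
  for (g in names(config$cohort)) {
    g_idx <- g_idx + 1L
    for (m in seq_len(config$cohort[[g]])) {
      for (d_i in seq_along(config$days)) {
        sc_args <- list(n_trials = config$n_trials,
                        seed = derive_seed(config$seed,
                                           g_idx * 100000L + m * 1000L + d_i,
                                           salt = 3L))
        if (!is.null(config$success_by_day[[g]])) {
          sc_args$category_probabilities <-
            category_probs_for(config$success_by_day[[g]][d_i])
        }
        if (!is.null(config$trajectory_by_day[[g]])) {
          sc_args$trajectory_length_mean <- config$trajectory_by_day[[g]]$mean[d_i]
          sc_args$trajectory_length_sd <- config$trajectory_by_day[[g]]$sd[d_i]
        }
        sc_args <- utils::modifyList(sc_args, config$synth)
        rows[[length(rows) + 1L]] <- list(
          genotype = g, mouse = sprintf("%s_m%d", g, m),
          day = config$days[d_i],
          dir = file.path(config$out_dir, "raw",
                          sprintf("%s_m%d_day%03d", g, m, config$days[d_i])),
          synth = do.call(synth_config, sc_args)
        )
      }
    }
  }
  rows
}

#' Pipeline stage: simulate the cohort's raw sessions
#'
#' Writes, per session, the event log, the ground-truth JSON, and one pose
#' CSV per trial under `out_dir/raw/<genotype>_m<mouse>_day<day>/`.
#' Widefield movies are not written to disk; the imaging stage regenerates
#' them deterministically from the stored per-session seed.
#'
#' @param config a `run_config`.
#' @return invisibly, the session index data.frame (also written as
#'   `sessions.csv`).
#' @export
pipeline_simulate <- function(config) {
  sess <- cohort_sessions(config)
  idx <- list()
  for (s in sess) {
    dir.create(s$dir, recursive = TRUE, showWarnings = FALSE)
    session <- generate_session(s$synth)
    write_event_log(session$log, file.path(s$dir, "events.csv"))
    write_ground_truth(session$ground_truth,
                       file.path(s$dir, "ground_truth.json"))
    for (i in seq_len(nrow(session$log))) {
      write_pose_csv(session$tracks[[i]],
                     file.path(s$dir, sprintf("pose_trial%03d.csv", i)))
    }
    idx[[length(idx) + 1L]] <- data.frame(
      genotype = s$genotype, mouse = s$mouse, day = s$day, dir = s$dir,
      seed = s$synth$seed)
  }
  idx <- do.call(rbind, idx)
  utils::write.csv(idx, file.path(config$out_dir, "sessions.csv"),
                   row.names = FALSE)
  invisible(idx)
}

read_session_index <- function(config) {
  path <- file.path(config$out_dir, "sessions.csv")
  if (!file.exists(path)) stop("sessions.csv not found; run pipeline_simulate first")
  utils::read.csv(path)
}

#' Pipeline stage: classify every trial from pose
#'
#' Rebuilds each trial's timeline from the event log, truncates tracks to
#' the 10-s analysis window, resolves the spout geometry per trial and
#' applies the rule cascade. Writes `trial_records.csv`.
#'
#' @param config a `run_config`.
#' @param params a [classifier_params()].
#' @return invisibly, the trial-record data.frame.
#' @export
pipeline_classify <- function(config, params = classifier_params()) {
  idx <- read_session_index(config)
  recs <- list()
  for (r in seq_len(nrow(idx))) {
    log <- read_event_log(file.path(idx$dir[r], "events.csv"))
    for (i in seq_len(nrow(log))) {
      tr <- read_pose_csv(file.path(idx$dir[r],
                                    sprintf("pose_trial%03d.csv", i)))
      timeline <- build_timeline(log$type[i], log$touch_time_s[i])
      geom <- spout_distance(tr)
      category <- classify_trial(tr, log$type[i], timeline, geom, params)
      early <- if (identical(as.character(category), "success") &&
                   log$type[i] == "rewarded") {
        detect_early_reach(tr, timeline, geom, params)
      } else NA
      recs[[length(recs) + 1L]] <- data.frame(
        genotype = idx$genotype[r], mouse = idx$mouse[r], day = idx$day[r],
        trial_index = i, type = log$type[i],
        category = as.character(category), early_reach = early,
        reach_onset_s = attr(category, "reach_onset_s") %||% NA_real_)
    }
  }
  recs <- do.call(rbind, recs)
  utils::write.csv(recs, file.path(config$out_dir, "trial_records.csv"),
                   row.names = FALSE)
  invisible(recs)
}

#' Pipeline stage: reach kinematics of successful trials
#'
#' Computes the reward-to-+1.1-s left-paw path length (in spout-distance
#' multiples) for every trial classified successful, plus the binned
#' distance histogram per mouse and day. Writes `distances.csv` and
#' `histograms.csv`.
#'
#' @param config a `run_config`.
#' @return invisibly, the per-trial distance data.frame.
#' @export
pipeline_kinematics <- function(config) {
  idx <- read_session_index(config)
  recs <- utils::read.csv(file.path(config$out_dir, "trial_records.csv"))
  out <- list()
  for (r in seq_len(nrow(idx))) {
    sel <- recs[recs$mouse == idx$mouse[r] & recs$day == idx$day[r] &
                  recs$category == "success", , drop = FALSE]
    if (!nrow(sel)) next
    log <- read_event_log(file.path(idx$dir[r], "events.csv"))
    for (i in sel$trial_index) {
      tr <- read_pose_csv(file.path(idx$dir[r],
                                    sprintf("pose_trial%03d.csv", i)))
      timeline <- build_timeline(log$type[i], log$touch_time_s[i])
      geom <- spout_distance(tr)
      len <- path_length(tr, timeline, geom)
      out[[length(out) + 1L]] <- data.frame(
        genotype = idx$genotype[r], mouse = idx$mouse[r], day = idx$day[r],
        trial_index = i, length = as.numeric(len),
        flagged = isTRUE(attr(len, "flagged")))
    }
  }
  out <- do.call(rbind, out)
  utils::write.csv(out, file.path(config$out_dir, "distances.csv"),
                   row.names = FALSE)
  hk <- interaction(out$mouse[!out$flagged], out$day[!out$flagged], drop = TRUE)
  hists <- do.call(rbind, lapply(
    split(out[!out$flagged, , drop = FALSE], hk), function(d) {
      h <- bin_distances(d$length)
      if (!nrow(h)) return(NULL)
      cbind(genotype = d$genotype[1L], mouse = d$mouse[1L], day = d$day[1L], h)
    }))
  utils::write.csv(hists, file.path(config$out_dir, "histograms.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Pipeline stage: widefield imaging metrics
#'
#' Regenerates each session deterministically, simulates the strobed movie
#' for the first `imaging$n_trials` successful trials, runs the full
#' processing chain (demultiplex, per-channel dF/F, reflectance
#' subtraction, atlas-ROI traces) and measures peak amplitudes for every
#' ROI with a configured transient, plus the activated area of the first
#' imaged trial. Writes `roi_peaks.csv` and `area_activated.csv`.
#'
#' @param config a `run_config` with `imaging$enabled = TRUE`.
#' @return invisibly, the peak data.frame.
#' @export
pipeline_imaging <- function(config) {
  if (!isTRUE(config$imaging$enabled)) {
    message("imaging disabled in config; skipping")
    return(invisible(NULL))
  }
  sess <- cohort_sessions(config)
  recs <- utils::read.csv(file.path(config$out_dir, "trial_records.csv"))
  peaks <- list()
  areas <- list()
  for (s in sess) {
    session <- generate_session(s$synth)
    sel <- recs[recs$mouse == s$mouse & recs$day == s$day &
                  recs$category == "success", , drop = FALSE]
    take <- utils::head(sel$trial_index, config$imaging$n_trials)
    for (i in take) {
      stack <- simulate_widefield(session, trials = i)[[1L]]
      timeline <- session$timelines[[i]]
      ch <- demultiplex(stack)
      bw <- c(0, timeline$reward_s)
      dff <- hemodynamic_correct(compute_dff(ch$fluorescence, bw),
                                 compute_dff(ch$reflectance, bw))
      for (roi in names(s$synth$roi_peak_amplitudes)) {
        trace <- truncate_trial(extract_trace(dff, session$roi_map, roi),
                                rate = dff$rate)
        pk <- peak_amplitude(trace, timeline, "success")
        peaks[[length(peaks) + 1L]] <- data.frame(
          genotype = s$genotype, mouse = s$mouse, day = s$day,
          trial_index = i, roi = roi, amplitude = pk$amplitude,
          peak_time_s = pk$peak_time_s, baseline_sd = pk$baseline_sd,
          true_amplitude = unname(s$synth$roi_peak_amplitudes[[roi]]))
      }
      if (i == take[1L]) {
        dff10 <- dff
        dff10$values <- truncate_trial(dff10$values, rate = dff10$rate)
        aa <- area_activated(dff10, timeline, "success", session$roi_map)
        areas[[length(areas) + 1L]] <- data.frame(
          genotype = s$genotype, mouse = s$mouse, day = s$day,
          trial_index = i, n_pixels = aa$n_pixels, area_mm2 = aa$area_mm2,
          n_eligible = aa$n_eligible)
      }
    }
  }
  peaks <- do.call(rbind, peaks)
  utils::write.csv(peaks, file.path(config$out_dir, "roi_peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, areas),
                   file.path(config$out_dir, "area_activated.csv"),
                   row.names = FALSE)
  invisible(peaks)
}

#' Pipeline stage: genotype x day summary tables
#'
#' Aggregates the stage outputs into one row per (genotype, day, mouse) —
#' category fractions, early-reach fraction, per-mouse trajectory mean/SD,
#' per-ROI mean peak amplitude — plus genotype contrast tables (means of
#' per-mouse values with SEM) and a reproducibility manifest. Writes
#' `summary_table.csv`, `contrast_*.csv` and `manifest.json`.
#'
#' @param config a `run_config`.
#' @return invisibly, the summary data.frame.
#' @export
pipeline_report <- function(config) {
  recs <- utils::read.csv(file.path(config$out_dir, "trial_records.csv"))
  key <- interaction(recs$mouse, recs$day, drop = TRUE)
  summ <- do.call(rbind, lapply(split(recs, key), function(d) {
    perf <- summarize_performance(d)
    cbind(genotype = d$genotype[1L], mouse = d$mouse[1L], perf)
  }))
  dist_path <- file.path(config$out_dir, "distances.csv")
  if (file.exists(dist_path)) {
    dists <- utils::read.csv(dist_path)
    dists <- dists[!dists$flagged, , drop = FALSE]
    tk <- interaction(dists$mouse, dists$day, drop = TRUE)
    tstats <- do.call(rbind, lapply(split(dists, tk), function(d) {
      data.frame(mouse = d$mouse[1L], day = d$day[1L],
                 traj_mean = mean(d$length),
                 traj_sd = if (nrow(d) > 1L) stats::sd(d$length) else NA_real_)
    }))
    summ <- merge(summ, tstats, by = c("mouse", "day"), all.x = TRUE)
  }
  peaks_path <- file.path(config$out_dir, "roi_peaks.csv")
  if (file.exists(peaks_path)) {
    pk <- utils::read.csv(peaks_path)
    pk_wide <- do.call(rbind, lapply(
      split(pk, interaction(pk$mouse, pk$day, drop = TRUE)), function(d) {
        m <- tapply(d$amplitude, d$roi, mean)
        out <- data.frame(mouse = d$mouse[1L], day = d$day[1L])
        out[paste0("peak_", names(m))] <- as.list(m)
        out
      }))
    summ <- merge(summ, pk_wide, by = c("mouse", "day"), all.x = TRUE)
  }
  summ <- summ[order(summ$genotype, summ$day, summ$mouse), , drop = FALSE]
  utils::write.csv(summ, file.path(config$out_dir, "summary_table.csv"),
                   row.names = FALSE)
  for (measure in intersect(c("success", "unrewarded_reach", "early_reach",
                              "traj_mean", "traj_sd"), names(summ))) {
    ct <- genotype_compare(summ, measure, by = "day")
    utils::write.csv(ct, file.path(config$out_dir,
                                   sprintf("contrast_%s.csv", measure)),
                     row.names = FALSE)
  }
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    package = "mesoreach",
    version = as.character(utils::packageVersion("mesoreach")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_sessions = length(cohort_sessions(config)),
    n_trials_per_session = config$n_trials
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summ)
}

#' Run the full pipeline
#'
#' simulate -> classify -> kinematics -> imaging (if enabled) -> report.
#' Deterministic given the config: re-running writes byte-identical tables.
#'
#' @param config a `run_config`.
#' @param params a [classifier_params()].
#' @return invisibly, the summary table.
#' @export
run_pipeline <- function(config, params = classifier_params()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  stage("simulate", pipeline_simulate(config))
  stage("classify", pipeline_classify(config, params))
  stage("kinematics", pipeline_kinematics(config))
  if (isTRUE(config$imaging$enabled)) stage("imaging", pipeline_imaging(config))
  invisible(stage("report", pipeline_report(config)))
}
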