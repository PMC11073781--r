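#' Pipeline configuration
#'
#' Nested configuration for the full chain: simulate (or load) a cohort,
#' filter/standardize/segment/label, train the BiLSTM detector on all but one
#' subject, detect on the held-out subject, refine detections, compute and
#' enhance the fetal heart rate, and evaluate against ground truth.
#'
#' A single global `seed` fans out to per-stage seeds as `seed + stage index`
#' (simulate = +1, train = +3), so each stage is independently reproducible.
#'
#' @param n_subjects cohort size when simulating.
#' @param sim a [sim_config()].
#' @param cohort_dir optional directory of an existing cohort written by
#'   [write_cohort()]; when given, simulation is skipped.
#' @param frame_ms frame duration in milliseconds.
#' @param detector a [detector_config()]; the default here is a reduced
#'   `c(64, 32, 16)` architecture sized for CPU-scale experiments.
#' @param schedule a [train_schedule()].
#' @param holdout_subject subject id to hold out; default the last subject.
#' @param fecgpp_args list of [fecgpp()] thresholds.
#' @param fhre_args list with `thresholds`, `alpha`, `window_s`.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 6, sim = sim_config(), cohort_dir = NULL,
                            frame_ms = 65,
                            detector = detector_config(hidden_sizes = c(64, 32, 16)),
                            schedule = train_schedule(epochs = 15),
                            holdout_subject = NULL,
                            fecgpp_args = list(rr_min_ms = 250, gap_factor = 1.8,
                                               promote_floor = 0.2),
                            fhre_args = list(thresholds = c(8, 20), alpha = 0.3,
                                             window_s = 10),
                            seed = 1) {
  structure(list(n_subjects = n_subjects, sim = sim, cohort_dir = cohort_dir,
                 frame_ms = frame_ms, detector = detector, schedule = schedule,
                 holdout_subject = holdout_subject, fecgpp_args = fecgpp_args,
                 fhre_args = fhre_args, seed = seed),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "fetalpeaks_stage_error", parent = e)
  })
}

#' Run the end-to-end detection pipeline
#'
#' Executes simulate -> filter -> standardize -> segment/label -> train ->
#' detect -> FECGPP -> heart rate -> FHRE -> evaluate, holding one subject
#' out of training entirely. Artifacts (cohort files, detections, peaks, HR
#' series, evaluation report, manifest with checksums) are written when
#' `out_dir` is given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return a list: `fit`, `detections`, `events_raw`, `events`, `hr`,
#'   `hr_truth`, `report` (named list of evaluation numbers), `holdout`,
#'   `cohort`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("stage 1/7: cohort")
  cohort <- run_stage("simulate", {
    if (is.null(config$cohort_dir)) {
      generate_cohort(config$n_subjects, config$sim, seed = seed + 1)
    } else {
      load_cohort(config$cohort_dir)
    }
  })

  holdout <- config$holdout_subject %||% tail(cohort$subject, 1)
  assert_that(holdout %in% cohort$subject, "holdout subject not present in cohort")
  notch <- config$sim$powerline_hz

  say("stage 2/7: preprocessing (filter, standardize, frame, label)")
  prep <- run_stage("preprocess", {
    filtered <- purrr::map(cohort$record, bandpass_notch, notch = notch)
    train_mask <- cohort$subject != holdout
    std <- fit_standardizer(filtered[train_mask])
    sets <- purrr::map2(filtered, cohort$truth, function(rec, tr) {
      frpl_label(segment_frames(apply_standardizer(std, rec), config$frame_ms),
                 tr$fetal_peaks)
    })
    list(std = std, sets = sets, train_mask = train_mask)
  })
  train_frames <- bind_frame_sets(prep$sets[prep$train_mask])
  test_frames <- prep$sets[[which(cohort$subject == holdout)]]

  say("stage 3/7: training (%d frames)", dim(train_frames$x)[1])
  sched <- config$schedule
  sched$seed <- seed + 3
  fit <- run_stage("train", {
    fit_detector(train_frames, config$detector, sched, standardizer = prep$std)
  })

  say("stage 4/7: detection on held-out subject %s", holdout)
  detections <- run_stage("detect", predict(fit, test_frames))

  say("stage 5/7: FECGPP refinement")
  events_raw <- run_stage("postprocess", merge_runs(detections, test_frames$frame_len))
  events <- run_stage("postprocess", {
    do.call(fecgpp, c(list(events = events_raw, detections = detections,
                           fs = test_frames$fs, frame_len = test_frames$frame_len),
                      config$fecgpp_args))
  })

  say("stage 6/7: heart rate + FHRE")
  truth <- cohort$truth[[which(cohort$subject == holdout)]]
  hr_out <- run_stage("heartrate", {
    win <- config$fhre_args$window_s
    dur <- config$sim$duration
    beat_times <- fill_rr_dropouts(events$sample_idx, test_frames$fs)
    hr <- windowed_hr(beat_times, test_frames$fs, win, duration_s = dur)
    hr <- fhre(hr, thresholds = config$fhre_args$thresholds,
               alpha = config$fhre_args$alpha)
    hr_truth <- windowed_hr(truth$fetal_peaks, test_frames$fs, win, duration_s = dur)
    list(hr = hr, hr_truth = hr_truth)
  })

  say("stage 7/7: evaluation")
  report <- run_stage("evaluate", {
    y <- test_frames$info$label
    before <- confusion_metrics(y, detections$pred)
    after <- confusion_metrics(y, events_to_frame_labels(events, length(y)))
    auc <- roc_auc(y, detections$p1)$auc
    beat <- match_peaks(events$sample_idx, truth$fetal_peaks, test_frames$fs)
    ok <- !is.na(hr_out$hr_truth$hr_bpm)
    mae <- mean(abs(hr_out$hr$hr_fhre_bpm[ok] - hr_out$hr_truth$hr_bpm[ok]))
    list(holdout = holdout,
         frames_before = before, frames_after = after,
         auc = auc, beat_level = beat, hr_mae_bpm = mae)
  })

  result <- list(fit = fit, detections = detections, events_raw = events_raw,
                 events = events, hr = hr_out$hr, hr_truth = hr_out$hr_truth,
                 report = report, holdout = holdout, cohort = cohort)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  result
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing per-subject record CSVs and
#'   `*_fetal_peaks.txt` annotation files.
#' @return a cohort tibble with `subject`, `record` and `truth` list-columns.
#' @export
load_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  assert_that(file.exists(manifest_path), paste0("no manifest.json in ", dir))
  manifest <- jsonlite::read_json(manifest_path)
  rows <- purrr::map(manifest$files, function(f) {
    rec <- read_record_csv(file.path(dir, f$record))
    attr(rec, "subject") <- f$subject
    peaks <- read_peak_annotations(file.path(dir, f$annotations))
    tibble(subject = f$subject, record = list(rec),
           truth = list(list(fetal_peaks = peaks)))
  })
  bind_rows(rows)
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$detections, file.path(out_dir, "detections.csv"))
  fs <- record_fs(result$cohort$record[[1]])
  events <- result$events |>
    mutate(time_s = (sample_idx - 1) / fs)
  readr::write_csv(events, file.path(out_dir, "peaks.csv"))
  hr_both <- result$hr |>
    dplyr::rename(hr_raw_bpm = hr_bpm) |>
    mutate(hr_truth_bpm = result$hr_truth$hr_bpm)
  readr::write_csv(hr_both, file.path(out_dir, "hr.csv"))
  report <- result$report
  report$frames_before <- as.list(report$frames_before)
  report$frames_after <- as.list(report$frames_after)
  report$beat_level <- as.list(report$beat_level)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg <- strip(config)
  manifest <- list(
    seed = config$seed,
    stage_seeds = list(simulate = config$seed + 1, train = config$seed + 3),
    config = cfg,
    checksums = as.list(tools::md5sum(list.files(out_dir, pattern = "\\.csv$",
                                                 full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Detector pipeline factory for the cross-validation harnesses
#'
#' Returns a `function(train_frames, test_frames)` that standardizes both
#' frame sets with the training frames' per-channel statistics, fits the
#' detector and returns hard labels for the test frames — the shape
#' [kfold_cv()] and [loso_cv()] expect.
#'
#' @param cfg a [detector_config()].
#' @param schedule a [train_schedule()].
#' @return a pipeline function.
#' @export
detector_pipeline <- function(cfg = detector_config(hidden_sizes = c(32, 16, 8)),
                              schedule = train_schedule(epochs = 8)) {
  function(train_frames, test_frames) {
    mu <- apply(train_frames$x, 3, mean)
    sigma <- apply(train_frames$x, 3, sd)
    scale_fs <- function(fs_obj) {
      for (ch in seq_along(mu)) {
        fs_obj$x[, , ch] <- (fs_obj$x[, , ch] - mu[ch]) / sigma[ch]
      }
      fs_obj
    }
    fit <- fit_detector(scale_fs(train_frames), cfg, schedule)
    predict(fit, scale_fs(test_frames))$pred
  }
}
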