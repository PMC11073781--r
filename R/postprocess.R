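#' Collapse frame-level detections into candidate peak events
#'
#' Each maximal run of consecutive Class-1 frames becomes one candidate event
#' placed at the center sample of the run's maximum-posterior frame, with that
#' posterior as the event confidence.
#'
#' @param detections a tibble from [predict.bilstm_fit()] (`frame`, `start`,
#'   `p1`, `pred`).
#' @param frame_len frame length in samples.
#' @return an events tibble: `sample_idx`, `confidence`, `frame`.
#' @export
merge_runs <- function(detections, frame_len) {
  det <- arrange(detections, frame)
  pos <- det$pred == 1
  if (!any(pos)) {
    return(tibble(sample_idx = integer(0), confidence = numeric(0), frame = integer(0)))
  }
  r <- rle(pos)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  det$run <- run_id
  det |>
    filter(pred == 1) |>
    group_by(.data$run) |>
    summarise(frame = frame[which.max(p1)],
              start = start[which.max(p1)],
              confidence = max(p1), .groups = "drop") |>
    mutate(sample_idx = as.integer(start + frame_len %/% 2)) |>
    select(sample_idx, confidence, frame) |>
    arrange(sample_idx)
}

#' Refine candidate events into a physiological beat sequence (FECGPP)
#'
#' Two passes reduce false detections and recover missed beats:
#' \enumerate{
#'   \item Refractory: while two events are closer than `rr_min_ms`, the
#'     lower-confidence one is deleted (no fetal heart beats above the
#'     equivalent 240 bpm ceiling at the 250 ms default).
#'   \item Gap fill: where an inter-event interval exceeds `gap_factor` times
#'     the running median R-R (window of 9 intervals), the highest-posterior
#'     unused frame inside the gap is promoted to an event if its posterior is
#'     at least `promote_floor` and its center keeps `rr_min_ms` clearance to
#'     both gap endpoints. The pass repeats until no insertion is possible, so
#'     the whole refinement is idempotent.
#' }
#'
#' @param events candidate events from [merge_runs()].
#' @param detections the full frame-level detection tibble (posteriors are
#'   needed to promote frames inside gaps).
#' @param fs sampling rate in Hz.
#' @param frame_len frame length in samples.
#' @param rr_min_ms refractory period in milliseconds.
#' @param gap_factor multiple of the running median R-R that flags a gap.
#' @param promote_floor minimum posterior for gap-fill promotion.
#' @return the refined events tibble (same columns as input).
#' @export
fecgpp <- function(events, detections, fs, frame_len,
                   rr_min_ms = 250, gap_factor = 1.8, promote_floor = 0.2) {
  if (nrow(events) < 2) {
    inform("fewer than 2 candidate events; returning them unchanged")
    return(events)
  }
  rr_min <- rr_min_ms / 1000 * fs

  # (i) refractory pass
  ev <- arrange(events, sample_idx)
  repeat {
    gaps <- diff(ev$sample_idx)
    bad <- which(gaps < rr_min)
    if (length(bad) == 0) break
    j <- bad[1]
    drop <- if (ev$confidence[j] < ev$confidence[j + 1]) j else j + 1
    ev <- ev[-drop, ]
    if (nrow(ev) < 2) break
  }

  # (ii) gap-fill pass, repeated to a fixed point
  centers <- as.integer(detections$start + frame_len %/% 2)
  repeat {
    if (nrow(ev) < 3) break
    rr <- diff(ev$sample_idx)
    med <- running_median(rr, 9)
    long <- which(rr > gap_factor * med)
    inserted <- FALSE
    for (j in long) {
      lo <- ev$sample_idx[j]; hi <- ev$sample_idx[j + 1]
      ok <- centers > lo & centers < hi &
        centers - lo >= rr_min & hi - centers >= rr_min &
        !(centers %in% ev$sample_idx) &
        detections$p1 >= promote_floor
      if (!any(ok)) next
      k <- which(ok)[which.max(detections$p1[ok])]
      ev <- bind_rows(ev, tibble(sample_idx = centers[k],
                                 confidence = detections$p1[k],
                                 frame = detections$frame[k])) |>
        arrange(sample_idx)
      inserted <- TRUE
      break # interval structure changed; recompute medians
    }
    if (!inserted) break
  }
  ev
}

# Running median of x over a centered window of `width` entries (shrunk at
# the edges).
running_median <- function(x, width = 9) {
  half <- width %/% 2
  vapply(seq_along(x), function(i) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    median(x[lo:hi])
  }, numeric(1))
}

#' Map refined events back onto frame labels
#'
#' A frame is predicted Class 1 after refinement iff it hosts an event; this
#' is how frame-level metrics before and after FECGPP are compared.
#'
#' @param events an events tibble.
#' @param n_frames total number of frames.
#' @return integer 0/1 vector of length `n_frames`.
#' @export
events_to_frame_labels <- function(events, n_frames) {
  labels <- integer(n_frames)
  labels[events$frame[events$frame <= n_frames]] <- 1L
  labels
}
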