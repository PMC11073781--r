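#' Acquisition-style filtering: bandpass plus mains notch
#'
#' Zero-phase (forward-backward) filtering per channel emulating the
#' acquisition chain: a 0.05-100 Hz passband realized as a cascade of a
#' second-order Butterworth high-pass and a fourth-order Butterworth low-pass,
#' followed by a second-order Butterworth band-stop (+/- 2 Hz) at the mains
#' frequency.
#'
#' @param record an abdominal record tibble.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param notch mains frequency to reject (50 or 60 Hz), `< fs/2`.
#' @return the filtered record, same shape and attributes.
#' @export
bandpass_notch <- function(record, low = 0.05, high = 100, notch = 50) {
  fs <- record_fs(record)
  assert_that(low > 0 && low < high && high < fs / 2,
              "band edges must satisfy 0 < low < high < fs/2")
  assert_that(notch < fs / 2, "notch frequency must be below fs/2")
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  bs <- signal::butter(2, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
  mat <- record_matrix(record)
  for (j in seq_len(ncol(mat))) {
    x <- signal::filtfilt(hp, mat[, j])
    x <- signal::filtfilt(lp, x)
    mat[, j] <- signal::filtfilt(bs, x)
  }
  chans <- grep("^ch[0-9]+$", names(record), value = TRUE)
  record[chans] <- as_tibble(mat)
  record
}

#' Per-channel z-score standardization
#'
#' `fit_standardizer()` computes per-channel means and standard deviations
#' from training records only; `apply_standardizer()` applies the frozen
#' parameters (`z = (X - mu) / sigma`) to any record, training or test.
#'
#' @param records a list of abdominal record tibbles (training pool).
#' @return `fit_standardizer()`: a `standardizer` object with fields `mu` and
#'   `sigma` (one value per channel).
#' @export
fit_standardizer <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  assert_that(length(records) > 0, "training set must be non-empty")
  pooled <- do.call(rbind, lapply(records, record_matrix))
  mu <- colMeans(pooled)
  sigma <- apply(pooled, 2, sd)
  degenerate <- which(sigma <= 0 | !is.finite(sigma))
  if (length(degenerate) > 0) {
    abort(paste0("constant channel(s) with zero standard deviation: ",
                 paste(channel_names(ncol(pooled))[degenerate], collapse = ", ")),
          class = "fetalpeaks_degenerate_channel_error")
  }
  structure(list(mu = mu, sigma = sigma), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a fitted `standardizer`.
#' @param record a record tibble to standardize.
#' @export
apply_standardizer <- function(params, record) {
  mat <- record_matrix(record)
  assert_that(ncol(mat) == length(params$mu), "channel count differs from fitted standardizer")
  mat <- sweep(sweep(mat, 2, params$mu, "-"), 2, params$sigma, "/")
  chans <- grep("^ch[0-9]+$", names(record), value = TRUE)
  record[chans] <- as_tibble(mat)
  record
}

#' Segment a record into contiguous fixed-duration frames
#'
#' Frames are non-overlapping, contiguous, `round(fs * frame_ms / 1000)`
#' samples long (65 at 1 kHz for the default 65 ms). A trailing remainder
#' shorter than one frame is dropped.
#'
#' @param record an abdominal record tibble.
#' @param frame_ms frame duration in milliseconds.
#' @return a `frame_set`: list with `x` (array n_frames x frame_len x
#'   n_channels), `info` (tibble: `frame`, `start` 1-based start sample,
#'   `subject`), `fs`, `frame_len`.
#' @export
segment_frames <- function(record, frame_ms = 65) {
  fs <- record_fs(record)
  frame_len <- as.integer(round(fs * frame_ms / 1000))
  mat <- record_matrix(record)
  n <- nrow(mat)
  if (n < frame_len) {
    abort(sprintf("record (%d samples) is shorter than one frame (%d samples)", n, frame_len),
          class = "fetalpeaks_empty_framing_error")
  }
  n_frames <- n %/% frame_len
  used <- mat[seq_len(n_frames * frame_len), , drop = FALSE]
  # [frame, within-frame sample, channel]
  x <- aperm(array(used, dim = c(frame_len, n_frames, ncol(mat))), c(2, 1, 3))
  info <- tibble(
    frame = seq_len(n_frames),
    start = (seq_len(n_frames) - 1L) * frame_len + 1L,
    subject = attr(record, "subject", exact = TRUE) %||% NA_character_
  )
  structure(list(x = x, info = info, fs = fs, frame_len = frame_len),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  lab <- if ("label" %in% names(x$info)) {
    sprintf(", %d Class-1 (%.1f%%)", sum(x$info$label),
            100 * mean(x$info$label))
  } else ""
  cat(sprintf("<frame_set> %d frames of %d samples x %d channels @ %g Hz%s\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$fs, lab))
  invisible(x)
}

#' Combine frame sets from several subjects
#'
#' @param ... `frame_set` objects with identical frame shape and fs.
#' @return a single `frame_set`.
#' @export
bind_frame_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "frame_set")) {
    sets <- sets[[1]]
  }
  dims <- vapply(sets, function(s) dim(s$x)[2:3], numeric(2))
  assert_that(all(dims == dims[, 1]), "frame sets have differing frame shapes")
  x <- do.call(abind_first, lapply(sets, function(s) s$x))
  info <- bind_rows(lapply(sets, function(s) s$info))
  structure(list(x = x, info = info, fs = sets[[1]]$fs, frame_len = sets[[1]]$frame_len),
            class = "frame_set")
}

# rbind 3-d arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[2:3]
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(total, d))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# Subset a frame_set by frame indices.
subset_frames <- function(fs_obj, idx) {
  structure(list(
    x = fs_obj$x[idx, , , drop = FALSE],
    info = fs_obj$info[idx, ],
    fs = fs_obj$fs, frame_len = fs_obj$frame_len
  ), class = "frame_set")
}

#' Label frames by fetal R-peak presence (frame R-peak labeling)
#'
#' A frame is Class 1 when at least one annotated fetal R-peak falls inside
#' its half-open sample interval `[start, start + frame_len)`, Class 0
#' otherwise. Unordered peak lists are sorted with a warning.
#'
#' @param frames a `frame_set` from [segment_frames()].
#' @param peaks integer vector of 1-based fetal R-peak sample indices.
#' @return the `frame_set` with a binary `label` column added to `$info`.
#' @export
frpl_label <- function(frames, peaks) {
  peaks <- as.integer(peaks)
  if (is.unsorted(peaks)) {
    warn("peak annotations were not ordered; sorting them")
    peaks <- sort(peaks)
  }
  n_total <- dim(frames$x)[1] * frames$frame_len
  assert_that(all(peaks >= 1), "peak indices must be >= 1")
  frame_of_peak <- (peaks - 1L) %/% frames$frame_len + 1L
  frame_of_peak <- frame_of_peak[frame_of_peak <= dim(frames$x)[1]]
  labels <- integer(dim(frames$x)[1])
  labels[unique(frame_of_peak)] <- 1L
  frames$info$label <- labels
  frames
}

#' Inverse-frequency class weights
#'
#' `w_c = ns / (nc * ns_c)` with `ns` the total number of frames, `nc = 2`
#' classes and `ns_c` the count in class `c`; balanced labels give unit
#' weights, the rare class is weighted up.
#'
#' @param labels binary vector (0/1), both classes present.
#' @return named numeric vector `c(w0 = ..., w1 = ...)`.
#' @export
#' @examples
#' class_weights(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
class_weights <- function(labels) {
  ns <- length(labels)
  ns1 <- sum(labels == 1)
  ns0 <- sum(labels == 0)
  if (ns0 == 0 || ns1 == 0) {
    abort("both classes must be present to define class weights",
          class = "fetalpeaks_imbalance_error")
  }
  c(w0 = ns / (2 * ns0), w1 = ns / (2 * ns1))
}

#' Record-to-labeled-frames convenience chain
#'
#' Filter, optionally standardize, segment and label one record in the order
#' the pipeline uses (filter, standardize, segment, label).
#'
#' @param record an abdominal record tibble.
#' @param peaks fetal R-peak annotations (1-based sample indices).
#' @param standardizer optional fitted [fit_standardizer()] parameters.
#' @param frame_ms frame duration in milliseconds.
#' @param filter logical; apply [bandpass_notch()] first.
#' @param notch mains frequency for the notch stage.
#' @return a labeled `frame_set`.
#' @export
prepare_frames <- function(record, peaks, standardizer = NULL, frame_ms = 65,
                           filter = TRUE, notch = 50) {
  if (filter) record <- bandpass_notch(record, notch = notch)
  if (!is.null(standardizer)) record <- apply_standardizer(standardizer, record)
  frpl_label(segment_frames(record, frame_ms), peaks)
}
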