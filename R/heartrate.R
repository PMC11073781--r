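#' R-R intervals from peak sample indices
#'
#' @param peaks strictly increasing 1-based sample indices (>= 2 of them).
#' @param fs sampling rate in Hz.
#' @return numeric vector of intervals in seconds.
#' @export
rr_intervals <- function(peaks, fs) {
  if (length(peaks) < 2) {
    abort("at least 2 peaks are needed to form an R-R interval",
          class = "fetalpeaks_insufficient_peaks_error")
  }
  diff(peaks) / fs
}

#' Instantaneous heart rate from R-R intervals
#'
#' `HR = 60 / RR` with RR in seconds, giving beats per minute.
#'
#' @param intervals positive R-R intervals in seconds.
#' @return heart rates in bpm.
#' @export
hr_from_rr <- function(intervals) {
  if (any(intervals <= 0)) {
    abort("R-R intervals must be strictly positive", class = "fetalpeaks_domain_error")
  }
  60 / intervals
}

#' Windowed heart-rate series
#'
#' Non-overlapping windows of `window_s` seconds; each window's HR is the mean
#' of the instantaneous `60 / RR` over the intervals whose midpoint falls in
#' the window. Windows holding no interval midpoint are NA.
#'
#' @param peaks strictly increasing 1-based peak sample indices.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (10 s is common clinical practice).
#' @param duration_s record span in seconds; defaults to the last peak time
#'   rounded up to a whole window.
#' @return an `hr_series` tibble: `t_start_s`, `t_end_s`, `hr_bpm`,
#'   `n_intervals`.
#' @export
windowed_hr <- function(peaks, fs, window_s = 10, duration_s = NULL) {
  rr <- rr_intervals(peaks, fs)
  t_peaks <- (peaks - 1) / fs
  mid <- (t_peaks[-length(t_peaks)] + t_peaks[-1]) / 2
  hr <- hr_from_rr(rr)
  duration_s <- duration_s %||% (ceiling(max(t_peaks) / window_s) * window_s)
  assert_that(duration_s >= window_s, "record must span at least one window")
  n_win <- floor(duration_s / window_s)
  win <- pmin(floor(mid / window_s) + 1L, n_win)
  out <- tibble(
    t_start_s = (seq_len(n_win) - 1) * window_s,
    t_end_s = seq_len(n_win) * window_s,
    hr_bpm = NA_real_, n_intervals = 0L
  )
  agg <- tibble(win = win, hr = hr) |>
    group_by(.data$win) |>
    summarise(hr_bpm = mean(.data$hr), n_intervals = dplyr::n(), .groups = "drop")
  out$hr_bpm[agg$win] <- agg$hr_bpm
  out$n_intervals[agg$win] <- agg$n_intervals
  class(out) <- c("hr_series", class(out))
  out
}

#' Correct detection dropouts in a beat sequence
#'
#' A missed beat leaves a doubled (or tripled) R-R interval that biases every
#' derived heart-rate window downwards. Intervals longer than `max_factor`
#' times the running median R-R (window of 9 intervals) are treated as
#' containing `round(RR / median) - 1` undetected beats, and that many
#' pseudo-peaks are inserted at even spacing. This is heart-rate-level
#' bookkeeping, not detection: the inserted times are interpolations for rate
#' computation, standard practice when displaying fetal heart rate through
#' detector dropouts.
#'
#' @param peaks strictly increasing 1-based peak sample indices.
#' @param fs sampling rate in Hz.
#' @param max_factor multiple of the running median R-R above which an
#'   interval is treated as a dropout.
#' @return the augmented, sorted peak index vector.
#' @export
fill_rr_dropouts <- function(peaks, fs, max_factor = 1.6) {
  if (length(peaks) < 3) return(peaks)
  rr <- diff(peaks)
  med <- running_median(rr, 9)
  extra <- integer(0)
  for (j in which(rr > max_factor * med)) {
    k <- round(rr[j] / med[j])
    if (k < 2) next
    ins <- peaks[j] + round(seq_len(k - 1) * rr[j] / k)
    extra <- c(extra, as.integer(ins))
  }
  sort(unique(c(peaks, extra)))
}

#' Signal-dependent rank-order mean (SD-ROM) impulse rejection
#'
#' For each interior sample x(n) the four neighbours
#' x(n-2), x(n-1), x(n+1), x(n+2) are ranked r1 <= r2 <= r3 <= r4 and the
#' rank-order mean is ROM = (r2 + r3) / 2. The rank-ordered distances of x
#' from the window are d_k = r_k - x when x <= ROM, else d_k = x - r_(5-k),
#' for k = 1, 2; x is replaced by ROM when d_k > T_k for either threshold.
#' The filter runs recursively (already-corrected samples feed later
#' windows), and the two edge samples on each side pass through.
#'
#' @param x numeric series (heart rates in bpm), length >= 5; shorter input
#'   passes through with a notice.
#' @param thresholds `c(T1, T2)` in the series' units.
#' @return the filtered series.
#' @export
#' @examples
#' sdrom_filter(c(140, 140, 200, 140, 140), thresholds = c(8, 20))
sdrom_filter <- function(x, thresholds = c(8, 20)) {
  if (length(x) < 5) {
    inform("series shorter than 5 samples; SD-ROM passes it through unchanged")
    return(x)
  }
  y <- x
  for (n in 3:(length(x) - 2)) {
    w <- sort(c(y[n - 2], y[n - 1], y[n + 1], y[n + 2]))
    rom <- (w[2] + w[3]) / 2
    d <- if (y[n] <= rom) w[1:2] - y[n] else y[n] - w[4:3]
    if (any(d > thresholds)) y[n] <- rom
  }
  y
}

#' Exponential adaptive smoothing
#'
#' `y_n = alpha * x_n + (1 - alpha) * y_(n-1)` with `y_1 = x_1`.
#'
#' @param x numeric series.
#' @param alpha smoothing coefficient in (0, 1]; 1 is the identity.
#' @return the smoothed series.
#' @export
adaptive_smooth <- function(x, alpha = 0.3) {
  assert_that(is_scalar_number(alpha) && alpha > 0 && alpha <= 1,
              "alpha must lie in (0, 1]")
  assert_that(length(x) >= 1, "series must be non-empty")
  if (length(x) == 1) return(x)
  c(x[1], as.numeric(stats::filter(alpha * x[-1], 1 - alpha,
                                   method = "recursive", init = x[1])))
}

#' Fetal heart-rate enhancement (FHRE)
#'
#' Fills undefined windows by linear interpolation, removes impulsive
#' artifacts with [sdrom_filter()] and smooths the result with
#' [adaptive_smooth()], adding an `hr_fhre_bpm` column to the series.
#'
#' @param series an `hr_series` from [windowed_hr()].
#' @param thresholds SD-ROM thresholds in bpm.
#' @param alpha smoothing coefficient.
#' @return the series with an added `hr_fhre_bpm` column.
#' @export
fhre <- function(series, thresholds = c(8, 20), alpha = 0.3) {
  x <- series$hr_bpm
  if (anyNA(x)) x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  series$hr_fhre_bpm <- adaptive_smooth(sdrom_filter(x, thresholds), alpha)
  class(series) <- unique(c("hr_series", class(series)))
  series
}

#' Plot a heart-rate series
#'
#' @param object an `hr_series` tibble.
#' @param ... unused.
#' @return a ggplot showing the raw (and, if present, FHRE-enhanced) windowed
#'   heart rate.
#' @method autoplot hr_series
#' @export
autoplot.hr_series <- function(object, ...) {
  df <- object |>
    mutate(t_mid = (t_start_s + t_end_s) / 2) |>
    tidyr::pivot_longer(dplyr::any_of(c("hr_bpm", "hr_fhre_bpm")),
                        names_to = "variant", values_to = "hr")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_mid, .data$hr, colour = .data$variant)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "fetal HR (bpm)", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
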