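#' Synthesize a single-channel cardiac beat train
#'
#' Generates a clean single-source ECG trace by placing one PQRST complex per
#' beat. Successive R-R intervals are drawn i.i.d. from a truncated normal
#' whose mean and sd derive from the heart-rate specification (RR truncated to
#' [0.2, 2] s). Each wave of the complex is a Gaussian in time whose center
#' offset and width scale with the local R-R interval, so QRS duration tracks
#' the rhythm.
#'
#' The annotated peak of each beat is the sample of maximum amplitude of the
#' clean trace within +/-20 ms of the scheduled R time (for an all-zero
#' morphology the scheduled sample itself is annotated). Sample indices are
#' 1-based.
#'
#' @param hr_mean,hr_sd heart-rate mean and sd in bpm.
#' @param morphology a [beat_morphology()] tibble.
#' @param fs sampling rate in Hz.
#' @param duration trace length in seconds.
#' @return a `beat_train` list: `trace` (length `round(fs * duration)`),
#'   `peaks` (1-based sample indices, strictly increasing), `rr` (intervals in
#'   seconds), `fs`.
#' @export
#' @examples
#' bt <- synth_beat_train(140, 3, fetal_morphology(), fs = 500, duration = 5)
#' length(bt$peaks)
synth_beat_train <- function(hr_mean, hr_sd, morphology = beat_morphology(),
                             fs = 1000, duration = 60) {
  assert_that(is_scalar_number(fs) && fs > 0, "fs must be > 0")
  assert_that(is_scalar_number(duration) && duration > 0, "duration must be > 0")
  assert_that(duration * hr_mean / 60 >= 1, "duration too short for a single beat")
  n <- round(fs * duration)

  rr_mean <- 60 / hr_mean
  rr_sd <- rr_mean * hr_sd / hr_mean
  # draw R-R intervals in one vectorized batch (inverse-CDF truncated normal);
  # top up in the unlikely case the batch does not span the record
  rr <- draw_rr(ceiling(duration / rr_mean * 1.5) + 20, rr_mean, rr_sd)
  while (sum(rr) < duration) rr <- c(rr, draw_rr(20, rr_mean, rr_sd))
  r_times <- cumsum(rr)
  keep <- r_times <= duration - 1 / fs
  r_times <- r_times[keep]
  rr <- rr[seq_along(r_times)]

  trace <- numeric(n)
  if (!all(morphology$amplitude == 0)) {
    for (k in seq_along(r_times)) {
      rr_loc <- rr[k]
      for (w in seq_len(nrow(morphology))) {
        a <- morphology$amplitude[w]
        if (a == 0) next
        center <- r_times[k] + morphology$phase[w] / (2 * pi) * rr_loc
        sig <- morphology$width[w] / (2 * pi) * rr_loc
        i0 <- max(1L, floor((center - 5 * sig) * fs) + 1L)
        i1 <- min(n, ceiling((center + 5 * sig) * fs) + 1L)
        if (i0 > i1) next
        t_loc <- (seq(i0, i1) - 1) / fs
        trace[i0:i1] <- trace[i0:i1] + a * exp(-(t_loc - center)^2 / (2 * sig^2))
      }
    }
  }

  sched <- as.integer(pmin(n, round(r_times * fs) + 1))
  peaks <- vapply(seq_along(sched), function(k) {
    lo <- max(1L, sched[k] - as.integer(round(0.02 * fs)))
    hi <- min(n, sched[k] + as.integer(round(0.02 * fs)))
    win <- trace[lo:hi]
    if (diff(range(win)) == 0) sched[k] else lo + which.max(win) - 1L
  }, integer(1))

  structure(list(trace = trace, peaks = peaks, rr = rr, fs = fs,
                 hr_mean = hr_mean, hr_sd = hr_sd),
            class = "beat_train")
}

# Truncated-normal R-R draws via inverse CDF, so a vectorized batch consumes
# the same uniform stream as a one-at-a-time renewal simulation.
draw_rr <- function(n, rr_mean, rr_sd, lower = 0.2, upper = 2) {
  if (rr_sd == 0) return(rep(rr_mean, n))
  u <- runif(n)
  p_lo <- pnorm(lower, rr_mean, rr_sd)
  p_hi <- pnorm(upper, rr_mean, rr_sd)
  qnorm(p_lo + u * (p_hi - p_lo), rr_mean, rr_sd)
}

#' Mix maternal and fetal sources into a 12-lead abdominal record
#'
#' Each channel is `g_m * maternal + g_f * fetal` plus baseline wander, a
#' powerline tone and white Gaussian noise, quantized to the configured
#' resolution over the full-scale range. Maternal lead gains are drawn
#' uniformly from `cfg$maternal_gain_range`; the fetal gain of each lead is
#' sign-varying (mimicking electrode geometry) with magnitude tied to the
#' maternal gain so that the per-channel RMS ratio of the two contributions
#' equals `cfg$f2m_ratio` up to `cfg$ratio_jitter`.
#'
#' @param maternal,fetal `beat_train` sources of equal length and fs.
#' @param cfg a [sim_config()]; `cfg$seed`, when non-NULL, fixes gains and
#'   noise.
#' @param montage optional lead montage from [draw_montage()] fixing the
#'   maternal gains and fetal polarities (how [generate_cohort()] shares one
#'   electrode placement across subjects); when NULL a fresh montage is drawn.
#' @return list with `record` (an abdominal record tibble, microvolts,
#'   `time_s` + `ch01..ch12`, with `fs` attribute), `truth` (fetal and maternal
#'   peak indices plus the clean source traces) and `gains` (per-lead gain
#'   tibble).
#' @export
mix_abdominal <- function(maternal, fetal, cfg = sim_config(), montage = NULL) {
  if (length(maternal$trace) != length(fetal$trace)) {
    abort("maternal and fetal sources must have the same length",
          class = "fetalpeaks_shape_error")
  }
  assert_that(isTRUE(all.equal(maternal$fs, fetal$fs)), "sources must share one sampling rate")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(maternal$trace)
  fs <- maternal$fs
  nch <- cfg$n_channels

  rms_m <- rms(maternal$trace)
  rms_f <- rms(fetal$trace)
  if (is.null(montage)) montage <- draw_montage(cfg)
  g_m <- montage$g_maternal
  sign_f <- montage$sign_fetal
  jitter <- runif(nch, 1 - cfg$ratio_jitter, 1 + cfg$ratio_jitter)
  g_f <- if (rms_f > 0) sign_f * jitter * cfg$f2m_ratio * g_m * rms_m / rms_f else rep(0, nch)

  t <- (seq_len(n) - 1) / fs
  mat <- matrix(0, n, nch)
  for (l in seq_len(nch)) {
    x <- cfg$amplitude_uv * (g_m[l] * maternal$trace + g_f[l] * fetal$trace)
    x <- x + baseline_wander(n, fs, cfg$noise_bw_uv)
    if (cfg$noise_pl_uv > 0) {
      x <- x + sqrt(2) * cfg$noise_pl_uv * sin(2 * pi * cfg$powerline_hz * t + runif(1, 0, 2 * pi))
    }
    if (cfg$noise_wn_uv > 0) x <- x + rnorm(n, sd = cfg$noise_wn_uv)
    mat[, l] <- quantize(x, cfg$full_scale_uv, cfg$bits)
  }

  record <- record_from_matrix(mat, fs)
  truth <- list(
    fetal_peaks = fetal$peaks, maternal_peaks = maternal$peaks,
    fetal_source = fetal$trace, maternal_source = maternal$trace
  )
  gains <- tibble(channel = channel_names(nch), g_maternal = g_m, g_fetal = g_f)
  list(record = record, truth = truth, gains = gains)
}

#' Draw a lead montage
#'
#' The per-lead coupling of the two cardiac sources into the abdominal
#' electrodes: maternal gains drawn uniformly from the configured range and a
#' random fetal polarity per lead. A cohort recorded with one standardized
#' electrode placement shares a single montage up to per-subject variation
#' (see [generate_cohort()]).
#'
#' @param cfg a [sim_config()].
#' @return a list with `g_maternal` and `sign_fetal`, one entry per lead.
#' @export
draw_montage <- function(cfg = sim_config()) {
  nch <- cfg$n_channels
  list(g_maternal = runif(nch, cfg$maternal_gain_range[1], cfg$maternal_gain_range[2]),
       sign_fetal = sample(c(-1, 1), nch, replace = TRUE))
}

# Per-subject view of a cohort montage: gains jittered, occasional fetal
# polarity flips (fetal position varies between pregnancies).
jitter_montage <- function(montage, gain_jitter = 0.15, flip_prob = 0.05) {
  nch <- length(montage$g_maternal)
  list(
    g_maternal = montage$g_maternal * runif(nch, 1 - gain_jitter, 1 + gain_jitter),
    sign_fetal = montage$sign_fetal * ifelse(runif(nch) < flip_prob, -1, 1)
  )
}

# Sum of three sub-0.5 Hz sinusoids scaled to a target RMS (microvolts).
baseline_wander <- function(n, fs, target_rms) {
  if (target_rms <= 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  f <- runif(3, 0.05, 0.45)
  ph <- runif(3, 0, 2 * pi)
  x <- rowSums(vapply(1:3, function(i) sin(2 * pi * f[i] * t + ph[i]), numeric(n)))
  x / rms(x) * target_rms
}

# Uniform mid-tread quantizer on the 2^bits grid of [-fs_uv, fs_uv].
quantize <- function(x, fs_uv, bits) {
  step <- 2 * fs_uv / 2^bits
  pmin(pmax(step * round(x / step), -fs_uv), fs_uv)
}

#' Generate a synthetic cohort of abdominal records
#'
#' Draws per-subject fetal and maternal heart-rate means uniformly from the
#' configured ranges (defaults 110-160 and 60-100 bpm), synthesizes both
#' sources and mixes them under `cfg`. All subjects share one lead montage
#' (the cohort is recorded with a standardized electrode placement), seen by
#' each subject through mild gain jitter and occasional fetal polarity flips.
#' The seed fixes the whole cohort: identical seeds give bit-identical output.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cfg a [sim_config()] template (its `seed` field is ignored; the
#'   cohort `seed` argument governs).
#' @param seed integer seed.
#' @param fetal_hr_range,maternal_hr_range per-subject heart-rate mean ranges
#'   in bpm.
#' @param montage_gain_jitter,montage_flip_prob per-subject deviation from the
#'   shared montage: relative gain jitter and probability of a fetal polarity
#'   flip per lead.
#' @return a tibble with one row per subject: `subject`, `fetal_hr_mean`,
#'   `maternal_hr_mean`, and list-columns `record`, `truth`, `gains`.
#' @export
#' @examples
#' cohort <- generate_cohort(2, sim_config(duration = 4, fs = 250), seed = 1)
#' cohort$subject
generate_cohort <- function(n_subjects, cfg = sim_config(), seed = 1,
                            fetal_hr_range = c(110, 160),
                            maternal_hr_range = c(60, 100),
                            montage_gain_jitter = 0.15,
                            montage_flip_prob = 0.05) {
  assert_that(is_scalar_number(n_subjects) && n_subjects >= 1, "n_subjects must be >= 1")
  set.seed(seed)
  cfg$seed <- NULL
  montage <- draw_montage(cfg)
  rows <- purrr::map(seq_len(n_subjects), function(i) {
    f_hr <- runif(1, fetal_hr_range[1], fetal_hr_range[2])
    m_hr <- runif(1, maternal_hr_range[1], maternal_hr_range[2])
    m <- synth_beat_train(m_hr, cfg$maternal_hr_sd, maternal_morphology(),
                          fs = cfg$fs, duration = cfg$duration)
    f <- synth_beat_train(f_hr, cfg$fetal_hr_sd, fetal_morphology(),
                          fs = cfg$fs, duration = cfg$duration)
    mix <- mix_abdominal(m, f, cfg,
                         montage = jitter_montage(montage, montage_gain_jitter,
                                                  montage_flip_prob))
    attr(mix$record, "subject") <- sprintf("S%02d", i)
    tibble(subject = sprintf("S%02d", i),
           fetal_hr_mean = f_hr, maternal_hr_mean = m_hr,
           record = list(mix$record), truth = list(mix$truth),
           gains = list(mix$gains))
  })
  bind_rows(rows)
}
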