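#' Beat morphology specification
#'
#' Describes one PQRST complex as a sum of five Gaussian waves evaluated over
#' the beat phase (McSharry-style). Each wave has a dimensionless amplitude
#' (the record is later calibrated to microvolts), a width and a phase offset,
#' both in radians of beat phase, so wave durations scale with the local R-R
#' interval.
#'
#' @param amplitude named numeric vector of wave amplitudes for P, Q, R, S, T.
#' @param width named numeric vector of Gaussian widths (radians), all > 0.
#' @param phase named numeric vector of wave centers (radians); R must sit at 0.
#' @return a `beat_morphology` tibble with one row per wave.
#' @export
#' @examples
#' beat_morphology()
beat_morphology <- function(amplitude = c(P = 0.05, Q = -0.15, R = 1, S = -0.25, T = 0.3),
                            width = c(P = 0.25, Q = 0.1, R = 0.1, S = 0.1, T = 0.4),
                            phase = c(P = -pi / 3, Q = -pi / 12, R = 0, S = pi / 12, T = pi / 2)) {
  waves <- c("P", "Q", "R", "S", "T")
  amplitude <- amplitude[waves]; width <- width[waves]; phase <- phase[waves]
  assert_that(!anyNA(amplitude) && !anyNA(width) && !anyNA(phase),
              "morphology must name all five waves P, Q, R, S, T")
  assert_that(all(width > 0), "wave widths must be strictly positive")
  if (!all(amplitude == 0)) {
    assert_that(amplitude[["R"]] > 0, "R amplitude must be strictly positive")
    assert_that(all(abs(amplitude[["R"]]) > abs(amplitude[setdiff(waves, "R")])),
                "R amplitude must be strictly largest in magnitude")
  }
  out <- tibble(wave = waves, amplitude = unname(amplitude),
                width = unname(width), phase = unname(phase))
  class(out) <- c("beat_morphology", class(out))
  out
}

#' @rdname beat_morphology
#' @details `fetal_morphology()` widens the Q/S offsets slightly so the fetal
#'   QRS spans roughly 50-60 ms at typical fetal rates, in line with reported
#'   fetal QRS durations; `maternal_morphology()` is the plain adult template.
#' @export
maternal_morphology <- function() beat_morphology()

#' @rdname beat_morphology
#' @export
fetal_morphology <- function() {
  beat_morphology(
    amplitude = c(P = 0.04, Q = -0.12, R = 1, S = -0.2, T = 0.25),
    width = c(P = 0.2, Q = 0.12, R = 0.12, S = 0.12, T = 0.35),
    phase = c(P = -pi / 3, Q = -pi / 8, R = 0, S = pi / 8, T = pi / 2)
  )
}

#' Simulator configuration
#'
#' Parameters of the synthetic 12-channel abdominal composite record: sampling,
#' rhythm statistics for the two cardiac sources, the global fetal-to-maternal
#' amplitude ratio, per-lead gain behaviour, additive noise levels and the
#' acquisition quantization. Defaults emulate a 1-minute clinical abdominal
#' recording at 1 kHz / 16 bit with the fetal ECG a fraction of the maternal
#' amplitude.
#'
#' Noise levels are target RMS amplitudes in microvolts of the emitted record;
#' baseline wander is a sum of low-frequency (< 0.5 Hz) sinusoids, powerline a
#' tone at `powerline_hz`, and white noise i.i.d. Gaussian.
#'
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param maternal_hr_mean,maternal_hr_sd maternal heart-rate mean/sd in bpm.
#' @param fetal_hr_mean,fetal_hr_sd fetal heart-rate mean/sd in bpm.
#' @param f2m_ratio fetal-to-maternal amplitude ratio (per-channel RMS of the
#'   two contributions), in (0, 1].
#' @param n_channels number of abdominal leads.
#' @param amplitude_uv calibration: maternal source R amplitude in microvolts
#'   at unit gain.
#' @param maternal_gain_range per-lead maternal gain drawn uniformly here.
#' @param ratio_jitter relative per-lead jitter of the fetal/maternal RMS ratio.
#' @param noise_bw_uv,noise_pl_uv,noise_wn_uv baseline-wander, powerline and
#'   white-noise RMS in microvolts.
#' @param powerline_hz mains frequency, 50 or 60 Hz.
#' @param full_scale_uv quantizer full scale (+/-) in microvolts.
#' @param bits quantizer resolution.
#' @param seed optional integer seed fixing all randomness of a record.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs = 1000, duration = 60,
                       maternal_hr_mean = 80, maternal_hr_sd = 2,
                       fetal_hr_mean = 140, fetal_hr_sd = 3,
                       f2m_ratio = 0.3, n_channels = 12,
                       amplitude_uv = 100,
                       maternal_gain_range = c(0.6, 1.4),
                       ratio_jitter = 0.03,
                       noise_bw_uv = 20, noise_pl_uv = 10, noise_wn_uv = 5,
                       powerline_hz = 50,
                       full_scale_uv = 5000, bits = 16, seed = NULL) {
  assert_that(is_scalar_number(fs) && fs > 0, "sampling_rate must be > 0")
  assert_that(is_scalar_number(duration) && duration > 0, "duration must be > 0")
  for (hr in c(maternal_hr_mean, fetal_hr_mean)) {
    assert_that(hr > 30 && hr < 300, "heart-rate means must lie in (30, 300) bpm")
  }
  assert_that(maternal_hr_sd >= 0 && fetal_hr_sd >= 0, "heart-rate sd must be >= 0")
  assert_that(f2m_ratio > 0 && f2m_ratio <= 1, "fetal/maternal amplitude ratio must lie in (0, 1]")
  assert_that(powerline_hz %in% c(50, 60), "powerline_hz must be 50 or 60")
  assert_that(all(c(noise_bw_uv, noise_pl_uv, noise_wn_uv) >= 0), "noise levels must be >= 0")
  assert_that(bits >= 2 && bits <= 32, "quantization_bits must lie in [2, 32]")
  structure(list(
    fs = fs, duration = duration,
    maternal_hr_mean = maternal_hr_mean, maternal_hr_sd = maternal_hr_sd,
    fetal_hr_mean = fetal_hr_mean, fetal_hr_sd = fetal_hr_sd,
    f2m_ratio = f2m_ratio, n_channels = n_channels,
    amplitude_uv = amplitude_uv,
    maternal_gain_range = maternal_gain_range, ratio_jitter = ratio_jitter,
    noise_bw_uv = noise_bw_uv, noise_pl_uv = noise_pl_uv, noise_wn_uv = noise_wn_uv,
    powerline_hz = powerline_hz,
    full_scale_uv = full_scale_uv, bits = bits, seed = seed
  ), class = "sim_config")
}
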