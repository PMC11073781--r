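test_that("constant-rate rhythm gives exact half-second R-R intervals", {
  bt <- synth_beat_train(120, 0, fs = 1000, duration = 10)
  expect_true(length(bt$peaks) %in% 19:21)
  expect_true(all(bt$rr == 0.5))
  expect_length(bt$trace, 10000)
})

test_that("zero-amplitude morphology yields a flat trace but scheduled peaks", {
  morph <- beat_morphology(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  bt <- synth_beat_train(120, 0, morph, fs = 500, duration = 5)
  expect_true(all(bt$trace == 0))
  expect_gt(length(bt$peaks), 0)
  expect_true(all(diff(bt$peaks) > 0))
})

test_that("beat count matches an independent renewal-process oracle", {
  for (s in c(11, 12, 13)) {
    set.seed(s)
    bt <- synth_beat_train(140, 5, fs = 1000, duration = 60)
    set.seed(s)
    expect_identical(length(bt$peaks), renewal_count(140, 5, 60, 1000))
  }
})

test_that("annotated peaks are local maxima of the clean trace", {
  set.seed(3)
  bt <- synth_beat_train(140, 4, fetal_morphology(), fs = 1000, duration = 20)
  for (p in bt$peaks) {
    lo <- max(1, p - 2); hi <- min(length(bt$trace), p + 2)
    expect_equal(bt$trace[p], max(bt$trace[lo:hi]))
  }
})

test_that("invalid rhythm or timing configuration is rejected", {
  expect_error(synth_beat_train(120, 0, fs = -1, duration = 10), class = "fetalpeaks_config_error")
  expect_error(synth_beat_train(120, 0, fs = 100, duration = 0), class = "fetalpeaks_config_error")
  expect_error(synth_beat_train(5, 0, fs = 100, duration = 2), class = "fetalpeaks_config_error")
  expect_error(sim_config(f2m_ratio = 0), class = "fetalpeaks_config_error")
  expect_error(sim_config(fetal_hr_mean = 400), class = "fetalpeaks_config_error")
})

noise_free <- function(...) {
  sim_config(duration = 10, noise_bw_uv = 0, noise_pl_uv = 0, noise_wn_uv = 0, ...)
}

test_that("noise-free mixture with a silent fetus is a scaled maternal source", {
  cfg <- noise_free(seed = 5)
  m <- synth_beat_train(80, 0, fs = 1000, duration = 10)
  f <- synth_beat_train(140, 0, beat_morphology(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0)),
                        fs = 1000, duration = 10)
  mix <- mix_abdominal(m, f, cfg)
  mat <- fetalpeaks:::record_matrix(mix$record)
  step <- 2 * cfg$full_scale_uv / 2^cfg$bits
  for (l in seq_len(ncol(mat))) {
    expected <- cfg$amplitude_uv * mix$gains$g_maternal[l] * m$trace
    expect_lte(max(abs(mat[, l] - expected)), step / 2 + 1e-9)
  }
})

test_that("mixing is linear up to quantization under a fixed noise realization", {
  cfg <- noise_free(seed = 9)
  m <- synth_beat_train(80, 0, fs = 500, duration = 10)
  f <- synth_beat_train(140, 0, fetal_morphology(), fs = 500, duration = 10)
  half <- function(src) {
    out <- src
    out$trace <- src$trace / 2
    out
  }
  mix_ab <- mix_abdominal(half(m), half(f), cfg)
  mix_cd <- mix_abdominal(half(m), half(f), cfg)
  mix_sum <- mix_abdominal(m, f, cfg)
  lhs <- fetalpeaks:::record_matrix(mix_ab$record) + fetalpeaks:::record_matrix(mix_cd$record)
  rhs <- fetalpeaks:::record_matrix(mix_sum$record)
  step <- 2 * cfg$full_scale_uv / 2^cfg$bits
  expect_lte(max(abs(lhs - rhs)), 2 * step)
})

test_that("configured white-noise RMS is realized per channel", {
  silent <- beat_morphology(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  m <- synth_beat_train(80, 0, silent, fs = 1000, duration = 60)
  f <- synth_beat_train(140, 0, silent, fs = 1000, duration = 60)
  cfg <- sim_config(duration = 60, noise_bw_uv = 0, noise_pl_uv = 0,
                    noise_wn_uv = 7, seed = 21)
  mix <- mix_abdominal(m, f, cfg)
  mat <- fetalpeaks:::record_matrix(mix$record)
  for (l in seq_len(ncol(mat))) {
    expect_lt(abs(rms(mat[, l]) - 7) / 7, 0.05)
  }
})

test_that("quantized samples sit on the configured grid", {
  cfg <- sim_config(duration = 5, seed = 2)
  m <- synth_beat_train(80, 2, fs = 1000, duration = 5)
  f <- synth_beat_train(140, 3, fetal_morphology(), fs = 1000, duration = 5)
  mat <- fetalpeaks:::record_matrix(mix_abdominal(m, f, cfg)$record)
  step <- 2 * cfg$full_scale_uv / 2^cfg$bits
  expect_true(all(abs(mat / step - round(mat / step)) < 1e-9))
})

test_that("per-channel fetal/maternal RMS ratio matches the configured ratio", {
  cfg <- noise_free(seed = 8, f2m_ratio = 0.3)
  m <- synth_beat_train(80, 2, fs = 1000, duration = 10)
  f <- synth_beat_train(140, 3, fetal_morphology(), fs = 1000, duration = 10)
  mix <- mix_abdominal(m, f, cfg)
  ratio <- abs(mix$gains$g_fetal) * rms(f$trace) / (mix$gains$g_maternal * rms(m$trace))
  expect_true(all(abs(ratio - 0.3) / 0.3 < 0.1))
})

test_that("mismatched source lengths raise a shape error", {
  m <- synth_beat_train(80, 0, fs = 500, duration = 10)
  f <- synth_beat_train(140, 0, fs = 500, duration = 5)
  expect_error(mix_abdominal(m, f, sim_config()), class = "fetalpeaks_shape_error")
})

test_that("cohort generation is deterministic and respects heart-rate ranges", {
  cfg <- sim_config(duration = 3, fs = 200)
  c1 <- generate_cohort(3, cfg, seed = 42)
  c2 <- generate_cohort(3, cfg, seed = 42)
  expect_identical(c1, c2)
  expect_identical(c1$subject, c("S01", "S02", "S03"))

  big <- generate_cohort(100, sim_config(duration = 2, fs = 100), seed = 7)
  expect_true(all(big$fetal_hr_mean >= 110 & big$fetal_hr_mean <= 160))
  expect_true(all(big$maternal_hr_mean >= 60 & big$maternal_hr_mean <= 100))
  expect_length(unique(big$subject), 100)
})

test_that("record and annotation files round-trip through disk", {
  withr::with_tempdir({
    cohort <- generate_cohort(2, sim_config(duration = 3, fs = 200), seed = 6)
    write_cohort(cohort, "cohort", cfg = sim_config(duration = 3, fs = 200), seed = 6)
    expect_true(file.exists("cohort/manifest.json"))
    back <- load_cohort("cohort")
    expect_identical(back$subject, cohort$subject)
    expect_identical(back$truth[[1]]$fetal_peaks, cohort$truth[[1]]$fetal_peaks)
    orig <- fetalpeaks:::record_matrix(cohort$record[[2]])
    got <- fetalpeaks:::record_matrix(back$record[[2]])
    expect_equal(got, orig, tolerance = 1e-9)
    expect_equal(record_fs(back$record[[1]]), 200)
  })
})
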