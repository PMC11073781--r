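---
title: "Detecting fetal R-peaks in abdominal ECG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal R-peaks in abdominal ECG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalpeaks)
```

## The problem

A noninvasive abdominal ECG records, on every electrode, a superposition of
the maternal ECG (large), the fetal ECG (an order of magnitude smaller), and
noise. Clinically useful fetal heart-rate (FHR) monitoring needs the fetal
R-peak times, which classical cancellation or source-separation pipelines
recover only with expert tuning. **fetalpeaks** implements a direct route:
a recurrent sequence classifier decides, for every short multichannel frame,
whether it contains a fetal R-peak; post-processing turns those frame
decisions into a physiologically plausible beat sequence; the beat sequence
yields a windowed FHR series that is then cleaned of impulsive artifacts.

The chain is

1. **simulate / load** — 12-channel, 1 kHz, 16-bit abdominal records;
2. **preprocess** — 0.05–100 Hz band-pass, mains notch, per-channel z-scoring,
   segmentation into contiguous 65 ms frames, frame labeling;
3. **detect** — a 3-layer bidirectional LSTM with class-weighted
   cross-entropy;
4. **refine (FECGPP)** — refractory pruning plus median-based gap filling;
5. **heart rate (FHRE)** — 10-s windowed FHR, SD-ROM impulse rejection,
   exponential smoothing;
6. **evaluate** — confusion metrics, ROC/AUC, Pearson and Bland–Altman
   agreement, k-fold and leave-one-subject-out harnesses, stratified cohort
   summaries.

## The synthetic cohort

Clinical abdominal recordings with beat-exact fetal annotations are rarely
shareable, so the package ships a generative stand-in that preserves the
statistical features the detector relies on. Every piece is explicit and
seeded:

* **Sources.** Each cardiac source is a Gaussian-wave PQRST template evaluated
  on a per-beat phase, so wave widths scale with the local R–R interval.
  R–R intervals are i.i.d. truncated normal (support [0.2, 2] s), derived
  from a heart-rate mean and SD. Per-subject fetal HR means are drawn from
  110–160 bpm, maternal from 60–100 bpm — the clinically normal ranges.
* **Montage.** A cohort shares one electrode placement, so the per-lead
  coupling (maternal gain in U(0.6, 1.4), fetal polarity per lead) is drawn
  once per cohort and each subject sees it through mild jitter
  (gains ×U(0.85, 1.15), fetal polarity flips with probability 0.05 per
  lead, emulating differing fetal positions). Fully independent per-subject
  montages are available through `mix_abdominal()` directly, but they make
  subject-independent generalization from a handful of subjects nearly
  impossible for *any* detector — no shared geometry is left to learn — and
  do not represent a study that uses one standardized electrode layout.
* **Amplitude calibration.** The maternal R wave maps to 100 µV at unit gain
  (typical for abdominal leads). The fetal contribution is scaled so the
  per-channel fetal/maternal RMS ratio equals the configured
  `f2m_ratio` (default 0.3) up to ±3 % per-lead jitter. Studies in this area
  rarely report their fetal-to-maternal SNR; the ratio is therefore an
  explicit, inspectable configuration value, not a hidden constant.
* **Noise.** Baseline wander (three sinusoids below 0.5 Hz, 20 µV RMS),
  mains tone (50/60 Hz, 10 µV RMS), and white Gaussian noise (5 µV RMS),
  per channel. The band-pass/notch stage removes most of the first two;
  the white noise is the effective in-band floor (roughly a fifth of the
  fetal RMS at default settings).
* **Quantization.** Uniform 16-bit grid over ±5 mV, matching the stated
  acquisition resolution.

What the simulator does **not** model: uterine EMG bursts, electrode motion
artifacts, autonomic heart-rate variability spectra, twins, arrhythmic
morphologies, and any coupling between the two rhythms. Overlapping
maternal/fetal QRS complexes do occur freely and are the hard cases. Passing
tests on this cohort therefore show that the pipeline recovers fetal beats
under realistic amplitude ratios, montage variation and stationary noise —
not that it is robust to every artifact class seen in the field.

## Frame labeling and class weights

The fetal QRS spans roughly 50–70 ms at 1 kHz, so records are cut into
contiguous, non-overlapping 65 ms frames (65 samples × 12 channels); a frame
is Class 1 iff a fetal R-peak annotation falls inside its half-open sample
interval. The trailing remainder of a record (5 samples of a 60 s record at
1 kHz) is dropped. With fetal rates around 110–160 bpm about 15 % of frames
are positive, so training uses inverse-frequency class weights
`w_c = ns / (2 * ns_c)`; a positive fraction of 0.1577 gives the
(0.59, 3.17) pair that weighted training is known to use in this
architecture family.

Standardization is per channel (12 means and SDs), fitted on training
records only and frozen for test data. Channels carry different gains, so
pooled-across-channel statistics would leave systematic scale differences.

## The detector

Three stacked bidirectional LSTM layers with per-direction hidden sizes
(200, 100, 50) by default, dropout 0.5 after the first and second layers, a
fully connected layer on the concatenated final states of the last layer
(forward direction at the last timestep, backward at the first), and a
softmax over two classes. In the stacked-bidirectional convention a layer
with H units per direction has input weights 8H × D and recurrent weights
8H × H; the default sizes make that whole table mutually consistent
(1600 × 12, 1600 × 200, 800 × 400, 800 × 100, 400 × 200, fully connected
2 × 100). A smaller variant is always one `detector_config()` away.

Training minimizes the class-weighted cross-entropy
`mean(w[y] * -log p[y])` with Adam (β₁ = 0.9, β₂ = 0.999), a learning rate
of 5e-4 dropped once by ×0.1 after half the epochs, and global L2 gradient
clipping at 1. Each 65-sample frame is one sequence-to-label training
sequence. Everything is deterministic given the schedule seed: weight
initialization (Glorot uniform, unit forget-gate bias), shuffling, and
dropout masks. The forward/backward recurrences run in compiled kernels
(`src/lstm_kernels.cpp`); all input projections are single BLAS products.
The backward pass is verified against central finite differences in the test
suite.

An optional montage augmentation (random per-channel sign flips, gain
jitter, channel permutation per minibatch) is available in
`train_schedule()` for cohorts whose electrode geometry genuinely varies;
it is off by default — at the package's training scales it slows learning
more than it helps transfer.

## FECGPP: from frame decisions to beats

The raw classifier output is a per-frame posterior. Refinement is two
deterministic passes:

1. **Merge runs.** Each maximal run of consecutive positive frames becomes
   one candidate event at the center of its maximum-posterior frame.
2. **Refractory.** While two events are closer than 250 ms (a 240 bpm fetal
   ceiling), the lower-confidence one is deleted.
3. **Gap fill.** Where an inter-event interval exceeds 1.8× the running
   median R–R (window of 9 intervals), the highest-posterior unused frame
   inside the gap is promoted to an event, provided its posterior is at
   least 0.2 and its center keeps 250 ms clearance to both neighbors. The
   pass repeats until no insertion is possible, which makes the whole
   refinement idempotent.

The 1.8 gap factor flags a single missed beat (a doubled interval) without
firing on normal rate variability; 0.2 is low enough to recover beats the
softmax ranked correctly but below threshold. All three numbers are exposed
as configuration.

Peaks are located at frame centers: the pipeline works at frame resolution
throughout, so sub-frame re-centering against a clean fetal waveform (which
does not exist at inference time) is deliberately out of scope.

## FHRE: heart-rate computation and enhancement

Instantaneous HR is `60 / RR` (bpm). The series is summarized over
non-overlapping 10 s windows — the common clinical display resolution — as
the mean instantaneous HR of the intervals whose midpoints fall in the
window; windows without an interval are undefined and linearly interpolated
before enhancement.

Enhancement is SD-ROM followed by exponential smoothing. SD-ROM ranks the
four neighbors x(n±1), x(n±2) as r1 ≤ … ≤ r4, computes the rank-order mean
ROM = (r2+r3)/2, and replaces x(n) by ROM when its rank-ordered distance
from the window exceeds either threshold (defaults 8 and 20 bpm); the filter
is recursive (corrected samples feed later windows) and passes edge samples
through. A detection error of one beat flips a 10 s window by tens of bpm —
exactly the impulse shape SD-ROM removes — while true accelerations and
decelerations move neighboring windows together and are preserved. The
smoother `y[n] = 0.3 x[n] + 0.7 y[n-1]` is the simplest adaptive filter;
the enhancement stage is deliberately filter-agnostic, and α is exposed.

## Evaluation machinery

Frame-level confusion metrics are the primary measure (accuracy,
sensitivity, PPV, NPV, F1); beat-level matching within ±50 ms is provided as
a secondary, clearly-labeled convenience for HR validation. ROC/AUC uses the
trapezoidal rule with a fixed orientation (higher posterior ⇒ Class 1), so
anti-separating scores genuinely score below 0.5. Bland–Altman limits of
agreement are bias ± 1.96 × sample SD. All summary statistics use the
sample (n−1) standard deviation, which is what reproduces the bundled
reference cohort's printed 88.8 ± 6.4 exactly; printed-table reproduction
rounds half-to-even at the printed precision.

The 5-fold harness builds folds from subject-contiguous chunks (each
subject's frames are cut into k contiguous blocks assigned to folds by a
seeded permutation), so folds stay temporally coherent while every fold
sees every subject. The leave-one-subject-out harness trains on all other
subjects and never lets test-subject frames into training or into the
standardizer.

Two small reference tables from a published 26-subject clinical validation
(per-fold accuracies/F1 of a 5-fold run; per-subject demographics with LOSO
accuracies) are bundled as CSV so the package's summary arithmetic —
means, SDs, gestational-age and maternal-status strata — can be checked
against printed values. The underlying signals are confidential and not
included; nothing in the package attempts to reproduce signal-level results
on them.

## Problem sizes and numerical choices

The package's own experiments (test suite and `scripts/acceptance.R`) use a
6-subject cohort of 60 s records at 1 kHz, a reduced (64, 32, 16)
architecture, and 15 training epochs with batch size 64 — sizes chosen so a
complete leave-one-subject-out experiment trains in minutes on one CPU core
while leaving the published-scale (200, 100, 50) architecture as the
default configuration for real use. Other conventions:

* sample indices are 1-based (R convention) everywhere, including
  annotation files;
* the softmax subtracts the row maximum before exponentiation; posteriors
  are floored at 1e-12 inside the loss;
* the truncated-normal R-R sampler uses the inverse-CDF transform, so a
  vectorized batch consumes the same uniform stream as a sequential renewal
  simulation (this is what the renewal-oracle test exploits);
* degenerate confusion ratios (empty denominators) are reported as 0 and
  flagged rather than NaN;
* zero-variance channels abort standardization with the channel named.

## Known limitations

* The simulator's noise model is stationary; real abdominal recordings are
  not, and performance there will depend on artifact handling outside this
  package's scope.
* Frame-resolution peak timing (±32 ms) bounds the accuracy of any derived
  beat-to-beat variability measure; windowed HR is unaffected.
* With very small cohorts the detector inherits the montage: a subject whose
  electrode placement differs grossly from the training cohort's is out of
  distribution (the optional training-time montage augmentation exists for
  that regime, at a cost in training time).
* The LOSO harness retrains one model per subject; at the published
  architecture size this is a long CPU computation and is intended for
  scheduled runs, not interactive use.
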