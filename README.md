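# fetalpeaks

Detection of **fetal ECG R-peaks directly from multichannel maternal
abdominal recordings**, with fetal heart-rate estimation on top. The package
is aimed at biomedical-signal researchers and engineers who need a fully
automated, trainable alternative to maternal-ECG cancellation and blind
source separation for noninvasive fetal monitoring — including a synthetic
cohort generator, so the whole pipeline can be trained, tested and studied
without access to (typically confidential) clinical recordings.

## The method

A 12-channel abdominal record x(t) ∈ ℝ¹² (1 kHz, 16-bit) is band-passed to
0.05–100 Hz, notch-filtered at the mains frequency, standardized per channel
with training-set statistics (z = (X − μ)/σ), and cut into contiguous 65 ms
frames. Each frame gets a binary label: Class 1 iff an annotated fetal
R-peak falls inside the frame (FRPL — frame R-peak labeling). A
sequence-to-label classifier — three stacked bidirectional LSTM layers
(default 200/100/50 units per direction), dropout 0.5 between them, a fully
connected layer on the concatenated final hidden states and a softmax —
is trained with class-weighted cross-entropy,

    w_c = ns / (nc · ns_c),   nc = 2,

so the rare R-peak class (≈ 16 % of frames) is up-weighted (e.g. w₁ = 3.17,
w₀ = 0.59 at a positive fraction of 0.1577). Training uses Adam, learning
rate 5·10⁻⁴ dropped ×0.1 halfway through the epochs, and global
gradient-norm clipping at 1. The recurrences run in compiled C++ kernels;
the backward pass is verified against finite differences in the test suite.

Frame-level detections are refined (FECGPP): runs of positive frames
collapse to their best frame's center, events violating a 250 ms fetal
refractory period are pruned (weaker confidence first), and missed beats
are recovered where an inter-event interval exceeds 1.8× the running median
R–R. The refined beat sequence gives windowed fetal heart rate,
HR = 60/RR (bpm) averaged over 10-s windows, which is then enhanced (FHRE):
dropout-length intervals are split, impulsive artifacts are removed by the
signal-dependent rank-order mean (SD-ROM) filter, and the series is
exponentially smoothed.

Evaluation tools cover frame-level confusion metrics, ROC/AUC, Pearson
correlation, Bland–Altman limits of agreement, 5-fold and
leave-one-subject-out (LOSO) cross-validation harnesses, and stratified
cohort summaries.

## Worked example

Simulate a 6-subject cohort (60 s each, fetal/maternal amplitude ratio 0.3,
moderate noise), train on five subjects and detect on the held-out sixth:

```r
library(fetalpeaks)

cfg <- pipeline_config(
  n_subjects = 6,
  sim        = sim_config(duration = 60, f2m_ratio = 0.3),
  detector   = detector_config(hidden_sizes = c(64, 32, 16)),
  schedule   = train_schedule(epochs = 15, batch_size = 64),
  seed       = 1
)
res <- run_pipeline(cfg, verbose = TRUE)   # ~5 min on one CPU core

res$report$frames_after
#> # A tibble: 1 × 11
#>      tp    fp    fn    tn accuracy sensitivity specificity   ppv   npv    f1
#>   <int> <int> <int> <int>    <dbl>       <dbl>       <dbl> <dbl> <dbl> <dbl>
#> 1   110     1    20   792    0.977       0.846       0.999 0.991 0.975 0.913
round(res$report$auc, 3)
#> [1] 0.994
round(res$report$hr_mae_bpm, 2)
#> [1] 0.57
```

Reading the numbers: of the held-out subject's 923 frames, the refined
detections hit 110 of 130 true R-peak frames with a single false positive —
97.7 % frame accuracy, F1 0.913, AUC 0.994. Refinement raised sensitivity
from 81.5 % (raw network output) to 84.6 %. The enhanced 10-s heart-rate
series tracks the ground-truth fetal HR with a mean absolute error of
0.57 bpm. `autoplot(res$hr)` plots the raw and enhanced HR series;
`plot_roc(roc_auc(...))` and `autoplot(bland_altman(...))` cover the other
standard displays.

A bundled reference table from a 26-subject clinical validation
(`reference_cohort()`) supports the stratified summaries, e.g.:

```r
stratified_summary(reference_cohort(),
                   list(vernix_period = ~ ga_weeks >= 28 & ga_weeks <= 34),
                   accuracy_pct)
#> # A tibble: 1 × 5
#>   stratum            n  mean    sd mean_rounded
#>   <chr>          <int> <dbl> <dbl>        <dbl>
#> 1 vernix_period     10  86.7  7.86         86.7
```

A thin command-line front end (`inst/cli/fetalpeaks.R`) exposes
`simulate`, `run`, `detect`, `heartrate` and `evaluate` subcommands over
the same functions.

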