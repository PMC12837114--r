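# vsabci

Simulation and gaze-independent decoding of six-target visual oddball
brain–computer interface (BCI) sessions.

## What this is for

P300 spellers select a target by detecting which flashed stimulus
elicits the attended-target response — chiefly the P3, a centro-parietal
positivity ~300–500 ms after an attended flash. They work well when the
user fixates the target (*overt* visuospatial attention, VSA), but users
with combined speech, physical and gaze impairment often cannot fixate,
leaving *covert* VSA (gaze at center, attention in the periphery) or
*free*, uninstructed gaze. Covert operation is harder for two reasons:
the P3 is smaller, and its trial-to-trial **latency jitter** is larger,
which smears any classifier with a fixed temporal window.

`vsabci` is for researchers studying this computationally. It provides:

* a **session simulator** for a Hex-o-Spell-style paradigm (6 targets on
  a 12.28° hexagon, 100 ms flashes at 200 ± 50 ms onset asynchrony,
  10–15 intensifications per target, 3 conditions × 6 cued targets = 18
  blocks) with condition-dependent P3 amplitude/jitter, gaze-dependent
  early visual components, colored spatially-correlated noise, binocular
  gaze traces with dropout, and full ground truth;
* the standard **preprocessing chain**: zero-phase 0.5–16 Hz Butterworth
  filtering, RANSAC bad-channel detection, mastoid (TP9/TP10)
  re-referencing, epoching to [−0.1, 0.9) s, truncation to the first 10
  repetitions;
* three **decoders** — block-Toeplitz LDA (`fit_tlda`), xDAWN-covariance
  tangent-space LDA (`fit_xdawn_ts`), and WCBLE (`fit_wcble`),
  classifier-based latency estimation with Woody iterations: slide the
  classifier over a wide −100..900 ms epoch, realign target epochs at
  the score maximum, refit, and score test epochs by the max over
  latencies;
* **evaluation machinery**: block-wise 6-fold cross-validation,
  single-trial and k-averaged selections, percentile-bootstrap CIs
  (10,000 resamples), cross-condition calibration transfer, and
  repetitions-to-80% summaries with the "–" convention for
  never-reached.

The decision rule for tLDA is `w = Σ⁻¹(μ_T − μ_NT)` with the pooled
covariance averaged over equal time-lag channel blocks (block-Toeplitz
stationarity) and shrunk toward a scaled identity; a selection is
`argmax_t w·x_t + b` over one epoch per target.

## Worked example

```r
library(vsabci)

cfg <- paradigm_config(sfreq = 250, conditions = c("overt", "covert"))
ses <- simulate_session(cfg, seed = 42)
ses
#> <bci_session> 12 blocks, 914 events, 52382 samples @ 250 Hz (209.5 s), seed 42

ses    <- rereference_mastoids(bandpass(ses))
epochs <- drop_excess_repetitions(extract_epochs(ses), keep = 10)
epochs
#> <epoch_set> 720 epochs x 18 channels x 250 samples  [-0.1, 0.9) s @ 250 Hz
#>   targets: 120 / 720

blockwise_cv(epochs, "tlda", condition = "overt")
#> <selection_report> tlda / overt / single_trial
#>   accuracy 0.533  [0.400, 0.667]  (60 selections)

cross_condition_eval(epochs, "tlda")[, 1:5]
#>   train_condition test_condition accuracy ci_low ci_high
#> 1           overt          overt    0.533  0.400   0.650
#> 2           overt         covert    0.267  0.167   0.383
#> 3          covert          overt    0.283  0.183   0.400
#> 4          covert         covert    0.250  0.150   0.367
```

Reading the output: single-trial overt selection accuracy is 0.53
(chance is 1/6 ≈ 0.17; the bracket is a 95% percentile-bootstrap CI over
the 60 cross-validated selections). The cross-condition grid shows the
calibration-transfer effect this package exists to study: covert-test
accuracy is slightly *higher* when the decoder was calibrated on overt
blocks (0.267) than on covert blocks themselves (0.250), because overt
calibration data carries a larger P3.

Results are tibbles (or carry `tidy()`/`glance()` methods), and
`autoplot()` / `plot_accuracy()` / `plot_gaze_density()` /
`plot_accuracy_by_k()` produce the standard figures. A thin command-line
wrapper is installed as `exec/vsabci` (`vsabci simulate -c scenario.yaml
-o out/`, `vsabci decode -s out/session --decoder wcble`, `vsabci report
out/`).

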