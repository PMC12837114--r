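---
title: "Simulating and decoding gaze-independent visual oddball BCI sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding gaze-independent visual oddball BCI sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vsabci)
```

## The problem

Visual P300 spellers select one of several targets by detecting which
flashed stimulus elicits an attended-target response — most prominently
the P3 (P300), a broad centro-parietal positivity 300–500 ms after the
attended flash. Classical spellers assume the user fixates the attended
target (*overt* visuospatial attention, VSA). Users with combined speech,
physical and gaze impairment often cannot fixate reliably, so the
interesting regimes are *covert* VSA (gaze held at the screen center
while attending a peripheral target) and *free* VSA (uninstructed gaze).
Two things are known to change across these regimes and both drive this
package's design:

* the P3 is **smaller** under covert attention than under overt
  attention, and early **visual** components (P1/N1) are strongly driven
  by how close the gaze is to the flashed stimulus;
* the P3's **trial-to-trial latency jitter is larger** under covert
  attention, which smears the averaged response and hurts any classifier
  with a fixed temporal window.

`vsabci` provides the full experimental loop for studying this
computationally: a generative session simulator, the standard
preprocessing chain, three decoders (tLDA, xDAWN-covariance
tangent-space LDA, and the jitter-correcting WCBLE), and the evaluation
machinery (block-wise cross-validation, cross-condition calibration
transfer, bootstrap CIs, repetitions-to-threshold).

## The generative model

A session is laid out like the emulated study: six circular targets on a
regular hexagon (radius 12.28° of visual angle, target diameter 4.15°,
intensified to 5.50°), flashed for 100 ms at a stimulus-onset asynchrony
of 200 ± 50 ms (uniform), 10–15 intensifications per target drawn
uniformly per block, and one block for every (condition, cued target)
pair: 3 × 6 = 18 blocks in randomized order. We interpret the nominal
"inter-stimulus interval" as onset-to-onset spacing; that keeps the
100 ms flash non-overlapping at the minimum 150 ms gap and matches rapid
oddball pacing. Flash order is round-structured: each round is a random
permutation of the targets still owed intensifications, with no target
flashing twice in a row across a round boundary. The round structure is a
design choice (the emulated protocol only says "pseudorandom"), adopted
so that consecutive groups of six flashes always cover all six targets —
the unit we score as one *selection*. Per-target counts are redrawn in
the rare case where one target's count exceeds the runner-up's by two or
more, which would force two consecutive single-target rounds and hence an
unavoidable immediate repeat.

Each flash contributes a response that is a sum of components, each a
fixed scalp topography times a Gaussian temporal kernel (truncated at
4 SD). The defaults:

| component | modulation | topography peak | latency | width (SD) | amplitude |
|---|---|---|---|---|---|
| P1 | visual | Oz | 110 ms | 25 ms | +3 µV |
| N1 | visual | Oz/P3/P4 | 180 ms | 35 ms | −4 µV |
| P3 | attention | Pz | 400 ms | 60 ms | +5 µV |

*Visual* components occur for **every** flash and scale with
`exp(-d² / 2σ²)` where `d` is the distance between the gaze fixation
point and the flashed stimulus (σ = 6° by default). Under overt VSA this
makes the early components discriminative (the fixated target's flashes
land on the fovea); under covert VSA all six stimuli are equidistant
from fixation and the early components cancel exactly in the
target-minus-nontarget contrast. The *attention* component (P3) occurs
only for attended-target flashes; the condition profile multiplies its
amplitude and sets its latency-jitter SD. All attention components of an
event share one drawn latency shift, which is recorded as ground truth.

Default condition profiles: overt (amplitude ×1.0, jitter SD 20 ms, gaze
on the cued target), covert (×0.65, 60 ms, gaze at center), free
(×0.85, 35 ms, per-block Bernoulli(0.7) choice between target and center
fixation). The overt/covert contrast in amplitude and jitter encodes the
two findings above; the free profile's 0.7 leaning-overt mixture encodes
that users with residual gaze control tend to use it when uninstructed.

Background noise is spatially correlated, temporally colored Gaussian
noise: white innovations mixed by the Cholesky factor of a distance-decay
channel covariance `exp(-d / 0.5)` (unit-head-radius electrode
coordinates), then an AR(1) recursion with coefficient 0.97, scaled to a
stationary SD of 5 µV per channel. The default SD was fixed once so that
simulated overt single-trial selection accuracy lands mid-range (around
0.5) and covert accuracy near chance (1/6) — the operating regime such
studies typically report for mid-range participants. The simulator
does **not** model eye-movement artifacts, line noise, non-stationary
drifts, electrode pops, or inter-subject variability; passing tests show
that the algorithms behave correctly under the stated generative
assumptions, not that they will reach any particular accuracy on real
recordings.

Binocular gaze is simulated at 30 Hz: each eye is the block's fixation
point plus independent 1° Gaussian noise, with 5% per-eye dropout.

## Preprocessing

The chain mirrors standard ERP practice: zero-phase 0.5–16 Hz
Butterworth filtering (4th-order high-pass and low-pass applied
forward–backward), RANSAC bad-channel detection, re-referencing to the
mean of the mastoid channels TP9/TP10, epoching to [−0.1, 0.9) s with no
baseline correction for decoding (wider baseline-corrected epochs,
[−0.2, 1.0) s, are used only for contrast visualization), and truncation
to the first 10 intensifications per target and block.

Numerical notes. The band-pass is realized as cascaded second-order
sections: an 8th-order direct-form band-pass with a 0.5 Hz edge at EEG
sampling rates is numerically ill-conditioned (its polynomial
coefficients cancel catastrophically), while biquads keep the
forward–backward filter linear to ~1e−11. Ends are padded by odd
reflection (3/0.5 Hz = 6 s) so edge transients decay inside the pads.
Epoch windows are half-open `[onset + tmin, onset + tmax)` with the
onset sample included and 0-based sample indexing of time, so a 1 s
window at 1000 Hz has exactly 1000 samples.

RANSAC parameters (50 resamples, subsets of 25% of the other channels,
correlation threshold 0.75, bad fraction 0.4, 5 s windows) follow the
conventions of the published algorithm; flagged channels are *excluded*
from decoding rather than interpolated — interpolation would add an
unforced modeling choice, and the exclusion is recorded in the quality
report so it is auditable. Ocular artifact handling is an optional EOG
linear-regression stage (`regress_eog()`), off by default: the classical
ICA-plus-visual-inspection route is not automatable, and the simulator
lets ocular artifacts be toggled instead.

## Decoders

**tLDA** (block-Toeplitz LDA). Features are epochs cropped to
[0, 800) ms and decimated to 50 Hz by boxcar binning (the data are
already low-passed at 16 Hz, so bin means are alias-free), flattened
time-major. The pooled within-class covariance is averaged over
equal-time-lag channel blocks — enforcing the assumption that the noise
process is stationary across the epoch — and shrunk toward a scaled
identity with an analytically chosen (Ledoit–Wolf-style) intensity.
Weights solve `Σw = μ_T − μ_NT`; the bias centers scores at the
class-mean midpoint. Lag-averaging a sample covariance need not stay
positive definite; when a Cholesky check fails the spectrum is clamped
at the shrinkage ridge level. With one retained time sample the
structure is vacuous and tLDA equals ordinary shrinkage LDA — an oracle
identity the tests verify.

**xDAWN + tangent space.** Per class, xDAWN spatial filters are the
leading generalized eigenvectors of the class-evoked covariance against
the epoch noise covariance (4 filters per class). Each epoch is
augmented with the filtered class prototypes and its own filtered
signal (12 rows), its covariance floored to SPD at 1e−10 of the trace,
projected to the tangent space at the affine-invariant Riemannian mean
(fixed-point iteration, tolerance 1e−8, at most 50 iterations), and
classified with shrinkage LDA on the 78-dimensional tangent vectors.

**WCBLE** (classifier-based latency estimation with Woody iterations).
Trained on wide epochs [−100, 900) ms. Iteration 0 fits tLDA on the
nominal [0, 800) ms crop. Each Woody iteration slides the classifier
over every *target-labeled* training epoch, takes the latency of the
maximum classification score within the ±100 ms search window (earliest
latency on ties), re-cuts those epochs at their aligned windows, and
refits; non-target epochs stay at nominal alignment since they carry no
attended response to align. Iterations stop after 3 or when the mean
absolute latency change drops below 5 ms. At test time every epoch is
scored by the maximum of the sliding score over the allowed latencies —
so the WCBLE score never falls below the base classifier's score at
nominal alignment, and a zero-width search window reproduces tLDA
exactly. Latency search runs on the decimated bin grid (20 ms steps at
50 Hz features), which bounds the quantization error at half a bin.
These details (targets-only alignment, test-time max rule, iteration
caps) are this package's implementation contract; the method family is
described in the literature only loosely.

## Evaluation machinery

A *selection* is one decision: one epoch per target, scored, argmax
(ties to the lowest target index). Single-trial evaluation partitions
each truncated block into its 10 consecutive rounds; k-averaged
evaluation averages each target's first k epochs, giving one selection
per block, as in realistic multi-repetition operation. Accuracy is
estimated by 6-fold cross-validation with folds equal to stimulation
blocks, so train and test epochs never share a block. Confidence
intervals are percentile bootstrap over 10,000 resamples of the
per-selection correctness flags (for binary flags this equals a
binomial draw, which is how it is computed); the resampling unit is the
selection, not the block. Cross-condition transfer trains on 5 blocks
of condition A and tests on each block of condition B, rotating which
A block is dropped by fold index so all A data is used symmetrically
and the training size stays at 5; diagonal cells delegate to the
within-condition cross-validation. Repetitions-to-threshold reports the
smallest k whose accuracy meets the threshold (inclusive, default 0.8),
with never-reached rendered as "–".

The truncated sentence in the emulated protocol describing a selection
("6 subsequent unique") is read here as "six subsequent stimuli with
unique targets"; the round-structured schedule guarantees such groups
exist.

## Benchmark problem sizes

The packaged benchmarks (test suite and `scripts/acceptance.R`) simulate
single- or two-condition sessions at 250 Hz — paradigm timing, block
structure and all decoder mathematics are sampling-rate independent, and
50 Hz feature bins are identical either way.

Two benchmark scenarios depart deliberately from the default profiles:

* **Jitter benchmark** (WCBLE vs tLDA): covert fixation profile with
  jitter SD 60 ms vs 0 ms, P3 amplitude ×1.0, noise SD 1 µV. The purpose
  is to isolate the latency-jitter mechanism: at the default noise level
  covert decoding sits near chance, and a benchmark at the noise floor
  measures nothing — no alignment scheme can help a decoder that cannot
  see single trials. At high SNR the single-trial latency estimate
  is reliable and the comparison reflects the alignment machinery
  itself.
* **Transfer benchmark** (train overt → test covert): both profiles get
  equal jitter (30 ms) and differ only in P3 amplitude (×1.0 vs ×0.65),
  plus their gaze behavior. This isolates the amplitude mechanism by
  which overt calibration data — higher SNR for the same underlying
  response — yields better-estimated weights that transfer to covert
  operation.

## Known limitations

* The generative ERP model is a sum of Gaussian-kernel components; real
  ERPs are not Gaussian-shaped and overlap with ongoing oscillatory
  activity that is not phase-random.
* Latency jitter applies to the attention components only and is
  Gaussian; dual-task jitter in real covert operation may be skewed or
  bimodal.
* WCBLE's search window (±100 ms) clips shifts beyond it; with 60 ms
  jitter SD roughly 10% of true shifts are censored.
* Bad-channel exclusion changes the feature dimension between sessions,
  so models do not transfer across sessions with different exclusions.
* The bootstrap CI treats selections as exchangeable; selections within
  a block share a decoder fit, so coverage can be slightly optimistic on
  strongly block-correlated errors.
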