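---
title: "Methods: P300 detection and online selection in p300bmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P300 detection and online selection in p300bmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300bmi)
```

## The problem

A P300-based brain-machine interface lets a user pick one of `n_c = 6`
options — here, flexion-extension movements of a robotic hand-orthosis
(one per finger, plus all five fingers together) — by attending to one of
six circles that flash in random order. Each flash of the attended
(*target*) option evokes an event-related potential (ERP) with a positive
deflection around 300–400 ms; flashes of the other five options do not.
The pipeline's job is to label each 800 ms post-flash EEG epoch as
*target* or *non-target* and to accumulate those labels into a reliable
selection.

The package implements the complete offline chain: session containers and
I/O, preprocessing, CCA spatial filtering, stepwise-regularized LDA,
the interface controller, calibration scheduling and training, ERP
significance analysis, performance evaluation, and a synthetic-EEG
generator that stands in for recorded sessions.

## Signal chain

**Montage and epochs.** Eight channels (Fz, Cz, P3, Pz, P4, PO7, PO8, Oz)
at 256 Hz, amplitudes in microvolts throughout. Sample indexing is
0-based at the file boundary; epoch windows are half-open
`[onset, onset + n_t)` with `n_t = floor(0.8 s x 256 Hz) = 204`. The
0.8 x 256 = 204.8 product is floored — a fixed choice so every epoch has
identical shape.

**Filtering.** Three FIR band-passes: 4–14 Hz (classification band),
20–40 Hz (muscle band), 4–40 Hz (broadband). Filters are Hamming-window
linear-phase FIR of order 256 at 256 Hz. They are applied causally and
the constant group delay (`order/2` samples) is compensated by shifting,
rather than by forward-backward filtering; this keeps the offline
filtered signal identical to what a causal online implementation sees,
up to the shift. The trailing `order/2` samples of a recording are
therefore zero, which only matters for epochs placed closer than 0.5 s
to the end of a recording.

**Epoch validation.** Per channel of the broadband epoch: peak-to-peak
voltage, sample standard deviation (n−1 denominator), and the ratio of
20–40 Hz to 4–40 Hz power. An epoch is an *artifact* when any channel
reaches 200 uV peak-to-peak, 50 uV standard deviation, or power ratio
0.7, with `>=` semantics at the thresholds. A zero broadband-power
denominator (dead channel) is also an artifact: the ratio is undefined
and a flat channel indicates a disconnect, not clean data.

**Decimation.** Valid epochs are decimated by plain subsampling of the
4–14 Hz band with stride 4 and phase 0 (51 of 204 samples). No
additional anti-alias filter is applied: the 14 Hz band edge is far
below the 32 Hz post-decimation Nyquist frequency.

## CCA spatial filters

Let the artifact-free target epochs be `Y_k` (8 x 51) with average
`Ybar`. Stacking all transposed epochs into `U` and as many copies of
the transposed average into `V` (both `51 n_target x 8`), canonical
correlation analysis finds electrode weights `w` maximizing the
correlation between `U w` and the matching projection of `V` — i.e.
spatial projections of single epochs that look most like the average
ERP. The four projections with the highest canonical correlations form
the filter bank (`n_w = 4`).

Numerical choices, all of which the correlation objective leaves free:

* both blocks are column-centered before the fit (standard CCA);
* the fit is a whitened cross-covariance SVD with a relative ridge of
  1e-8 on the covariance diagonals, for stability when `V` (whose rank
  cannot exceed the channel count) is nearly degenerate;
* each weight vector is scaled to unit norm with its largest-magnitude
  entry positive, so fits are deterministic and projections scale with
  the input;
* equal correlations are ordered by filter index.

Tests verify the correlations against two independent routes: a
brute-force generalized eigenproblem on the covariance blocks, and
`stats::cancor`.

## Classification

Features are the `4 x 51` spatially filtered samples, flattened
filter-major (feature `(j-1) * 51 + k` is filter `j` at time `k`).

**RLDA.** Two-class linear discriminant with the pooled covariance
shrunk toward the scaled identity,
`C(gamma) = (1 - gamma) C + gamma mean(diag(C)) I`. The shrinkage
intensity is re-estimated at every fit with an analytic Ledoit-Wolf-style
formula computed from the pooled centered second and fourth moments
(`gamma = "auto"`, overridable). The decision rule uses **equal class
priors**: the calibration set is 1:5 unbalanced (264 target vs 1,320
non-target epochs), and a prior-weighted rule would push the boundary
toward never answering *target*; the weighted accuracy
`0.5 (acc_t + acc_nt)` used for model assessment corresponds to the
equal-prior rule.

**Stepwise selection.** Forward-backward selection over the 204
candidates: add the candidate that maximizes the scoring criterion if it
improves it by more than `eps`; remove any included feature whose removal
costs at most `eps`; stop when neither step changes the set. The scoring
criterion — which the underlying procedure leaves open — is 5-fold
cross-validated weighted accuracy with `eps = 0.001`, a cap of 60
features, a fixed internal fold seed (so selection is a deterministic
function of the data), and ties broken toward the lowest feature id.
Scoring slices precomputed per-fold moment matrices, so a full
calibration-size selection runs in seconds. An input on which no single
feature beats the empty model (chance, 0.5) raises an error rather than
returning an arbitrary classifier.

## Interface controller

Per option, a ring buffer keeps the last 10 artifact-free labels
(artifacts only increment a discard counter). After each valid label the
controller selects option `o` iff

1. `o` has at least 5 buffered labels,
2. at least 70% of them are *target*, and
3. every other option with at least one buffered label is *non-target*
   at least 60% of the time.

Options with empty buffers cannot veto (early in an attempt most options
have no valid epochs yet; the rule counts only classified responses).
Because 70% + 60% > 100%, at most one option can satisfy the conditions
at any time — verified exhaustively in the tests. After a selection all
buffers reset and flashing pauses 4 s while the orthosis moves. An
attempt times out after 30 s of flashing; rest between attempts is 5 s.

## Calibration sessions

Eight cued runs; per run 33 rounds in which each option flashes exactly
once in random order at a 150 ms cycle (75 ms face icon + 75 ms blank).
Balanced per-round randomization is the only scheduling consistent with
the fixed totals of 264 target and 1,320 non-target epochs; round
permutations are redrawn when an option would flash twice in a row
across a round boundary. Flashing occupies 198 x 0.15 = 29.7 s per run;
fixation (3 s), cue (2 s), preparation (2 s) and rest (3.3 s) — a
breakdown not fixed by the total, chosen here — pad each run to 40 s and
the session to 320 s. Cued targets are drawn uniformly per run
(`balanced_targets` draws them without replacement instead). Training
requires at least 20 valid target epochs; below that the average ERP is
too noisy to anchor the CCA fit.

## ERP significance

ERP analysis uses the broadband signal with 200 ms pre- and 800 ms
post-stimulus samples (51 + 204 points). Per channel, the class average
is baseline-corrected by its pre-stimulus mean; the baseline amplitude
distribution is then estimated from the averaged waveform's own 51
pre-stimulus samples by Gaussian-kernel density estimation
(normal-reference bandwidth, configurable multiplier), and a
post-stimulus point is flagged (+/−) when the averaged amplitude falls
outside the `alpha/2` / `1 - alpha/2` quantiles of that estimated
distribution (`alpha = 0.05`, two-tailed).

Taking the baseline from the *average's* pre-stimulus interval (rather
than pooling single-epoch baselines) makes the test computable from an
average alone and matches the per-channel display convention; the
pooled alternative would widen the band by the single-epoch variance and
is deliberately not the default. With 51 baseline samples the KDE band
is slightly conservative (the smoothing inflates the quantiles by a few
percent), which Monte-Carlo level checks in the test suite confirm:
the empirical flag rate under the null sits near 0.04 for nominal 0.05.

## Evaluation

* **Cross-validation**: stratified 5-fold; the *entire* stepwise + RLDA
  stage is refit inside every training fold; held-out predictions are
  pooled into per-class accuracies and
  `acc_w = 0.5 (acc_target + acc_nontarget)`.
* **Permutation test**: labels are permuted `m` times, the cross-validated
  pipeline re-scored, and `p = (1 + #{permuted >= observed}) / (1 + m)`
  — the smoothed estimator, so p is never exactly zero. The study-scale
  default is 10,000 permutations; tests and examples use smaller `m`.
* **Online metrics**: accuracy `100 n_sel / n_att` over attempts
  (timeouts and wrong selections are failures); bits per selection
  `B = log2 n_c + acc log2 acc + (1 - acc) log2((1 - acc) / (n_c - 1))`
  with `0 log 0 = 0` at both ends; `ITR = 60 B / t_avg` bit/min. The
  average selection time is taken over correct selections only —
  timeouts have no selection time — and is measured from flashing start
  to the deciding epoch's completion.
* **Condition contrasts**: two-sided paired t-tests (reported as
  `t`, `df = n - 1`, `p`) for within-subject comparisons, Wilcoxon rank
  sum for group comparisons. Identical paired samples return `t = 0`,
  `p = 1` rather than an error.

The package bundles the study's published per-subject benchmark tables
(cross-validated accuracies; online accuracy, selection time and ITR
with and without the orthosis). The test suite recomputes from them the
printed summary statistics, the ITR column from its accuracy/time
inputs, and the orthosis contrasts (selection times slow by ~1.6 s when
the device is worn, `t = -3.67`, `df = 21`).

## The synthetic-EEG generator

The generator emulates the statistical structure the pipeline assumes,
not any particular subject:

* **Background**: per-channel Gaussian noise with a `1/f` amplitude
  spectrum (exponent 1), a 10 Hz alpha bump (relative gain 0.5), and
  inter-channel correlation 0.3, scaled to 4 uV standard deviation.
  The default level emulates a low-noise recording of an attentive
  subject — the upper end of the benchmark range (best subject ~96%
  cross-validated accuracy), so that the default conditions exercise the
  pipeline at high signal-to-noise ratio; weaker subjects are emulated by
  raising `noise_sd` or lowering `erp_amplitude`.
* **Evoked response**: at every target-flash onset, a Gaussian-windowed
  positive deflection (5 uV, 350 ms latency, 120 ms FWHM) with a
  centro-parietal topography, plus an early negativity (2.5 uV, 220 ms)
  weighted toward parieto-occipital channels.
* **Artifacts**: Poisson-scheduled bursts (2 per minute) shaped as a
  30 Hz tone under a raised-cosine envelope, peak 300 uV, 200 ms. The
  in-band carrier matters: a smooth 300 uV pulse of the same envelope is
  essentially a 5 Hz transient that the 4–40 Hz filter attenuates below
  every rejection threshold, so it would corrupt epochs invisibly. With
  the EMG-band tone, a burst trips both the peak-to-peak and the
  power-ratio rules, and the ground truth (envelope >= 100 uV inside the
  window, the level at which in-band peak-to-peak reaches 200 uV) agrees
  with the validator on >99% of epochs.
* **Reproducibility**: all randomness derives from one session seed
  through named substreams (schedule, noise, artifacts).

What the generator does **not** model: eye-blink and EMG waveform
morphology, non-stationary background (drowsiness, electrode drift),
latency jitter of the evoked response across trials, and volume-conduction
topographies beyond fixed per-channel gains. Passing tests therefore
show that the chain recovers the structure it assumes at realistic
amplitudes and rejects matched artifacts — not that it handles every
pathology of real recordings.

## Problem sizes used in the checks

Deterministic quantities (ITR values, benchmark statistics, schedule
counts) are computed at full scale. Monte-Carlo checks use sizes chosen
to keep the whole suite in a few minutes while leaving comfortable
margins: full 320 s calibration sessions where the published epoch
counts matter; reduced sessions (4 runs x 15 rounds) for
amplitude-recovery and null-calibration sweeps; 20–60 online attempts
for end-to-end accuracy; 19–199 permutations for permutation-test
behavior (10,000 remains the study-scale default).

## Known limitations

* EDF input is not implemented; sessions are CSV/TSV/JSON bundles (an
  extension point is left for binary formats).
* The stepwise scoring criterion and the shrinkage-intensity estimator
  are reasoned reconstructions: the procedure they instantiate leaves
  both open, and different choices (AIC-style criteria, fixed gamma)
  would select slightly different feature sets.
* The controller's timing model is event-driven: epoch labels arrive at
  onset + 800 ms, and phase durations are idealized constants.
* Under the null (no evoked response) the evidence thresholds make
  timeouts, not random selections, the dominant outcome — so online
  "chance level" manifests as near-zero selections rather than 1-in-6
  correct guesses.
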