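---
title: "Grasp decoding and force estimation from surface EMG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grasp decoding and force estimation from surface EMG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myoelectric prosthesis control needs two things from the surface EMG of
the residual limb: *which* grasp the user intends, and *how hard* they
intend to squeeze. This package implements an offline pipeline for both
over four natural grasping movements — pinch, palmar (whole-hand)
grasp, twist, and plug grasp — recorded from eight electrode sites
(C1–C8, forearm and upper arm) at 2000 Hz together with a force channel
and a synchronization trigger.

Two study designs are covered:

* **Classification.** Each 13 s trial is 7 s rest, 0.5 s reach, a 1.5 s
  force ramp and a 4 s hold at one of three levels (20/50/80 % of the
  movement's maximum voluntary contraction, MVC). Five labeling schemes
  (SCH1–SCH5) combine movement and force level into 4-, 8- or 12-class
  problems.
* **Force estimation.** The subject tracks one of four target force
  profiles — rectangular (2 s plateaus at 20/50/80 %MVC), triangular
  (0→80→0 %MVC over 5 s), step-climbing (a staircase to 80 %MVC in
  8.5 s) and a seeded random polyline bounded by 80 %MVC — and a
  regressor reconstructs the continuous force from the EMG.

No public recordings accompany the study design, so the package ships a
synthetic session generator with the statistical structure the analysis
assumes; every downstream stage is exercised against it.

## Generative model for synthetic sessions

EMG channel $c$ during movement $m$ is amplitude-modulated band-limited
Gaussian noise, the standard sEMG surrogate:

$$x_c(t) = g_{cm}\,\bigl(f_a(t)/100\bigr)^{\alpha} n_c(t) + b\,e_c(t),$$

where $n_c, e_c$ are independent unit-variance Gaussian processes
band-limited to 20–450 Hz, $g$ is an 8×4 channel-by-movement gain
matrix, $b$ the baseline (rest) noise amplitude (default 0.02 in the
gain's amplitude units), and $\alpha$ (default 1) the amplitude–force
exponent. Measured force is the target profile scaled by the movement's
MVC plus Gaussian sensor noise (default σ = 0.5 %MVC).

Two mechanisms couple the EMG envelope and the measured force
imperfectly, and both matter for the regression results:

* **Electromechanical delay** (default 30 ms): force lags the EMG
  envelope, as muscle tension builds after activation.
* **Overshoot ringing** (default fraction 0.3, threshold 60 %MVC/s):
  when the target jumps faster than a muscle can track smoothly, the
  executed force overshoots by a fraction of the jump and rings down as
  a decaying ~1.5 Hz oscillation. The ringing is part of the *force
  response*, not of the neural drive, so it is invisible in the EMG.

The second mechanism is what makes profile shape matter: the triangular
ramp (32 %MVC/s) stays below the threshold and regresses almost
perfectly, while the rectangular profile's 80–320 %MVC/s transitions
excite ringing that no memoryless EMG feature can predict. This
reproduces the qualitative finding that slowly applied force is easier
to estimate than jumped force. We considered instead perturbing the EMG
envelope in proportion to the force slope ("noisy drive during
transients"), but that penalizes the all-ramp triangle more than the
mostly-plateau rectangle and inverts the effect; the force-side ringing
is the mechanism consistent with the observed ordering.

The `"paperlike"` gain preset encodes the ordinal channel–movement
coupling structure reported for these grasps (C2–C5 informative for all
movements; C7/C8 nearly silent for pinch; C7 strongly recruited by
plug; C6 weak for plug), with gain values chosen so the four movements
remain separable in channel-pattern space — the reported 91–97 %
accuracies imply such separability. The preset is *not* a quantitative
reconstruction: the published per-channel statistics are correlation
percentages, not amplitude gains.

What the generator does **not** emulate: motor-unit recruitment and
firing statistics, electrode crosstalk, fatigue drift, and
between-subject variability. Tests passing on synthetic sessions
therefore validate the pipeline's arithmetic, bookkeeping and
statistical machinery — not the claim that real EMG of these grasps is
this separable.

One timing conflict is resolved in the generator's favor of the stated
13 s total: the 8.5 s staircase cannot follow 7 s rest + 0.5 s reach
inside 13 s, so the rest period shrinks per profile
(rest = 13 − 0.5 − duration); the 5–5.5 s profiles keep exactly 7 s
rest.

## Preprocessing

EMG is filtered zero-phase (forward–backward) with a sixth-order
Butterworth band-pass, realized as cascaded high-pass (10 Hz) and
low-pass (500 Hz) sections so each edge keeps full roll-off, plus an
RBJ biquad notch at 50 Hz (Q = 30). Zero-phase filtering is chosen
because the analysis is offline and EMG–force alignment must be
preserved. The binding contract (asserted in tests): ≥ 20 dB
attenuation at 50 Hz and at 2 Hz, 100 Hz passed within 10 %.

Trigger pulses (50 ms, amplitude 1) mark trial onsets; detection takes
the leading supra-threshold edge (threshold 0.5) and merges edges
closer than 100 ms. Trials are cut to exactly 13 s from each onset,
and force is normalized to %MVC by the per-movement MVC reference (the
mean of three maximal-effort maxima).

The classification analysis window defaults to 10–13 s. The paradigm's
hold phase nominally starts at 9 s, but the explicit analysis statement
is 10–13 s; the window is configurable.

## Features and learners

Windows slide at 175/20 ms (classification) and 200/80 ms (regression);
a signal of $L$ samples yields $\lfloor (L-W)/S \rfloor + 1$ full
windows. Five time-domain features per channel and window: MAV, RMS,
VAR (unbiased, mean-subtracted — EMG is near zero-mean so the
mean-subtraction choice is benign), WAMP and WL. The WAMP threshold is
nowhere standardized; the default is adaptive, 2 × MAD of the trial's
rest-phase signal per channel, making the count scale-free across gain
settings; a fixed override exists. Columns are ordered channel-major
("C1_mav" … "C8_wl") for reproducibility.

The classifier is an RBF-kernel SVM (C = 1, γ = 1/n_features; the
study names SVM without hyperparameters), scored by 5-fold
cross-validation. Folds are assigned at the **trial** level, stratified
by class: windows of one trial overlap heavily (175/20 ms), so
window-level folds would leak test information into training.
Features are z-scored with statistics fitted on training folds only.
Accuracy is per-window, averaged over folds; whether the original
analysis scored per window or per trial (majority vote) is not
determinable from the text, and per-window is assumed.

The force regressor is a single-hidden-layer feed-forward network
(20 units, back-propagation training via `nnet`, linear output,
weight decay 10⁻³, ≤ 300 iterations; features z-scored, target scaled
to [0, 1]). The regression target is the window-mean force, and
performance is the coefficient of determination
$R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ on held-out trials
(75/25 trial-wise splits, repeated 5 times; the mean ± sd across
repeats mirrors a per-subject mean ± sd report). Reported predictions
are clipped to [0, 120] %MVC; raw values are retained.

## Channel analyses

* **Channel scan (classification).** Every channel subset of each size
  1–8 is scored by cross-validated accuracy (or a seeded random sample
  of subsets under a budget — the budgeted mode is labeled in the
  result). Per-size means give the increase of rate,
  IR$_n$ = acc$_n$ − acc$_{n-1}$, which telescopes to
  acc$_8$ − acc$_1$.
* **Correlation table (regression).** Per trial, the windowed RMS
  envelope of each channel is correlated with the window-mean force
  over the active phase; the table reports |Pearson r|×100 mean ± sd
  across trials per movement × channel. The published statistic behind
  this table is not defined in the text; |Pearson r| of the RMS
  envelope is this package's interpretation, flagged as such.
* **Selection.** `top_k` takes the k highest-mean channels (ties to
  the lower index); `preset` returns the study's fixed per-movement
  four-channel subsets (pinch C1 C2 C3 C5; palmar C2 C4 C5 C6; twist
  C1 C2 C3 C4; plug C2 C4 C5 C7).

One generator-specific caveat: because the per-window RMS estimator is
precise (≈ 3.5 % relative error at 200 ms windows) and baseline noise
is low, *any* nonzero gain yields a near-perfect envelope–force
correlation; graded correlation values like those seen in real
recordings arise here only between informative and truly silent
channels. Top-k selection on the default preset therefore
discriminates sharply against zero-gain channels but near-arbitrarily
among nonzero ones.

## Numerical and design choices

* Determinism: every stochastic step takes a seed; per-trial seeds are
  derived from the session seed by a fixed integer recurrence, so any
  report bundle regenerates byte-identically from (config, seed).
* Degenerate inputs: single-class label sets score 100 % with a
  warning; constant regression references give NaN R² with a warning;
  empty windows, inverted phase windows, band edges at or above
  Nyquist, non-positive MVC maxima and missing level annotations are
  rejected with messages.
* MVC defaults (palmar 100 N, pinch 30 N, twist/plug 20 N) are
  arbitrary scale constants; only %MVC matters downstream.
* The staircase geometry (four 20 %MVC steps joined by 0.5 s ramps)
  and the random profile (six-knot polyline) are fixed desk choices
  where only total durations and the 80 %MVC bound are specified.

## Problem sizes

Tests and the acceptance script run the full design *structure* at
reduced counts — typically 5 trials per movement × level
(classification) and 8–20 per movement × profile (regression) against
the study's 50/20 — and a 100 ms scan step for the budgeted full-size
channel scan. These sizes are the package's own desk-scale choice; the
generator's defaults keep the full counts.

## Interface note

The package is organized as an analysis workflow: `analysis/01–03`
scripts narrate the three stages over the exported functions, and
`run_experiment_1()` / `run_experiment_2()` orchestrate complete,
config-reproducible runs. No shell command-line tool is shipped; the
functions and scripts are the interface.

## Known limitations

Synthetic EMG only (no deposited recordings to replay); no artifact or
crosstalk modeling; no online/streaming path; classifier and regressor
hyperparameters are sensible defaults, not tuned per dataset; the
correlation statistic and the per-window scoring are interpretations
where the source text is silent.
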