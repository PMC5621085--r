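---
title: "Adaptive locomotion-mode recognition: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive locomotion-mode recognition: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A powered lower-limb prosthesis must know which ambulation task its user is
performing — level walking (W), ramp ascent/descent (RA/RD), stair
ascent/descent (SA/SD) — to select the right impedance parameters. A
locomotion-mode-recognition (LMR) system infers the task from surface EMG of
thigh muscles fused with load-cell forces and moments from the pylon. The
difficulty is that EMG is nonstationary: electrode shift, skin impedance,
temperature, moisture and the user's own motor adaptation all move the
feature distribution between and within sessions, so a classifier trained
once degrades over time (concept drift).

`lmradapt` implements the full recognition pipeline and three *unsupervised*
adaptation strategies that retrain the classifier from its own test-time
decisions, plus a synthetic gait-signal simulator that stands in for
human-subject recordings (none are publicly deposited for this class of
experiment) and reproduces the two canonical stress tests: slow gradual
drift across trials, and an abrupt mid-session shift (socket don/doff and
temperature change during a break).

## Recognition pipeline

Signals are 7 EMG channels plus 6 mechanical channels sampled at 1000 Hz.
A sliding analysis window of 160 ms advances by 20 ms; each window's gait
phase and true mode are attributed to its final sample (the causal choice —
a controller only knows the present). Within each window the EMG is
band-passed with a 20–420 Hz eighth-order Butterworth filter applied
forward, per window, with zero initial conditions; the start-up transient
this leaves in the first samples is accepted and identical across training
and testing, so it is absorbed by the classifier.

Per EMG channel four time-domain features are computed on the filtered
samples: mean absolute value, waveform length, slope-sign changes and zero
crossings. The two counting features use an amplitude dead zone; the
package's default dead zone is 1% of each channel's training-set standard
deviation (`deadzone_from_trials()`), a classical noise-robust choice that
the user can override, since the counting thresholds of the original
front-end are not published. Per mechanical channel the window maximum,
minimum, mean and standard deviation (population convention, divisor *n*)
are taken from the raw samples. Fusion concatenates EMG-first:
`emg1_mav … emg7_zc`, then `mech1_max … mech6_std` — 52 dimensions.

The gait cycle is divided into five controller phases (by the simulator's
convention, 1–3 stance with phase 2 the single-stance phase, 4–5 swing),
and each phase has its own classifier: a one-against-all (OAA) bank of five
binary RBF-kernel support-vector machines over standardized features.
Per-feature standardization uses the phase's training mean and population
standard deviation; constant features pass through with scale 1 and are
flagged. `(C, γ)` are selected per phase by stratified cross-validated OAA
accuracy on a coarse log-spaced grid (3 × 3 by default, configurable); the
search runs once on the initial training session and the winning pair is
frozen for all subsequent retrains.

Each binary margin is mapped to a probability with a Platt sigmoid and the
five per-class scores are renormalized to a posterior — the simplest
coupling consistent with the OAA structure. By default the sigmoids are fit
on training-set margins using Platt's prior-corrected targets
`t+ = (N+ + 1)/(N+ + 2)`, `t− = 1/(N− + 2)`, which bound the fit away from
degeneracy on separable data; `search_spec(calib = "holdout")` instead fits
them on margins from a stratified 30% held-out split at the cost of an
extra round of machine fits per phase. The decision is the posterior
argmax; a majority vote over the trailing five decisions of the trial
(window shrinking at the trial start, ties broken toward the most recent
raw label) produces the reported label. The vote length is not a published
constant; five decisions is the package default and is configurable.

Decision confidence is the Shannon entropy of the posterior,
`E = −Σ p_k ln p_k` (nats), zero for a certain decision and `ln 5 ≈ 1.61`
at the uniform distribution.

## The three adaptation strategies

All three run trial-by-trial: trial *k* is always classified with the bank
as retrained after trial *k − 1*; selection and retraining happen only
after a full trial, never mid-trial. Pseudo-labels always come from
pre-vote raw labels (voting mixes phases and adds latency), and every
selected window is routed to the classifier of its own gait phase. The
augmented set is unlimited by default; an optional per-phase cap with FIFO
eviction is available.

* **Entropy-based adaptation (EBA)** keeps exactly the windows with
  `E < τ`, with `τ = 0.6` nats. The boundary is strict (`<`); windows at
  exactly the threshold are not selected.
* **LIFT** thresholds each binary machine's calibrated score at 1/2 and
  keeps a window iff *exactly one* machine claims it, labeling it with
  that machine's mode.
* **Transductive SVM (TSVM)** updates each binary hyperplane directly: in
  each iteration, among unlabeled windows with signed decision value
  strictly inside (0, 1) on either side, the up-to-`m = 5` per side closest
  to 1 are moved into the labeled set with their side as label and the
  machine is refit; the loop ends when no point is inside the margin or
  none remain, and leftovers are assigned by sign. Only the *moved*
  (selected transductive) windows join the permanent training set; the
  sign-assigned leftovers receive a label but are not retained — they never
  influenced the hyperplane and retaining them would just replay the
  current boundary. After the five binary problems of a phase are updated,
  the sigmoids are refit on the updated margins (the margin scale changes
  with the support set) and the window's multiclass label is the posterior
  argmax.

Retraining refits, per phase, the standardizer, the five machines and the
calibrators on base ∪ augmented data with the frozen hyperparameters.
Everything is deterministic given the seeds carried in the configuration
objects; no global RNG state is consumed.

## The synthetic gait simulator

No recordings accompany the experimental design this package emulates, so
the simulator is a first-class, tested component. It emulates:

* **EMG**: per (mode, phase, channel) activation envelopes multiplying a
  band-limited (20–400 Hz) unit-variance Gaussian carrier, plus a white
  baseline noise floor. Envelopes are a shared per-(phase, channel)
  activation pattern times `1 + mode_separation × deviation`; the five
  mode-deviation patterns are drawn once per seed and *orthonormalized*
  across modes, so the classes are pairwise separable in expectation for
  every seed rather than by luck of the draw.
* **Mechanics**: per-channel load profiles (offset plus two phase-locked
  harmonics of the gait cycle) with mode deviations of the same relative
  scale, white measurement noise, and per-cycle amplitude variability.
* **Gait structure**: five phases per cycle with ±10% per-cycle duration
  jitter; stride-to-stride log-normal amplitude variability (s.d. 0.1) on
  every channel; the task sequence W→SA→W→SD→W→RA→W→RD→W with three gait
  cycles per segment, giving the 8 mode transitions of the protocol. Mode
  changes occur at phase-1 onsets (foot contact), so transitional periods
  are well defined.
* **Drift**: a gradual schedule (per-channel amplitude drift with a
  persistent direction and ±20% jitter, growing baseline noise, a slow
  downward shift of the carrier's upper corner, creeping mechanical
  biases), and an abrupt schedule (identity before the break; at the break
  a step of baseline noise ×1.6, spectral −0.12 and fixed-size
  random-direction amplitude/bias flips; mild gradual drift afterwards,
  since a re-donned socket keeps settling).

### Operating point and time base

The defaults put a freshly trained bank in the mid-90s static accuracy
regime without drift, falling to the low-to-mid 80s after ten
gradual-drift trials — the qualitative operating range of real
phase-dependent LMR systems. Two deliberate compressions keep a full
multi-seed experiment campaign tractable on a laptop:

* **Cycle duration** is 400 ms (5 × 80 ms phases) instead of a
  physiological ~1.1 s. All windowing constants stay at their standard
  values (160 ms window, 20 ms increment), so a window spans exactly two
  phases and a cycle yields 20 decisions.
* **Trial length** is 9 segments × 3 cycles ≈ 11 s. Three cycles per
  segment matters: with shorter segments the transitional periods dominate
  the trial, and self-training then feeds mostly on windows whose labels
  are ambiguous by definition — a failure mode the emulated protocol
  (walkway, ramp and stair bouts several strides long) does not have.

One constant is deliberately *not* taken literally: the online increment of
the emulated system (50 ms, up from 20 ms, for real-time processing
headroom). What governs voting and retraining economics is decisions per
gait cycle; 50 ms at a physiological cycle is ~4.5% of a cycle, which at
the compressed cycle corresponds to ~20 ms. The Part-2 harness therefore
defaults to the same 20 ms increment as Part 1, and `increment_ms = 50`
reproduces the literal value (at that setting the adaptive arm accumulates
too few retraining windows per compressed trial to recover reliably —
measurably, recovery then succeeds in only about half the seeds).

What the simulator does **not** model — and hence what passing its tests
does not establish about real data: physiological EMG generation
(motor-unit recruitment, inter-muscle correlation), crosstalk, load-cell
dynamics and kinematic coupling, fatigue trends within a trial, label noise
in the controller's phase/mode annotations, and any systematic difference
between able-bodied and amputee signal statistics.

## Evaluation

A **transitional period** starts at the foot contact where the mode
changes and ends when single stance (phase 2) of the *following* gait
cycle ends — one full cycle plus two stance phases. Windows whose decision
timestamp falls inside any period are transitional; the rest are static.
**Static accuracy** is the percentage of static windows whose voted label
matches the true mode. A **missed transition** is a period whose last
window (by decision timestamp) is not voted as the new mode; with 8
transitions per trial and 10 testing trials the session denominator is 80.
Part 2 additionally reports an **instability proxy**: runs of at least one
full vote window of consecutive wrong voted decisions during static-state
stance in SD or RD — the situations where a wrong impedance set would
destabilise a user. It is a proxy for human-reported stability events, not
that measure.

`run_part1_experiment()` generates one session (3 training repetitions, 10
testing trials under gradual drift), trains one bank, and runs all four
strategies on identical trials. `run_part2_experiment()` interleaves 10
adaptive (EBA) and 10 non-adaptive trials with the abrupt step at overall
trial 11 (each arm's trial 6); the non-adaptive arm never retrains, the
adaptive arm retrains only from its own trials.

## Numerical and degenerate-input choices

* Standardization: population variance; constant features flagged, scale 1.
* Entropy: `0 · ln 0 ≡ 0`; posteriors validated non-negative, sum within
  1e-6 of one; per-binary sigmoid scores floored at 1e-12 before
  renormalization.
* Posterior argmax ties resolve to the first mode in (W, RA, RD, SA, SD)
  order; vote ties resolve to the most recent raw label.
* Decision values are computed directly from the support vectors
  (`K · coef − ρ`, one BLAS call), asserted equal to the fitting library's
  predictions in the test suite, and orientation-normalized so a positive
  margin always means "this mode" regardless of class encounter order.
* Grid-search ties resolve to the first grid entry; the toy grids in the
  tests use a single point, which skips the search entirely.
* TSVM iteration caps at `max_iter` (default 200) and flags
  non-convergence; the batch rule guarantees at most `⌈n_u / 1⌉` iterations
  regardless.
* libsvm termination tolerance defaults to 0.01 across the package
  (classification margins are O(1); the looser tolerance is far below the
  feature noise floor).

## Problem sizes used by the test suite

The acceptance properties run the full study conditions at 10 seeds:
10-trial gradual sessions for the drift properties, 6-trial stationary
sessions for the no-drift safety property (stationary trials are
exchangeable, and self-poisoning — the failure the property guards against
— compounds per retrain, so six retrain cycles are ample to expose it),
and the 20-trial Part-2 design for step recovery. Unit tests use toy
separable sets and two-cycle trials.

## Known limitations

* The simulator's drift magnitudes are calibrated to the qualitative
  published behaviour of such systems (no quantitative drift measurements
  exist to fit); absolute accuracies should not be read as predictions for
  any real device.
* Gait-phase labels are taken from the simulator's ground truth, standing
  in for the prosthesis controller's state machine; phase estimation from
  signals is out of scope.
* EBA inherits the classic self-training risk: confidently wrong decisions
  (e.g., immediately after a severe distribution shift) enter the training
  set. The package reproduces both the benefit and, under extreme steps,
  the failure — the latter is visible by raising the abrupt step
  magnitudes.
* The LDA baseline and supervised adaptation variants of the surrounding
  literature are not implemented.
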