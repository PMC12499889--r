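---
title: "Voltage-matrix profiling of nanopore translocation signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-matrix profiling of nanopore translocation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Solid-state nanopore sensing records the ionic current through a single
~10 nm pore while an applied voltage drives analyte molecules through it.
Each translocation transiently perturbs the open-pore current `I0`, leaving a
short blockade whose depth, duration and shape reflect the molecule's size,
charge and conformation. Classifiers trained on event features can
discriminate protein species — but translocation signals are highly sensitive
to the applied voltage, and a model trained under one bias condition may fail
silently under another, or worse, succeed for the wrong reason by reading the
acquisition condition instead of the molecule.

`voltmatrix` implements the voltage-matrix idea: acquire (here: simulate)
events under a grid of voltages, train a binary classifier at each voltage,
evaluate it at every voltage, and lay the AUCs out as a train-voltage ×
test-voltage matrix. The diagonal measures within-condition performance; the
off-diagonal measures cross-condition generalization. Three diagnostic
patterns matter:

* high everywhere — the classifier uses voltage-invariant molecular
  features (size/shape-like analytes);
* high diagonal, decaying off-diagonal — the analyte's signature itself is
  voltage-sensitive (e.g. an aptamer-protein complex whose conformation
  responds to the field);
* perfect diagonal with collapsing off-diagonal — the classifier has
  latched onto baseline features of the acquisition condition rather than
  the molecule (overfitting diagnosis).

## The simulator

All study conditions are generated by `simulate_trace()` /
`simulate_events()` from a `simulation_config()`:

* Baseline: `G·V` pA (G = 10 nS default) plus a per-run offset
  (N(0, 25 pA) or fixed per class), a slow linear drift (0.5 pA/s) and white
  Gaussian noise (12 pA RMS).
* Capture: per-class Poisson arrivals at the barrier-limited rate
  λ(V) = α·|V|·exp(−V*/|V|). The two default analytes use
  (α = 0.046, V* = 61.6 mV) and (α = 0.020, V* = 20 mV), the unique pair
  solving the two anchor conditions "equal rates at −50 mV" and "two-fold
  ratio at −300 mV".
* Events: rectangular depressions of depth `f·|I0,local|` with exponential
  edges (τ = 20 µs), where the fractional blockage `f` is Gaussian per class
  and the dwell is log-normal with median scaling as `(100/|V|)^γ`.
  Overlapping arrivals are rejected and redrawn (the analysis chain assumes
  isolated events); an impossible load raises a saturation error rather than
  degrading silently.
* Determinism: every trace is a pure function of (config, voltage, run,
  seed); derived seeds stay below 2^31.

Depth is proportional to the *local* baseline (including the run offset), so
relative features such as `ΔI/|I0|` are invariant to run offsets, which is
what makes the baseline-overfitting demonstration meaningful. When offsets,
drift and edge τ are zero, depth equals `f·|G·V|` exactly; the tests use this
to pin the depth law to float precision.

Dwell/blockage distribution parameters are package defaults chosen to give
realistic desk-scale data (sub-ms to few-ms dwells, 10–30% blockages); they
are config fields, not constants. The sampling rate (100 kHz) and the absence
of an explicit acquisition low-pass filter are simplifying assumptions: noise
is white, and event censoring by filtering is not modeled.

What the simulator does *not* emulate about real recordings: 1/f and
capacitive noise, clogging and gating artifacts, pore-to-pore geometry
variation, intra-event substates, and analyte interactions in mixtures.
Passing tests therefore demonstrate that the analysis chain is correct and
well-calibrated under its stated stochastic model — not that any particular
laboratory system behaves this way.

## Event detection

`detect_events()` is a two-threshold (Schmitt-trigger) detector over a
moving-median baseline: an event opens when the current deviates from
baseline by more than `threshold_k`·RMS (default 5) toward the blockade side
and extends until the deviation falls below `exit_k`·RMS (default 2);
candidates shorter than 5 samples are dropped and candidates closer than 5
samples are merged. The baseline is a two-pass moving median (50 ms window):
the first pass flags candidate event spans, which are replaced before the
second pass so long blockades do not drag the baseline. For speed the median
is evaluated on a strided grid (window/10) from subsampled blocks and
interpolated; since the baseline varies only through slow drift this is
numerically indistinguishable from the per-sample median at ~50× less cost.
RMS is estimated robustly (MAD, then SD of out-of-event residuals), and the
drift slope by least squares on the baseline. An absolute threshold floor
(10⁻⁸·|median|) keeps zero-noise synthetic traces from triggering on float
dust.

`ΔI` is reported both as the mean depth over the event core (`delta_i_pa`,
used for fractional blockage) and as the extremum (`delta_i_max_pa`), since
the field uses both conventions. Indices are 0-based half-open throughout.

## Feature sets A and B

`default_feature_sets()` returns the two specifications:

* **Set A** (event-intrinsic): dwell; fractional blockage `ΔI/|I0|`;
  normalized area (charge deficit / `|I0|`); skewness; excess kurtosis;
  FWHM/dwell; intra-event SD / mean depth.
* **Set B**: A plus the baseline-dependent features — absolute `ΔI` (mean
  and max), local `I0`, baseline RMS, drift slope.

A caveat discovered while validating the package and worth stating plainly:
with additive instrument noise of fixed RMS, any feature that normalizes an
absolute noise quantity by the signal depth (the SD/depth ratio, and more
weakly the shape moments) implicitly encodes the signal-to-noise ratio and
hence `|I0|`. Set A is therefore only *approximately* baseline-agnostic: when
two conditions differ by a baseline offset that is a sizeable fraction of
`|I0|` (±40 pA on a 500 pA baseline at −50 mV), a large-sample Random Forest
can still detect the difference through these members (diagonal AUC ≈ 0.84 in
the baseline-overfit demonstration at −50 mV, chance level at −150 mV and
beyond). The strictly offset-invariant members are dwell, fractional blockage
and normalized area, and the invariance test asserts exactly those. We kept
the conventional member list rather than pruning it, because the same
coupling exists in real recordings and pretending otherwise would overstate
what "baseline-free" feature engineering can do.

## The voltage matrix

`build_voltage_matrix()` splits each voltage's labeled events 70/30
(stratified, seeded), trains one classifier per voltage on its training
split, and evaluates every (train, test) pair on the *held-out* split of the
test voltage — the diagonal uses the same protocol as the off-diagonal, so
cells are comparable. Random Forest uses 500 trees and √p features per
split on raw features; the SVM uses an RBF kernel with Platt-style
probability calibration on features standardized by training-set statistics.
Both are seeded; per-voltage seeds derive from the voltage value so the
matrix is invariant to the ordering of the voltage list. AUC is computed by
the Mann–Whitney rank statistic (ties half-credited), which the tests pin
against an exhaustive pair-counting oracle.

Feature importance is measured by permutation (mean AUC drop over repeated
column permutations of the evaluation table) for both algorithms, so RF and
SVM profiles are directly comparable; impurity-based importance would not be.

A second validation lesson: features that are *constant within a run*
(drift slope, baseline RMS) act as run fingerprints. With three runs per
class and event-level splits, a forest memorizes the handful of run values —
this inflates the set-B diagonal legitimately (that is the overfitting being
demonstrated) but makes set-B *off-diagonal* cells land far from 0.5 in a
random direction, because the run values at an unseen voltage order
arbitrarily with respect to class. Run-aware splitting would remove this and
is a natural extension; we kept event-level splits as the standard protocol.

## Mixture quantification

For a mixed sample, events are scored by a classifier trained on pure
reference runs, and composition is estimated in stages
(`estimate_mixture()`):

1. raw fraction of scores above the fixed 0.5 threshold;
2. two-component Gaussian fit of the score distribution by EM
   (initialized at means 0.25/0.75, SDs 0.1, equal weights; SD floor 10⁻³;
   converged at ΔlogL < 10⁻⁸ or 500 iterations; components relabeled so
   μ₁ < μ₂);
3. optimized decision boundary: the intersection of the two weighted
   component densities (a quadratic in x; the root inside (μ₁, μ₂)), with
   the minimum of the mixture density as a configurable alternative — for
   Gaussian components the two rules coincide only approximately, so the
   report names the rule used;
4. corrected event ratio: fraction of scores beyond the boundary
   (default; operates on actual events) or the weight of the high-score
   component (peak-area alternative);
5. capture-frequency correction to a molecular fraction:
   p = (r/λ_A) / (r/λ_A + (1−r)/λ_B), with per-class rates λ measured on
   pure reference runs at the same voltage, never on the mixture. The form
   is the minimal inverse-rate weighting: it is the identity when rates are
   equal, preserves 0 and 1, and is monotone in r. It treats capture
   frequency as informative but incomplete, and is replaceable in the
   configuration.

Degenerate fits are handled explicitly: if a component weight collapses
(< 0.01) or a component SD pins at the floor — which happens whenever a
well-separated classifier emits hard 0/1 probabilities and the EM collapses
onto the point mass — the Gaussian model is declared invalid and the
boundary falls back to the fixed 0.5 threshold. Without this guard the
intersection lands inside the shoulder of the spike and silently corrupts
the corrected ratio; with it, the equimolar benchmark at −300 mV recovers
0.50 ± 0.02 despite the two-fold capture bias.

## Scenario library

`make_scenario()` bundles five study designs: `two_marker` (the default
tumor-marker pair), `equimolar_mixture` (same pair, 50/50 molar),
`baseline_overfit_demo` (identical classes, ±40 pA per-class run offsets,
10 s runs), `aptamer_shift`, and `serum_shift`.

For `aptamer_shift`, the complex shares the protein's capture model and its
blockage distribution is voltage-sensitive. A design point worth recording:
a monotone blockage shift that keeps the complex on the same side of the
protein at every voltage does *not* degrade cross-voltage AUC, because AUC is
rank-based. The paper-level phenomenon (matched-voltage separation with
cross-voltage collapse) requires the class ranking itself to invert within
the grid, so the complex's blockage crosses the protein's near −110 mV
(slope 0.20 per 250 mV) and its dwell scaling differs (γ = 0.2 vs 1);
training at −50 mV and testing at −300 mV then inverts almost completely.

`serum_shift` models centrifugation of a complex sample as a population
shift: the long-dwell/shallow subpopulation drops from weight 0.4 to 0.1,
and the retained subpopulations' waveform statistics shift slightly
(+0.04 blockage, ×0.75 dwell). The weight change alone caps the achievable
AUC near 0.65–0.70 (most events come from shared subpopulations), so the
waveform shift is what makes the two preparations separable (AUC ≈ 0.73–0.75
at −100/−150 mV); both ingredients mirror the qualitative description of the
serum experiment.

## Problem sizes and numerical choices

The test suite and the acceptance script regenerate everything from seeds.
Sizes were chosen to keep a full run on one CPU in tens of minutes while
leaving comfortable statistical margins: the two-marker benchmark uses the
full 60 s × 3 runs × 6 voltages × 3 seeds design; the baseline-overfit
demonstration uses its 10 s default; the aptamer and serum checks use 20 s
and 30 s runs respectively; capture-rate anchors pool ten seeded replicates
of the 60 s × 3 condition because a single replicate at −50 mV (~0.67
events/s) has a ratio SD of ~0.13, larger than the ±0.1 acceptance band —
the anchor is a statement about expected rates, so it is tested on a pooled
estimate with the band unchanged. The equimolar recovery runs the full
chain at −300 mV over multiple seeds (ten in the acceptance script, six in
the test suite) with per-seed recovery within ±0.05.

Other numerical conventions: voltages and baselines are negative and depths
are reported as positive magnitudes; blockades deviate away from zero;
fractional blockage uses the event-local `|I0|`; zero-variance feature
columns pass through standardization unscaled with a warning; the event
placement gap is 0.5 ms; EM and boundary tolerances are as given above.

## Known limitations

* White noise only; no acquisition filter, hence no censoring of fast
  events — the capture-rate correction here does not need the
  detection-efficiency term a filtered system would require.
* Two-component mixtures only; no per-event posterior output beyond the
  score column.
* Event-level splits allow run-fingerprint memorization for run-constant
  features (see above); run-aware splits are future work.
* The SNR coupling of shape features means "baseline-agnostic" is an
  approximation that weakens as offsets approach a sizeable fraction of
  `|I0|`.
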