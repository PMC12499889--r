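# voltmatrix

Voltage-matrix profiling of solid-state nanopore signals.

Solid-state nanopores read out single protein molecules as transient
blockades of the open-pore ionic current, and machine-learning classifiers
on blockade features (dwell time, fractional blockage ΔI/|I0|, waveform
shape) can discriminate biomarkers label-free. But translocation signals
depend strongly on the applied voltage, and a classifier trained under one
bias can fail — or cheat, by reading the acquisition baseline instead of the
molecule — under another. `voltmatrix` is a simulation and analysis toolkit
for studying exactly this: it trains a binary classifier at each voltage of
a grid and evaluates it at every voltage, producing a train-voltage ×
test-voltage AUC matrix whose diagonal measures within-condition performance
and whose off-diagonal measures cross-condition generalization.

The package provides, end to end:

* a seeded trace simulator (voltage-dependent Poisson capture
  λ(V) = α·|V|·exp(−V\*/|V|), run-level baseline offsets, drift, white noise,
  class-specific log-normal dwell and Gaussian blockage distributions, and
  scenario switches for voltage-sensitive complexes and serum population
  shifts);
* a two-threshold (Schmitt-trigger) event detector over a two-pass
  moving-median baseline;
* the two canonical feature sets — set A (event-intrinsic ratios and shape
  statistics) and set B (A plus baseline-dependent features: absolute ΔI,
  I0, baseline RMS, drift slope) — used to diagnose baseline overfitting;
* Random Forest / RBF-SVM voltage matrices with Mann–Whitney AUC and
  permutation feature importance;
* mixture quantification from classifier score histograms: two-Gaussian EM
  fit, optimized decision boundary (density intersection, with a
  density-minimum alternative and a degeneracy fallback to 0.5), corrected
  event ratio, and capture-frequency correction
  p = (r/λ_A)/(r/λ_A + (1−r)/λ_B) to a molecular fraction;
* plain-text I/O (TSV + JSON sidecars), a YAML pipeline configuration, and
  a command-line entry point.

## Worked example

Simulate the two default tumor-marker-like analytes at two voltages, build
a feature-set-A Random Forest matrix, then quantify an equimolar mixture at
−300 mV where the positive class is captured twice as often:

```r
library(voltmatrix)
cfg  <- make_scenario("two_marker", duration_s = 10)
sets <- default_feature_sets()
ev <- rbind(simulate_events(cfg, "CEA",    voltages = c(-100, -300), seed = 1),
            simulate_events(cfg, "CA15-3", voltages = c(-100, -300), seed = 2))
m <- build_voltage_matrix(ev, sets$A, positive = "CEA", seed = 3)
print(m)
#> <voltage_matrix_result> random_forest, feature set A, positive 'CEA'
#>       test
#> train   -100  -300
#>   -100 0.995 0.990
#>   -300 0.967 0.998

eq  <- make_scenario("equimolar_mixture", duration_s = 20)
est <- run_mixture_analysis(eq, -300, seed = 4)
print(est)
#> <mixture_estimate> n=533 events
#>   raw ratio @0.5:        0.683
#>   optimized boundary:    0.472 (intersection)
#>   corrected event ratio: 0.683 (exceedance)
#>   capture rates:         11.9 / 5.47 events/s
#>   molecular ratio:       0.497
```

Reading the output: the matrix rows are training voltages, columns test
voltages, cells AUC — here both diagonal and off-diagonal are high because
the two analytes differ in voltage-invariant features. In the mixture
report, 68% of events score as the positive class (it is captured ~2.2×
more often: 11.9 vs 5.5 events/s on the pure references), and the
inverse-rate correction recovers a molecular fraction of 0.497 — the true
equimolar composition — from the biased event counts.

The scenario library (`make_scenario`) also contains
`baseline_overfit_demo` (identical classes separated only by per-class
baseline offsets: feature set B scores a perfect 1.0 diagonal, diagnosing
baseline overfitting), `aptamer_shift` (a voltage-sensitive complex whose
cross-voltage AUC decays with |V_train − V_test|) and `serum_shift`
(centrifugation as a population shift in a complex sample).

## Command line

```sh
Rscript inst/cli/voltmatrix.R run-all --scenario two_marker --seed 7 --out-dir out
```

Subcommands `simulate`, `detect`, `features`, `matrix`, `mixture` and
`run-all` chain the pipeline stages over TSV/JSON files; every run writes a
provenance log and identical arguments give byte-identical numeric outputs.
A commented configuration template ships at
`inst/extdata/config_template.yaml`.

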