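# voltmatrix pipeline configuration template.
# Either reference a prebuilt scenario ...
simulation:
  scenario: two_marker        # two_marker | aptamer_shift | baseline_overfit_demo
                              # | equimolar_mixture | serum_shift
  duration_s: 60              # seconds per run
  runs_per_condition: 3
  seed: 1

# ... or spell the simulation out in full (delete the scenario block above):
# simulation:
#   voltage_grid: [-50, -100, -150, -200, -250, -300]   # mV, all negative
#   sampling_rate: 100000      # Hz
#   duration_s: 60             # s per run
#   runs_per_condition: 3
#   pore_conductance: 10       # nS; open-pore baseline = G * V pA
#   noise_rms: 12              # pA
#   drift_rate: 0.5            # pA/s
#   run_offset_sigma: 25       # pA, per-run baseline offset sd
#   mixture_fractions: [0.5, 0.5]
#   seed: 1
#   molecules:
#     - name: CEA
#       capture_prefactor_alpha: 0.046   # events/s/mV
#       capture_barrier_vstar: 61.6      # mV
#       blockage_frac_mean: 0.15
#       blockage_frac_sd: 0.03
#       dwell_median_ref_ms: 0.5         # ms at |V| = 100 mV
#       dwell_log_sd: 0.4
#       dwell_voltage_exponent_gamma: 1
#       blockage_voltage_slope: 0        # per 250 mV; nonzero = voltage-sensitive
#       edge_tau_us: 20
#     - name: CA15-3
#       capture_prefactor_alpha: 0.020
#       capture_barrier_vstar: 20
#       blockage_frac_mean: 0.28
#       blockage_frac_sd: 0.05
#       dwell_median_ref_ms: 2.0
#       dwell_log_sd: 0.5

detection:
  baseline_window_ms: 50      # moving-median window
  threshold_k: 5              # entry threshold, multiples of baseline RMS
  exit_k: 2                   # exit threshold
  min_dwell_samples: 5
  refractory_samples: 5

feature_set: A                # A (event-intrinsic) or B (adds baseline features)
algo: random_forest           # random_forest | svm
train_frac: 0.7
seed: 1
boundary_rule: intersection   # intersection | density_min
ratio_rule: exceedance        # exceedance | peak_area
output_dir: out
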