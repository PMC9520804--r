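# Accelerated/blast-phase CML cohort generator, calibrated to the blast
# column of the study's telomere parameter summary: telomere counts
# 41.51 +/- 5.25, aggregates 4.73 +/- 0.92, larger nuclei (~328.7 um^3),
# brighter telomere signals (~1.2x chronic) and a flatter telomere cloud
# (a/c ~ 6.65).
phase: accelerated_blast
n_patients: 18
n_nuclei_per_sample: 30
seed: 2
patient_effects:
  n_signals_sd: 0.35
  n_aggregates_sd: 0.2
  intensity_scale_sd: 0.03
  axis_scale_sd: 0.03
  flattening_scale_sd: 0.05
nucleus:
  semi_axes_um: [5.30, 4.40, 3.365]  # (4/3) pi a b c = 328.7 um^3
  axis_jitter_sd: 0.06
  n_signals: {mean: 41.51, sd: 5.25}
  n_aggregates: {mean: 4.73, sd: 0.92}
  intensity_mixture:
    component_means: [84, 120, 156]
    weights: [0.333333333333, 0.333333333333, 0.333333333334]
    sdlog: [0.08, 0.08, 0.08]
  aggregate:
    multiplicity: [2, 3]
    multiplicity_prob: [0.7, 0.3]
    spread_nm: [50, 50, 125]
  flattening: 4.2225                 # expected a/c = flattening * a / c = 6.65
  min_separation_nm: {lateral: 550, axial: 1100}
  psf_sigma_nm: [150, 150, 300]
  cy3: {background: 1.0, noise_sd: 0.15}
  dapi: {level: 1.0, background: 0.05, noise_sd: 0.05}
  fitc: {positive_level: 0.5, background: 0.02, noise_sd: 0.03}
  cd34_positive: true
  n_slices: 60
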