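# Chronic-phase CML cohort generator, calibrated to the chronic column of
# the study's telomere parameter summary: 18 patients, 30 CD34+ interphase
# nuclei per sample, telomere counts 39.45 +/- 6.49, aggregates 3.37 +/- 1.19,
# nuclear volume ~191.8 um^3, a/c ratio ~2.55. Intensities in arbitrary units.
phase: chronic
n_patients: 18
n_nuclei_per_sample: 30
seed: 1
patient_effects:
  n_signals_sd: 0.35
  n_aggregates_sd: 0.2
  intensity_scale_sd: 0.03
  axis_scale_sd: 0.03
  flattening_scale_sd: 0.05
nucleus:
  semi_axes_um: [4.50, 3.70, 2.75]   # (4/3) pi a b c = 191.8 um^3
  axis_jitter_sd: 0.06
  n_signals: {mean: 39.45, sd: 6.49} # marginal per-nucleus sd (patient + cell)
  n_aggregates: {mean: 3.37, sd: 1.19}
  intensity_mixture:
    component_means: [70, 100, 130]  # short / intermediate / long populations
    weights: [0.333333333333, 0.333333333333, 0.333333333334]
    sdlog: [0.08, 0.08, 0.08]
  aggregate:
    multiplicity: [2, 3]
    multiplicity_prob: [0.7, 0.3]
    spread_nm: [50, 50, 125]         # members pairwise < half Rayleigh limit
  flattening: 1.5583                 # expected a/c = flattening * a / c = 2.55
  min_separation_nm: {lateral: 550, axial: 1100}
  psf_sigma_nm: [150, 150, 300]
  cy3: {background: 1.0, noise_sd: 0.15}
  dapi: {level: 1.0, background: 0.05, noise_sd: 0.05}
  fitc: {positive_level: 0.5, background: 0.02, noise_sd: 0.03}
  cd34_positive: true
  n_slices: 60
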