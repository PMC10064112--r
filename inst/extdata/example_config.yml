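# Example configuration for run_deb_config(). Omitted keys take the study's
# standard defaults (full 48-species grid, f in {0.2,...,1}, seasonal means
# {0.4, 0.6, 0.8} with amplitude 0.2, 3-year integrations, 1-day output).
seed: 1
tasks: [sweep, validate, compare, paramspace, synth]
model:
  grid:
    v_dot: [0.2, 0.3, 0.4, 0.5]
    p_Am_max: [2000, 4000, 6000, 8000]
    kappa: [0.43, 0.51, 0.58]
environment:
  constant_f: [0.2, 0.4, 0.6, 0.8, 1.0]
  seasonal_f_mean: [0.4, 0.6, 0.8]
  f_amp: 0.2
integration:
  duration_days: 1095
  window_years: 2
synthetic:
  n_species: 300
  n_outliers: 6
output:
  dir: deb_outputs
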