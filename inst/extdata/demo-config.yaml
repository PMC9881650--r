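# Demo-scale pipeline configuration: a 20,000-person biennial panel
# emulating 1998-2018 waves, 50 bootstrap replicates, base year 2018,
# projection to 2050. Load with read_run_config() and pass to
# run_pipeline(); any field omitted here falls back to the same defaults.
seeds:
  panel: 101
  demographics: 102
  expansion: 103
  bootstrap: 104
panel:
  n_individuals: 20000
  n_waves: 11
  wave_spacing_years: 2
  base_year: 1998
  attrition: 0.03
estimation:
  B: 50
  allow_recovery: false
demographics:
  base_year: 2018
  horizon: 42
  total_population: 3.3e8
  true_migration: 0.003
projection:
  horizon: 32
  migration_mode: rate
calibration:
  bounds: [-0.05, 0.05]
report:
  years: [2020, 2035, 2050]
  interval: range
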