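# End-to-end demo configuration: a synthetic study region with a positive
# demographic-contamination association, run as
#   run_pipeline(system.file("extdata", "demo-config.yaml",
#                            package = "cwsdisparity"), out_dir)
simulate:
  seed: 20140101
  n_tracts_x: 18
  n_tracts_y: 18
  tract_side: 1000
  n_systems: 80
  tracts_per_system_range: [2, 5]
  population_range: [1200, 8000]
  subgroup_alpha: 2
  subgroup_beta: 2
  subgroup_name: minority
  effect_size: 1.5
  tests_per_system_range: [4, 12]
  population_noise_sd: 0.15
  half_cell_prob: 0.3
  wholesale_fraction: 0.05
  contaminants:
    - {id: ARSENIC, benchmark: 0.004, unit: ug/L, meanlog: 0.0, sdlog: 0.6, detection_limit: 0.5}
    - {id: THM4, benchmark: 0.15, unit: ug/L, meanlog: 3.4, sdlog: 0.7, detection_limit: 1.0}
risk:
  benchmarks:
    - {id: ARSENIC, benchmark: 0.004, unit: ug/L}
    - {id: THM4, benchmark: 0.15, unit: ug/L}
  window: ["2014-01-01", "2019-12-31"]
attribute:
  mode: counts
  eps: 1.0e-9
trend:
  subgroups: [pct_minority]
  by_size: false
  alternative: two.sided
  method: asymptotic
  min_n: 6
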