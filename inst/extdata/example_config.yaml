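# Example pipeline configuration (see ?read_pipeline_config).
cohort:
  n_patients: 75
  seed: 20
  pair_fraction: 0.24
  purity_range: [0.6, 1.0]
  stratum_hr:
    LOW: 1.0
    MODERATE: 1.5
    HIGH: 2.5
analysis:
  k: 3
  amp_threshold: 4.99
  extensive_loss_threshold: 0.5
  subclonal_cutoff: 0.25
  alpha1: 0.05
  alpha2: 0.05
  fdr: 0.10
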