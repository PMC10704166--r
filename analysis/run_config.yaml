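# Shared configuration for the analysis drivers. Every random draw in the
# workflow traces back to master_seed.
master_seed: 101
output_dir: results
cohort:
  n_subjects: 16
  atrophy_range: [0.86, 1.0]
  jitter: 1
electrodes:
  anchor_jitter_sd_deg: 5
solver:
  input_current_A: 0.002
  solver_tolerance: 1.0e-10
  max_iterations: 50000
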