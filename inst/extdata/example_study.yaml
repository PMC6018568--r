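# Example study configuration for read_study_config() / run_full_study().
# Desk-scale: a 120-patient cohort on a small grid with a reduced bootstrap.
generator:
  seed: 7
  n_patients: 120
  target_partial_r2: 0.11
  grid_shape: [16, 16, 16]
  voxel_size_mm: 8
min_overlap: 5
fwe_method: permutation_maxT
alpha_voxel: 0.05
n_perm: 1000
sizes: [30, 60, 120]
B: 600
alphas: [0.05, 0.001]
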