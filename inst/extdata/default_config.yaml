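seed: 1
simulate:
  stack:
    shape:
    - 96.0
    - 96.0
    - 16.0
    n_cells: 3
    radii:
    - 6.0
    - 6.0
    - 2.5
    peak: 3000.0
    base_z_extent: 3
    base_intensity: 2000.0
    background:
    - 80.0
    - 0.5
    - 0.5
    - 0.0
    poisson_scale: 60.0
    read_sd: 80.0
  counts:
    conditions:
      EM: 1.0
      DI: 2.0
    n_larvae: 18
    neuromasts_per_larva: 10
    baseline_rate: 0.5
    progenitor_rate: 0.3
    zero_inflation: 0.2
    n_replicates: 1
    replicate_sd: 0.0
    count_model: zip
    nb_size: 2.0
segmentation:
  tophat_footprint:
  - 50.0
  - 50.0
  - 3.0
  gaussian_sigma:
  - 1.0
  - 1.0
  - 0.5
  threshold: 500.0
  edt_min: 2.0
  edt_mode: 3d
  min_object_voxels: 20
  connectivity_2d: 8
  traverse_from: first_slice
quantify:
  tophat_footprint:
  - 15.0
  - 15.0
  - 1.0
  rolling_ball_radius: 50.0
stats:
  kind: mature
  control: EM
  alpha: 0.05
  multi_method: anova_dunnett
  normalize: no
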