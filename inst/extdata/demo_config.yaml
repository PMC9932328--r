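stages:
- phantom
- measure
- trap
- stats
seed: 1
cohort:
  n_subjects: 8.0
  timepoints:
  - 0.0
  - 3.0
  - 12.0
  - 24.0
airway_phantom:
  spacing_mm: 0.7
  noise_sd_hu: 15.0
  root_lumen_mm: 7.0
  taper: 0.8
  wall_mm: 0.9
  max_generation: 6.0
  dilation_prob: 0.4
  dilation_ratio_range:
  - 1.2
  - 1.6
  growth_rate_per_year: 0.04
lung_phantom:
  shape:
  - 48.0
  - 48.0
  - 60.0
  spacing_mm: 1.0
  insp_mean: -850.0
  insp_sd: 50.0
  exp_mean: -650.0
  exp_sd: 50.0
  defect_mean: -900.0
  defect_sd: 30.0
  blob_radius_mm: 3.0
  subject_defect_range:
  - 0.01
  - 0.12
  visit_defect_sd: 0.02
measurement:
  n_rays: 64.0
  plane_res_mm: 0.15
  max_radius_mm: 6.0
  section_step_mm: 1.0
  end_exclusion_mm: 2.0
  bei_kappa: 1.0
trapping:
  fractions:
  - 0.75
  - 0.5
  - 0.25
qc:
  volume_change_threshold: 0.05
stats:
  crosssectional_endpoints:
  - BEI
  - LA_5_10
  - WP_5_10
  longitudinal_endpoint: BEI
  longitudinal_intervals:
  - - 0.0
    - 3.0
  - - 0.0
    - 24.0
  robust: yes
write_volumes: no
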