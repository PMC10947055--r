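# Demonstration pipeline configuration: small synthetic cohort with
# severity-graded arcuate defects. All fields are optional; missing ones
# fall back to default_pipeline_config().
seed: 1
n_healthy: 24
n_glaucoma: 16
map_noise_sd: 2
vf_noise_sd: 0.5
defect:
  depth_range: [8, 16]
  inl_ratio: 0.3
  orc_delta: 0
  vf_depth_base: 6.6
  vf_depth_per_um: 0.12
match:
  age_window: 7.5
  se_window: 2.0
  min_subgroup: 3
clustering:
  k_max: 10
  criterion: 1
  feature: mean
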