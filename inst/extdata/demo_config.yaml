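# Demo configuration for the synthetic end-to-end pipeline.
# Unset fields fall back to defaultPipelineConfig().
seed: 1
n_subjects: 8
n_runs: 2
blocks_per_run: 24
tr_seconds: 2.5
grid: [20, 40, 20]
voxel_size_mm: 3
axis: 2
amplitude: 1
width: 1
center_jitter_sd: 0.3
subject_slope_jitter_sd: 0.1
noise:
  ar: [0.3, 0.2]
  innovation_sd: 10
  drift_amplitude: 5
  drift_period_seconds: 128
  baseline: 1000
min_intensity: 100
ar_method: pooled
alpha_voxel: 0.01
r2_gate: 0.7
n_perm: 1000
cluster_min: 5
connectivity: 6
q_regions: 0.05
era_volumes: 10
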