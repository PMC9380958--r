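# Full convective mixed-layer protocol: 100,000 microbes for 60 s against a
# pre-computed gridded velocity field (netCDF, dims t,z,y,x; u,v,w in m/s).
# Point flow.path at the DNS output before running. The motility grid spans
# B = 1, 3, 5 s crossed with v_swim = 10, 100, 500 um/s, plus the single
# non-motile baseline used for every Q comparison.
experiment: full convective mixed-layer patchiness protocol
master_seed: 1
flow:
  type: gridded
  path: /path/to/dns_velocity_fields.nc
domain:
  Lx_m: 0.6
  Ly_m: 0.6
  Lz_m: 0.3
simulation:
  n_microbes: 100000
  dt_s: 0.01
  total_time_s: 60
  output_interval_s: 0.1
  seed_z_range_m: [0.15, 0.3]
motility:
  - mode: non_motile
  - {mode: gyrotactic, B_s: 1.0, v_swim_um_per_s: 10}
  - {mode: gyrotactic, B_s: 1.0, v_swim_um_per_s: 100}
  - {mode: gyrotactic, B_s: 1.0, v_swim_um_per_s: 500}
  - {mode: gyrotactic, B_s: 3.0, v_swim_um_per_s: 10}
  - {mode: gyrotactic, B_s: 3.0, v_swim_um_per_s: 100}
  - {mode: gyrotactic, B_s: 3.0, v_swim_um_per_s: 500}
  - {mode: gyrotactic, B_s: 5.0, v_swim_um_per_s: 10}
  - {mode: gyrotactic, B_s: 5.0, v_swim_um_per_s: 100}
  - {mode: gyrotactic, B_s: 5.0, v_swim_um_per_s: 500}
analysis:
  f: 0.01
  q_cadence_s: 1
  regions: default
  effvel_window_s: [20, 60]
scales:
  nu_m2_per_s: 5.0e-6
  F_b_m2_per_s3: 5.0e-4
  h0_m: 0.15
output_dir: full-experiment-output
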