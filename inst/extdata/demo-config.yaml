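# Demo pipeline configuration: synthetic 15-kbp region, scaled-down
# dynamics, MicroC-like cross-linker preset.
seed: 1
region:
  synthetic:
    region_length: 15000
    region_name: demo
chain:
  bp_per_bead: 8
dynamics:
  protocol: desk
  equil_time: 500
  run_time: 2000
  snapshot_every: 50
  n_replicas: 5
map:
  lc_preset: microc
  n_reads: 50000
insulation:
  window: 6
boundaries:
  min_separation: 4
outputs:
  dir: demo_out
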