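# Demo pipeline: planted-path ensemble -> dynamic network -> allosteric
# paths -> communities -> report. Deterministic under `seed`.
seed: 1
output_dir: allonet_demo
stages: [synth, network, paths, communities, report]
synth:
  kind: planted_network
  n_residues: 30
  n_intermediates: 4
  rho: 0.8
  rho_bg: 0.05
  sigma: 0.03
  n_frames: 2000
network:
  cutoff_nm: 0.45
  persistence: 0.75
  k_neighbours: 7
paths:
  n_suboptimal: 20
communities:
  seed: 0
  discard_below: 0.01
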