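# Reference analysis defaults: every threshold of the standard protocol in
# one place. Units are embedded in key names where ambiguous.
seed: 1
output_dir: allonet_reference
stages: [synth, network, paths, communities, report]
synth:
  kind: planted_network
network:
  cutoff_nm: 0.45          # heavy-atom contact cutoff
  persistence: 0.75        # minimum contact fraction for an edge
  k_neighbours: 7          # MI estimator neighbours
paths:
  n_suboptimal: 20         # suboptimal paths after the optimal one
communities:
  seed: 0
  discard_below: 0.01      # discard communities below 1% of nodes
contacts:
  threshold_pp: 40         # differential-contact flag, percentage points
  hbond_angle_deg: 150     # D-H...A angle minimum
  classify_persistence: 0.5  # ligand/interlobe 50% rule
sensitivity:
  cutoffs_nm: [0.42, 0.45, 0.48]
  persistences: [0.65, 0.75, 0.85]
umbrella:
  windows_nm: [0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2]
  spring_k: 1500           # kJ mol^-1 nm^-2
  temperature_K: 310
states:
  close_nm: [0.0, 0.4]
  far_nm: [0.65, 10.0]
wham:
  n_bins: 100
  tolerance_kT: 1.0e-8
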