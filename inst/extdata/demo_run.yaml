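# Desk-scale demo configuration for run_pipeline(). Rates are boosted and
# the genome shrunk relative to a real MA experiment so the demo finishes in
# seconds while still producing non-empty tables at every stage.
seed: 42
reference:
  length: 30000
  n_genes: 25
  gene_length: 900
  gc: 0.508
ma:
  control:
    n_lines: 30
    bps_rate: 3.0e-8
    indel_rate: 3.0e-9
    divisions_per_transfer: 27.48
    transfers: 40
  treatment:
    n_lines: 30
    bps_rate: 3.0e-8
    indel_rate: 3.0e-9
    divisions_per_transfer: 27.81
    transfers: 40
evolution:
  n_populations: 4
  pop_size: 100000
  bottleneck_fraction: 1.0e-3
  generations_per_cycle: 10
  transfers: 15
  mu: 5.0e-7
plating:
  true_eop:
    "0": 1.0
    "20": 0.4
    "40": 0.1
    "60": 0.0
    "80": 0.0
  reference_cfu: 1000
  replicates: 3
thresholds:
  ci_level: 0.95
  min_freq: 0.05
  alpha: 0.05
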