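region_length: 2000000.0
chrom: chrS
target_fragment_bp: 500.0
resolution: 20000.0
tad_boundaries:
- 15
- 75
alpha: 1.0
tau: 1.0
loops:
- bin_i: 30
  bin_j: 55
  gamma: 8.0
enhancers:
- start: 1104000.0
  end: 1105000.0
  motif: SOX10
- start: 1108600.0
  end: 1109200.0
  motif: ETS1
- start: 1119000.0
  end: 1119300.0
  motif: HOXB2
n_pairs: 100000.0
seed: 1
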