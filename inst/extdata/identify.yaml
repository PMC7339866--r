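# Identification of the GPe activation and self-coupling from synthetic
# steady-state rate pairs (truth: a = 1.29, M = 400, B = 75, c22 = 0.35).
command: identify
synthetic:
  M: 400
  B: 75
  a: 1.29
  c22: 0.35
  n_pairs: 50
  u_min: 0
  u_max: 250
  noise_sd: 0
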