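# Target-variation scenario on the surrogate plant with the self-tuning
# ARV controller.
command: scenario
scenario: target_variation
controller:
  mode: adaptive_arv
  target: 0.1
  tau_theta_ms: 100
  sigma: 0.00875
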