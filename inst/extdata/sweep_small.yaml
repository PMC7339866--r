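# Reduced-resolution oscillation map over (c12, c21) coupling space.
command: sweep
model:
  preset: sweep
c12_values: [0, 2, 4]
c21_values: [0, 16, 32]
u1_level: 27
u2_level: 2
duration_ms: 4000
dt_ms: 0.1
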