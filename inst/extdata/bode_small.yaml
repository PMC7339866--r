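# Reduced frequency-response profile of the entrainable loop, DBS off.
command: bode
model:
  preset: exogenous
freqs_hz: [5, 10, 15, 20, 25, 30, 40, 50]
input_mean: 50
input_amplitude: 10
dt_ms: 0.1
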