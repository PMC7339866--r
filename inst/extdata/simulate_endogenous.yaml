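# Endogenous beta oscillation with the self-tuning controller switched on at
# 200 ms and a cortical input step (27 -> 42) at 750 ms.
command: simulate
model:
  preset: endogenous
u1:
  kind: piecewise
  breaks_ms: [750]
  levels: [27, 42]
u2:
  kind: constant
  level: 2
controller:
  mode: adaptive_beta
  tau_theta_ms: 75
  sigma: 0.19
  t_on_ms: 200
duration_ms: 2000
dt_ms: 0.1
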