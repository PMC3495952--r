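# Standard entrainment run: pulse 50 ms faster than the unperturbed stride,
# amplitude 10% of peak ankle torque, width 0.1 s.
model: {}
pulse:
  amplitude: 13.34645
  width: 0.1
  period: 1.8841
  offset: 0.0
  gating: truncate
experiment:
  kind: entrain
  strides: 300
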