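# Basin-of-entrainment scan over pulse periods 2*tau_0 +/- 0.1 s
# at 2 ms resolution, several initial offsets per period.
model: {}
experiment:
  kind: scan
  tp_step: 0.002
  deltas: 8
  strides: 300
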