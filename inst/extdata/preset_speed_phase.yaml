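# Speed versus pulse-onset-phase curve: one-shot probe from the limit
# cycle, 200 onset phases over one stride.
model: {}
experiment:
  kind: vphase
  grid: 200
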