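stages:
- stage: S9
  t_start: 0.0
  t_end: 40.0
- stage: S10E
  t_start: 40.0
  t_end: 70.0
- stage: S10
  t_start: 70.0
  t_end: 100.0
- stage: S11E
  t_start: 100.0
  t_end: 160.0
- stage: S11
  t_start: 160.0
  t_end: 220.0
- stage: S12
  t_start: 220.0
  t_end: 340.0
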