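ttfs:
- Hb
- Kr
- Pdm
- Cas
interactions:
- source: Hb
  target: Kr
  sign: activation
  klass: forward-relay
  has_threshold: yes
- source: Kr
  target: Pdm
  sign: activation
  klass: forward-relay
  has_threshold: yes
- source: Hb
  target: Pdm
  sign: repression
  klass: forward-decay
  has_threshold: yes
- source: Pdm
  target: Cas
  sign: activation
  klass: forward-relay
  has_threshold: yes
- source: Kr
  target: Cas
  sign: repression
  klass: forward-decay
  has_threshold: yes
- source: Hb
  target: Cas
  sign: repression
  klass: forward-decay
  has_threshold: yes
- source: Cas
  target: Pdm
  sign: repression
  klass: backward
  has_threshold: yes
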