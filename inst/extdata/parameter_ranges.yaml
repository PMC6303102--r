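ranges:
- param: beta_Hb
  low: 0.01
  high: 10.0
  kind: production
- param: beta_Kr
  low: 0.01
  high: 10.0
  kind: production
- param: beta_Pdm
  low: 0.01
  high: 10.0
  kind: production
- param: beta_Cas
  low: 0.01
  high: 10.0
  kind: production
- param: beta0_Pdm
  low: 0.01
  high: 10.0
  kind: production
- param: beta0_Cas
  low: 0.01
  high: 10.0
  kind: production
- param: alpha_Hb
  low: 0.005
  high: 0.5
  kind: degradation
- param: alpha_Kr
  low: 0.005
  high: 0.5
  kind: degradation
- param: alpha_Pdm
  low: 0.005
  high: 0.5
  kind: degradation
- param: alpha_Cas
  low: 0.005
  high: 0.5
  kind: degradation
- param: T_HbKr
  low: 0.01
  high: 1.0
  kind: threshold_ratio
- param: T_KrPdm
  low: 0.01
  high: 1.0
  kind: threshold_ratio
- param: T_HbPdm
  low: 0.01
  high: 0.1
  kind: threshold_ratio
- param: T_PdmCas
  low: 0.01
  high: 1.0
  kind: threshold_ratio
- param: T_KrCas
  low: 0.01
  high: 0.1
  kind: threshold_ratio
- param: T_HbCas
  low: 0.01
  high: 0.1
  kind: threshold_ratio
- param: T_CasPdm
  low: 0.01
  high: 0.1
  kind: threshold_ratio
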