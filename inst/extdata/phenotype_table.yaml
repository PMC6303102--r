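genotypes:
  WT:
    perturbation:
      kind: none
      target: ~
    expected:
    - Hb
    - Hb+Kr
    - Kr
    - Kr+Pdm
    - Pdm
    - Pdm+Cas
    - Cas
  hb_del:
    perturbation:
      kind: deletion
      target: Hb
    expected:
    - Pdm
    - Pdm+Cas
    - Cas
  kr_del:
    perturbation:
      kind: deletion
      target: Kr
    expected:
    - Hb
    - Pdm
    - Pdm+Cas
    - Cas
  pdm_del:
    perturbation:
      kind: deletion
      target: Pdm
    expected:
    - Hb
    - Hb+Kr
    - Kr
    - Cas
  hb_const:
    perturbation:
      kind: constitutive
      target: Hb
    expected:
    - Hb
    - Hb+Kr
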