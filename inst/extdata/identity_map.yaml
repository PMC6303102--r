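'': none
Hb: U1/U2
Hb+Kr: U1/U2
Kr: U3
Kr+Pdm: U4
Pdm: U4
Pdm+Cas: U5
Cas: interneuron
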