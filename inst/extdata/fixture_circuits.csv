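"name","seed","params_id","beta_Hb","beta_Kr","beta_Pdm","beta_Cas","beta0_Pdm","beta0_Cas","alpha_Hb","alpha_Kr","alpha_Pdm","alpha_Cas","T_HbKr","T_KrPdm","T_HbPdm","T_PdmCas","T_KrCas","T_HbCas","T_CasPdm"
"consistent",202,1051,0.627765562170096,0.0380399804258281,0.625167796530019,0.49063689280524,2.578840025413,0.212259234973576,0.295391986878087,0.00546313312134204,0.140590449169978,0.0085597554851743,0.109228610940147,3.01295863574328,0.0264458875945772,3.61781141154281,0.489455902505047,0.026481308759648,4.96837949002564
"robust",402,211,0.0537923684144392,0.691438163428377,0.0577987922679646,0.16970891054441,0.257537877352149,0.0913253386934509,0.0560024301265554,0.0307748909747982,0.133503692507286,0.0290405739474503,0.051023895250961,0.215758700568765,0.0208292837513999,0.0103798025201478,0.544653058421241,0.0164678538391665,1.09459995471717
"decay_dominant",402,305,0.0948120418771396,0.515688510849131,0.0381477722953755,0.157438997523068,0.220164871335008,0.0810965496455226,0.0567377744712951,0.0311225700156601,0.183774703780972,0.0286962874630246,0.0554003069047484,0.17773414860447,0.0218810148994033,0.0129030233998263,0.420789168628101,0.0144594234184259,0.853563099887031
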