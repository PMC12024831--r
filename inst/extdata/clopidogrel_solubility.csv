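pH,solubility_mg_per_mL
1.2,268.750
4.5,0.055
6.8,0.016
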