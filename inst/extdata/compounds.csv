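name,formula,molar_mass
PCT,C8H9NO2,151.163
SQX,C14H11N4NaO2S,322.318
FA,CH2O2,46.025
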