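disease,burden_dalys,burden_deaths,reduction_dalys,reduction_deaths
visceral leishmaniasis,3300000,51600,0.1,0.1
chagas disease,550000,8000,0.05,0.05
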