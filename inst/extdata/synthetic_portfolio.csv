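archetype,entry_phase,entry_year,multiplicity,capacity_factor,funded_phases,disease
repurposed_simple,2,2017,4,1,0;1;2;3,visceral leishmaniasis
nce_simple,0,2017,2,1,0;1;2;3,chagas disease
vaccine_simple,0,2018,1,1,0;1;2;3,
dx_assay,0,2018,2,1,0;1;2;3,visceral leishmaniasis
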