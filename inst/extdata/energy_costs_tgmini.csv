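reaction,atp,nadph,nadh,pathway
r_upt,0,0,0,uptake
r_tco2,0,0,0,uptake
r_cbb,9,6,0,CBB
r_hpa,0,0,0,CBB
r_pgm,0,0,0,storage
r_tpx,0,0,0,transport
r_pep,-1,0,-1,glycolysis
r_pk,-1,0,0,glycolysis
r_ppc,0,0,0,anaplerosis
r_pdh,0,0,-1,TCA
r_cs,0,0,0,TCA
r_idh,0,-1,0,TCA
r_ogd,0,0,-1,TCA
r_sdh,0,0,0,TCA
r_fum,0,0,0,TCA
r_mdh,0,0,-1,TCA
r_me,0,-1,0,TCA
sink_carb,1,0,0,biomass
sink_prot,15,5,0,biomass
sink_lip,1,2,0,biomass
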