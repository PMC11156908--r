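id	equation	reversible	pathway	notes
r_upt	CO2.ext (a) -> CO2.h (a)	FALSE	uptake	inorganic carbon uptake (bicarbonate/CO2 source)
r_tco2	CO2.c (a) -> CO2.h (a)	FALSE	uptake	refixation of respired CO2
r_cbb	CO2.h (a) + CO2.h (b) + CO2.h (c) -> TP.h (abc)	FALSE	CBB	lumped Calvin-Benson-Bassham cycle (3 CO2 per triose phosphate)
r_hpa	TP.h (abc) + TP.h (def) -> HP.h (cbadef)	FALSE	CBB	aldolase-like condensation to hexose phosphate
r_pgm	HP.h (abcdef) -> G1P.h (abcdef)	TRUE	storage	phosphoglucomutase branch to storage carbohydrate
r_tpx	TP.h (abc) -> TP.c (abc)	TRUE	transport	triose phosphate export chloroplast to cytosol
r_pep	TP.c (abc) -> PEP.c (abc)	TRUE	glycolysis	lower glycolysis lumped
r_pk	PEP.c (abc) -> PYR.c (abc)	FALSE	glycolysis	pyruvate kinase
r_ppc	PEP.c (abc) + CO2.c (d) -> OAA.c (abcd)	FALSE	anaplerosis	PEP carboxylase
r_pdh	PYR.c (abc) -> ACA.c (bc) + CO2.c (a)	FALSE	TCA	pyruvate dehydrogenase
r_cs	OAA.c (abcd) + ACA.c (ef) -> CIT.c (abcdef)	FALSE	TCA	citrate synthase
r_idh	CIT.c (abcdef) -> AKG.c (abcde) + CO2.c (f)	FALSE	TCA	aconitase + isocitrate dehydrogenase
r_ogd	AKG.c (abcde) -> SUC.c (bcde) + CO2.c (a)	FALSE	TCA	AKG to succinate branch (near zero in presets)
r_sdh	SUC.c (abcd) -> FUM.c (abcd)	FALSE	TCA	succinate dehydrogenase
r_fum	FUM.c (abcd) -> MAL.c (abcd)	TRUE	TCA	fumarase, high exchange
r_mdh	MAL.c (abcd) -> OAA.c (abcd)	TRUE	TCA	malate dehydrogenase
r_me	MAL.c (abcd) -> PYR.c (abc) + CO2.c (d)	FALSE	TCA	NADP malic enzyme
sink_carb	G1P.h ->	FALSE	biomass	storage carbohydrate sink
sink_prot	PYR.c + OAA.c + AKG.c + 0.5 PEP.c ->	FALSE	biomass	amino acid precursor sink (protein)
sink_lip	ACA.c ->	FALSE	biomass	acetyl-CoA sink (lipid)
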