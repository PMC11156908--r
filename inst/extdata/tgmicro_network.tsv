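id	equation	reversible	pathway	notes
m_upt	CO2.ext (a) -> CO2.c (a)	FALSE	uptake	inorganic carbon source
m_cbb	CO2.c (a) + CO2.c (b) + CO2.c (c) -> TP.c (abc)	FALSE	CBB	lumped carbon fixation
m_gly	TP.c (abc) -> PEP.c (abc)	TRUE	glycolysis	lumped glycolysis
m_pk	PEP.c (abc) -> PYR.c (abc)	FALSE	glycolysis	pyruvate kinase
m_ppc	PEP.c (abc) + CO2.c (d) -> OAA.c (abcd)	FALSE	anaplerosis	PEP carboxylase
m_mdh	OAA.c (abcd) -> MAL.c (abcd)	TRUE	TCA	malate dehydrogenase
m_me	MAL.c (abcd) -> PYR.c (abc) + CO2.c (d)	FALSE	TCA	malic enzyme
sink_tp	TP.c ->	FALSE	biomass	carbohydrate proxy sink
sink_pyr	PYR.c ->	FALSE	biomass	pyruvate-family sink
sink_oaa	OAA.c ->	FALSE	biomass	aspartate-family sink
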