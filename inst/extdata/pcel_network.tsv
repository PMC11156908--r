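id	equation	reversible	pathway	notes
rbco	RuBP.h (abcde) + CO2.h (f) -> PGA.h (fba) + PGA.h (cde)	FALSE	CBB	RuBisCO carboxylase
pgk	PGA.h (abc) -> GAP.h (abc)	TRUE	CBB	PGA kinase + GAP dehydrogenase lumped
tpi	GAP.h (abc) -> DHAP.h (abc)	TRUE	CBB	triose phosphate isomerase
fba	DHAP.h (abc) + GAP.h (def) -> FBP.h (cbadef)	TRUE	CBB	FBP aldolase
fbp	FBP.h (abcdef) -> F6P.h (abcdef)	FALSE	CBB	FBPase
tkt1	F6P.h (abcdef) + GAP.h (ghi) -> E4P.h (cdef) + X5P.h (abghi)	TRUE	CBB	transketolase 1
ald2	DHAP.h (abc) + E4P.h (defg) -> SBP.h (cbadefg)	TRUE	CBB	SBP aldolase
sbp	SBP.h (abcdefg) -> S7P.h (abcdefg)	FALSE	CBB	SBPase
tkt2	S7P.h (abcdefg) + GAP.h (hij) -> R5P.h (cdefg) + X5P.h (abhij)	TRUE	CBB	transketolase 2
rpi	R5P.h (abcde) -> Ru5P.h (abcde)	TRUE	CBB	ribose-5-phosphate isomerase
rpe	X5P.h (abcde) -> Ru5P.h (abcde)	TRUE	CBB	ribulose-phosphate epimerase
prk	Ru5P.h (abcde) -> RuBP.h (abcde)	FALSE	CBB	phosphoribulokinase
pgi	F6P.h (abcdef) -> G6P.h (abcdef)	TRUE	storage	phosphoglucoisomerase
pgm	G6P.h (abcdef) -> G1P.h (abcdef)	TRUE	storage	phosphoglucomutase
rbxo	RuBP.h (abcde) -> PG2.h (ab) + PGA.h (cde)	FALSE	photorespiration	RuBisCO oxygenase
pgp	PG2.h (ab) -> GA.c (ab)	FALSE	photorespiration	phosphoglycolate phosphatase + export
gox	GA.c (ab) -> GLY.c (ab)	FALSE	photorespiration	glycolate oxidase + aminotransferase lumped
gcs	GLY.c (ab) + GLY.c (cd) -> SER.c (cdb) + CO2.c (a)	FALSE	photorespiration	glycine cleavage + SHMT
sgat	SER.c (abc) -> PGA.c (abc)	FALSE	photorespiration	serine to glycerate to 3PGA lumped
tpt	DHAP.h (abc) -> DHAP.c (abc)	TRUE	transport	triose phosphate transporter
tpic	DHAP.c (abc) -> GAP.c (abc)	TRUE	glycolysis	cytosolic TPI
gapc	GAP.c (abc) -> PGA.c (abc)	TRUE	glycolysis	cytosolic GAPDH + PGK
pgat	PGA.h (abc) -> PGA.c (abc)	TRUE	transport	3PGA shuttle
eno	PGA.c (abc) -> PEP.c (abc)	TRUE	glycolysis	phosphoglycerate mutase + enolase
pk	PEP.c (abc) -> PYR.c (abc)	FALSE	glycolysis	pyruvate kinase
ppc	PEP.c (abc) + CO2.c (d) -> OAA.c (abcd)	FALSE	anaplerosis	PEP carboxylase
me	MAL.c (abcd) -> PYR.c (abc) + CO2.c (d)	FALSE	TCA	NADP malic enzyme
pyt	PYR.c (abc) -> PYR.m (abc)	TRUE	transport	pyruvate transporter
pdh	PYR.m (abc) -> ACA.m (bc) + CO2.m (a)	FALSE	TCA	pyruvate dehydrogenase
cs	OAA.m (abcd) + ACA.m (ef) -> CIT.m (abcdef)	FALSE	TCA	citrate synthase
idh	CIT.m (abcdef) -> AKG.m (abcde) + CO2.m (f)	FALSE	TCA	aconitase + isocitrate dehydrogenase
ogd	AKG.m (abcde) -> SUC.m (bcde) + CO2.m (a)	FALSE	TCA	AKG dehydrogenase + succinyl-CoA ligase
sdh	SUC.m (abcd) -> FUM.m (abcd)	TRUE	TCA	succinate dehydrogenase
fum	FUM.m (abcd) -> MAL.m (abcd)	TRUE	TCA	fumarase
mdh	MAL.m (abcd) -> OAA.m (abcd)	TRUE	TCA	malate dehydrogenase
oat	OAA.c (abcd) -> OAA.m (abcd)	TRUE	transport	oxaloacetate/aspartate shuttle lumped
mat	MAL.m (abcd) -> MAL.c (abcd)	TRUE	transport	malate shuttle
cup	CO2.ext (a) -> CO2.h (a)	FALSE	uptake	inorganic carbon uptake
cmc	CO2.m (a) -> CO2.c (a)	FALSE	uptake	mitochondrial CO2 release
cch	CO2.c (a) -> CO2.h (a)	FALSE	uptake	cytosolic CO2 refixation
sink_carb	G1P.h ->	FALSE	biomass	storage carbohydrate sink
sink_prot	PYR.c + 0.4 PEP.c + 0.6 OAA.c + 0.5 AKG.m + 0.2 R5P.h ->	FALSE	biomass	protein precursor sink
sink_lip	ACA.m ->	FALSE	biomass	lipid sink
sink_nuc	R5P.h ->	FALSE	biomass	nucleotide sink
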