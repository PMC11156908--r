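class,species,mmol_per_g,note
carbohydrate,G1P.h,6.173,anhydroglucose 162.14 g/mol
protein,PYR.c,3.3,pyruvate-family amino acids
protein,OAA.c,2.6,aspartate-family amino acids
protein,AKG.c,2.3,glutamate-family amino acids
protein,PEP.c,1.1,aromatic amino acids (PEP share)
fame,ACA.c,31.9,nine C2 units per 282 g C18 FAME
dna,HP.h,3.0,synthetic hexose-phosphate proxy for deoxynucleotides
rna,HP.h,3.0,synthetic hexose-phosphate proxy for nucleotides
chla,ACA.c,20.0,synthetic acetyl-CoA proxy for chlorophyll
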