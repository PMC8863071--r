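# Metabolite registry with phosphorus / carbon atom counts and currency
# flags. Proton compartments h_in / h_out are distinct species used by the
# membrane pumps of the toy models; they are not currency (h_out exchanges
# only through the pumps).
# id	name	P	C	currency
cb	Cellobiose	0	12	0
glucose_eq	Glucose equivalent (half cellobiose)	0	6	0
glc	Glucose	0	6	0
g1p	Glucose-1-phosphate	1	6	0
g6p	Glucose-6-phosphate	1	6	0
f6p	Fructose-6-phosphate	1	6	0
fbp	Fructose-1,6-bisphosphate	2	6	0
dhap	Dihydroxyacetone phosphate	1	3	0
gap	Glyceraldehyde-3-phosphate	1	3	0
bpg	1,3-Bisphosphoglycerate	2	3	0
pg3	3-Phosphoglycerate	1	3	0
pep	Phosphoenolpyruvate	1	3	0
pyr	Pyruvate	0	3	0
oaa	Oxaloacetate	0	4	0
mal	Malate	0	4	0
atp	ATP	3	10	1
adp	ADP	2	10	1
amp	AMP	1	10	1
gtp	GTP	3	10	1
gdp	GDP	2	10	1
atp_eq	ATP equivalent (ATP/GTP pool)	3	10	1
adp_eq	ADP equivalent (ADP/GDP pool)	2	10	1
pi	Orthophosphate	1	0	1
ppi	Pyrophosphate	2	0	1
nad	NAD+	2	21	1
nadh	NADH	2	21	1
nadp	NADP+	3	21	1
nadph	NADPH	3	21	1
co2	Carbon dioxide	0	1	1
h2o	Water	0	0	1
h	Proton	0	0	1
accoa	Acetyl-CoA	3	23	0
coa	Coenzyme A	3	21	0
acp	Acetyl phosphate	1	2	0
ac	Acetate	0	2	0
adpg	ADP-glucose	2	16	0
glyc	Glycogen (glucosyl unit)	0	6	0
h_in	Proton, cytoplasmic side	0	0	0
h_out	Proton, outside	0	0	0
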