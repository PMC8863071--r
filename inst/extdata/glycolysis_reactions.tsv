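# Elementary reactions of the PP_i-dependent glycolysis of C. thermocellum,
# cellobiose to pyruvate, with the Ppdk / malate-shunt split at PEP.
# Phosphoglycerate mutase + enolase are lumped (tag eno); hexokinase is
# GTP-dependent; phosphoglycerate kinase is taken with ADP (ADP/GDP are
# interchangeable after energy-equivalent folding).
# id	equation	reversible	enzyme	tags
cbh	cb + h2o -> 2 glc	0	Beta-glucosidase (cellobiose hydrolysis)	cbh
cbp	cb + pi -> g1p + glc	0	Cellobiose phosphorylase	cbp
pgm	g1p <-> g6p	1	Phosphoglucomutase	pgm
hk	glc + gtp -> g6p + gdp	0	GTP-dependent hexokinase	hk
pgi	g6p <-> f6p	1	Phosphoglucose isomerase	pgi
pfk	f6p + ppi -> fbp + pi	0	PPi-dependent phosphofructokinase	pfk_ppi
fba	fbp <-> dhap + gap	1	Fructose-bisphosphate aldolase	fba
tpi	dhap <-> gap	1	Triose-phosphate isomerase	tpi
gapdh	gap + nad + pi <-> bpg + nadh + h	1	Glyceraldehyde-3-phosphate dehydrogenase	gapdh
pgk	bpg + adp <-> pg3 + atp	1	Phosphoglycerate kinase	pgk
eno	pg3 <-> pep + h2o	1	Phosphoglycerate mutase + enolase (lumped)	eno
ppdk	pep + amp + ppi <-> pyr + atp + pi	1	Pyruvate phosphate dikinase	ppdk
pepck	pep + co2 + gdp <-> oaa + gtp	1	PEP carboxykinase	pepck
mdh	oaa + nadh + h <-> mal + nad	1	Malate dehydrogenase	mdh
me	mal + nadp -> pyr + co2 + nadph	0	Malic enzyme	me
ak	2 adp <-> atp + amp	1	Adenylate kinase	ak
ndk	atp + gdp <-> adp + gtp	1	Nucleoside-diphosphate kinase	ndk
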