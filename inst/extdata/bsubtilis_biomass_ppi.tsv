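# Macromolecular biomass composition (B. subtilis, aerobic glucose-limited
# chemostat at D = 0.10 1/h) with the PP_i stoichiometry of each
# macromolecule written as an affine function a + b*x of the Ppdk flux
# fraction x, in mmol PP_i per g biomass. Positive = net PP_i produced.
# Where available the biosynthesis / polymerization split is carried in
# separate columns; their sum matches the total up to the 0.001 rounding of
# the published per-part values (protein: -3.471 + 4.688 = 1.217 vs total
# 1.218). The totals are authoritative here. The published biosynthesis
# x-column total (-7.264) disagrees with its own component sum (-7.266);
# this file keeps the component sum. Version 1.
# name	mass_fraction	ppi_intercept	ppi_slope	biosyn_intercept	biosyn_slope	polym_intercept
protein	0.5285	1.218	-4.556	-3.471	-4.556	4.688
dna	0.0260	0.147	0	0.067	0	0.080
rna	0.0655	0.298	0	0.103	0	0.195
lipids	0.0760	-0.779	-1.636	-0.779	-1.636
lipoteichoic_acids	0.0304	0.073	-0.136	0.073	-0.136
cell_wall	0.2242	0.166	-0.938	0.166	-0.938
# ash fraction (ions and soluble metabolites), g per g biomass
# ash	0.0494
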