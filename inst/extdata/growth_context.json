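{
  "comment": "Catabolic context for wild-type C. thermocellum grown in cellobiose-limited chemostat culture (D = 0.1 1/h): biomass yield on cellobiose, cellobiose molar mass, fraction of substrate carbon unaccounted for by catabolic products or biomass, and the anabolic cellobiose demand from the biosynthesis analysis. Version 1.",
  "yield": 0.15,
  "substrate_molar_mass": 342.30,
  "unaccounted_fraction": 0.21,
  "anabolic_substrate_demand": 3.59
}
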