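Package: ppiflux
Title: Pyrophosphate Stoichiometry and PP_i-Generating Cycle Search for
    Atypical Glycolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric accounting tools for organisms with a
    pyrophosphate (PP_i) dependent glycolysis such as Clostridium
    thermocellum. Provides exact rational reaction algebra with folding of
    adenylate and guanylate currency into ATP-equivalents, reconstruction
    of the net glycolysis stoichiometry as a function of the pyruvate
    phosphate dikinase (Ppdk) flux fraction, ATP-yield scenarios for
    alternative PP_i supply mechanisms, a biosynthetic PP_i ledger over a
    macromolecular biomass composition with break-even analysis and
    anabolic coverage of the catabolic PP_i demand, and an optStoic-style
    minimal-total-flux search that enumerates candidate PP_i-generating
    reaction cycles in a stoichiometric model with successive solution
    exclusion, brute-force oracle verification, and a one-reaction
    augmentation mode. Ships toy metabolic networks with planted
    PP_i-generating mechanisms for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
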