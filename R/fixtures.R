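#' Shipped fixture bundle
#'
#' Loads the versioned parameter and reaction fixtures used across the
#' package: the metabolite registry, the elementary glycolysis reactions,
#' the macromolecular biomass composition with per-macromolecule PP_i
#' stoichiometry, and the catabolic growth context (biomass yield,
#' substrate molar mass, unaccounted-carbon fraction, anabolic substrate
#' demand). The bundle is read once per session and is byte-identical
#' across calls; `checksums` carries the md5 of each source file so a
#' report can be traced to a fixture version.
#'
#' @return A list with elements `metabolites`, `glycolysis_reactions`,
#'   `biomass_composition`, `growth_context`, `checksums`.
#' @export
ppi_fixtures <- function() {
  if (!is.null(.fixture_cache$bundle)) return(.fixture_cache$bundle)
  path <- function(f) system.file("extdata", f, package = "ppiflux", mustWork = TRUE)
  files <- c(metabolites = path("metabolites.tsv"),
             glycolysis = path("glycolysis_reactions.tsv"),
             composition = path("bsubtilis_biomass_ppi.tsv"),
             context = path("growth_context.json"))
  ctx <- jsonlite::read_json(files["context"])
  bundle <- list(
    metabolites = read_metabolite_table(files["metabolites"]),
    glycolysis_reactions = read_reaction_table(files["glycolysis"]),
    biomass_composition = read_composition_table(files["composition"]),
    growth_context = catabolic_context(
      yield = ctx$yield,
      substrate_molar_mass = ctx$substrate_molar_mass,
      unaccounted_fraction = ctx$unaccounted_fraction,
      anabolic_substrate_demand = ctx$anabolic_substrate_demand),
    checksums = tools::md5sum(unname(files))
  )
  .fixture_cache$bundle <- bundle
  bundle
}

.fixture_cache <- new.env(parent = emptyenv())
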