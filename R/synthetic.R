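#' Toy metabolic networks with planted PP_i-generating mechanisms
#'
#' Builds a small stoichiometric model containing any subset of the four
#' candidate PP_i-supplying mechanisms, each as its elementary reactions:
#'
#' * `membrane_ppase`: reversible H+-pumping membrane-bound
#'   pyrophosphatase (2 H+ per PP_i) plus a reversible ATPase proton pump
#'   (4 H+ per ATP). Run towards PP_i synthesis the pair nets
#'   `ATP + 3 Pi -> ADP + 2 PPi (+ H2O)`: two PP_i per ATP equivalent.
#' * `glycogen_cycle`: ADP-glucose synthase (Ags), glycogen synthase and
#'   glycogen phosphorylase; nets `ATP + Pi -> ADP + PPi`.
#' * `ppdk_malate_shunt`: reversible Ppdk run pyruvate-to-PEP, the malate
#'   shunt (Pepck, Mdh, Me) run PEP-to-pyruvate, with adenylate kinase and
#'   nucleoside-diphosphate kinase closing the AMP and GTP/GDP pools; nets
#'   `ATP + Pi -> ADP + PPi` with NADH/NADP+ transhydrogenation.
#' * `acetate_cycle`: Pta and Ack (acetyl-CoA to acetate, yielding ATP)
#'   plus acetyl-CoA synthetase (acetate back to acetyl-CoA, releasing
#'   AMP and PP_i) and adenylate kinase; nets `ATP + Pi -> ADP + PPi`.
#'
#' Proton compartments are distinct metabolites (`h_in`, `h_out`);
#' `h_out` is reachable only through the two pumps. The folded net
#' conversion of every planted mechanism is asserted when the model is
#' built.
#'
#' @param planted character subset of `c("membrane_ppase",
#'   "glycogen_cycle", "ppdk_malate_shunt", "acetate_cycle")`.
#' @param n_decoys dead-end decoy reactions appended via [add_decoys()].
#' @param seed seed for the decoy generator.
#' @return A [metabolic_model()].
#' @export
build_reference_toy <- function(planted = c("membrane_ppase", "glycogen_cycle",
                                            "ppdk_malate_shunt", "acetate_cycle"),
                                n_decoys = 0, seed = 1) {
  all_mech <- c("membrane_ppase", "glycogen_cycle", "ppdk_malate_shunt",
                "acetate_cycle")
  planted <- match.arg(planted, all_mech, several.ok = TRUE)
  if (length(planted) == 0L) stop("at least one planted mechanism is required")
  rx <- list()
  add <- function(text, id, enzyme, tags = character()) {
    rx[[id]] <<- parse_reaction_equation(text, id, enzyme = enzyme, tags = tags)
  }
  if ("membrane_ppase" %in% planted) {
    add("ppi + h2o + 2 h_in <-> 2 pi + 2 h_out", "ppase_mem",
        "H+-pumping membrane-bound pyrophosphatase", "ppase")
    add("atp + h2o + 4 h_in <-> adp + pi + 4 h_out", "atpase",
        "F-type ATPase (4 H+/ATP)", "atpase")
  }
  if ("glycogen_cycle" %in% planted) {
    add("g1p + atp -> adpg + ppi", "ags", "ADP-glucose synthase", "ags")
    add("adpg -> glyc + adp", "glgA", "Glycogen synthase", "glga")
    add("glyc + pi -> g1p", "glgP", "Glycogen phosphorylase", "glgp")
  }
  if ("ppdk_malate_shunt" %in% planted) {
    add("pep + amp + ppi <-> pyr + atp + pi", "ppdk",
        "Pyruvate phosphate dikinase", "ppdk")
    add("pep + co2 + gdp <-> oaa + gtp", "pepck", "PEP carboxykinase", "pepck")
    add("oaa + nadh + h <-> mal + nad", "mdh", "Malate dehydrogenase", "mdh")
    add("mal + nadp -> pyr + co2 + nadph", "me", "Malic enzyme", "me")
  }
  if ("acetate_cycle" %in% planted) {
    add("accoa + pi <-> acp + coa", "pta", "Phosphotransacetylase", "pta")
    add("acp + adp <-> ac + atp", "ack", "Acetate kinase", "ack")
    add("ac + atp + coa -> accoa + amp + ppi", "acs",
        "Acetyl-CoA synthetase", "acs")
  }
  if (any(c("ppdk_malate_shunt", "acetate_cycle") %in% planted)) {
    add("2 adp <-> atp + amp", "ak", "Adenylate kinase", "ak")
  }
  if ("ppdk_malate_shunt" %in% planted) {
    add("atp + gdp <-> adp + gtp", "ndk", "Nucleoside-diphosphate kinase", "ndk")
  }
  model <- metabolic_model(ppi_fixtures()$metabolites, rx)
  .assert_planted_nets(model, planted)
  if (n_decoys > 0) model <- add_decoys(model, n_decoys, seed)
  model
}

# folded net of each planted mechanism must be the qualifying conversion
# (or its 2 PP_i : 1 ATP membrane-PPase variant)
.assert_planted_nets <- function(model, planted) {
  net_of <- function(ids, mult) {
    fold_energy_equivalents(combine(model$reactions[ids], mult))
  }
  expect <- function(net, ids, vals) {
    ref <- stoich(ids, vals)
    net <- stoich_drop(net, c("h2o", "h"))
    if (!stoich_equal(net, ref)) {
      stop("internal error: planted mechanism net is ",
           format_reaction_equation(net), ", expected ",
           format_reaction_equation(ref))
    }
  }
  target4 <- list(c("adp_eq", "atp_eq", "pi", "ppi"), c(1, -1, -1, 1))
  if ("membrane_ppase" %in% planted) {
    expect(net_of(c("ppase_mem", "atpase"), c(rq(-2), rq(1))),
           c("adp_eq", "atp_eq", "pi", "ppi"), c(1, -1, -3, 2))
  }
  if ("glycogen_cycle" %in% planted) {
    expect(net_of(c("ags", "glgA", "glgP"), rq(c(1, 1, 1))),
           target4[[1]], target4[[2]])
  }
  if ("ppdk_malate_shunt" %in% planted) {
    expect(net_of(c("ppdk", "pepck", "mdh", "me", "ak", "ndk"),
                  rq(c(-1, 1, 1, 1, -1, -1))),
           c("adp_eq", "atp_eq", "nad", "nadh", "nadp", "nadph", "pi", "ppi"),
           c(1, -1, 1, -1, -1, 1, -1, 1))
  }
  if ("acetate_cycle" %in% planted) {
    expect(net_of(c("pta", "ack", "acs", "ak"), rq(c(1, 1, 1, -1))),
           target4[[1]], target4[[2]])
  }
  invisible(TRUE)
}

#' Append mass-balanced dead-end decoy reactions
#'
#' Decoys are linear chains over freshly minted internal metabolites that
#' terminate in dead ends, so they can never carry steady-state flux and
#' by construction cannot create a new route from ATP + P_i to PP_i. Each
#' decoy metabolite has one phosphorus-free, single-carbon formula, so the
#' chains are phosphorus- and carbon-balanced. Deterministic for a given
#' seed; the caller's RNG state is untouched.
#'
#' @param model a [metabolic_model()].
#' @param n number of decoy reactions (`>= 0`).
#' @param seed integer seed controlling chain lengths.
#' @return The augmented model.
#' @export
add_decoys <- function(model, n, seed) {
  stopifnot(n >= 0)
  if (n == 0L) return(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rx <- list(); met_ids <- character(0)
  made <- 0L; chain <- 0L
  while (made < n) {
    chain <- chain + 1L
    len <- min(sample.int(3L, 1L), n - made)
    nodes <- sprintf("dx%d_%d", chain, 0:len)
    met_ids <- c(met_ids, nodes)
    for (j in seq_len(len)) {
      made <- made + 1L
      id <- sprintf("decoy%03d", made)
      rx[[id]] <- parse_reaction_equation(paste(nodes[j], "->", nodes[j + 1L]),
                                          id, enzyme = "decoy", tags = "decoy")
    }
  }
  mets <- metabolite_table(met_ids, name = paste("decoy metabolite", met_ids),
                           P = 0, C = 1, currency = FALSE)
  model_add_reactions(model, rx, extra_mets = mets)
}
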