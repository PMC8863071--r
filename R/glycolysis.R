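#' Glycolysis route description
#'
#' The PEP-to-pyruvate flux is split between pyruvate phosphate dikinase
#' (fraction `x`) and the malate shunt (fraction `1 - x`). Cellobiose can
#' enter either by hydrolysis followed by two GTP-hexokinase reactions or
#' by phosphorolysis (one glucose unit enters as glucose-1-phosphate,
#' sparing one NTP).
#'
#' @param x Ppdk flux fraction in `[0, 1]`.
#' @param substrate `"cellobiose"` (the native disaccharide basis) or
#'   `"glucose_equivalent"` (half a cellobiose).
#' @param uptake_mode `"hydrolysis_hexokinase"` or `"phosphorolysis"`.
#' @return Object of class `glycolysis_route`.
#' @export
glycolysis_route <- function(x = 1,
                             substrate = c("cellobiose", "glucose_equivalent"),
                             uptake_mode = c("hydrolysis_hexokinase", "phosphorolysis")) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("Ppdk flux fraction x must be a single number in [0, 1]")
  }
  structure(list(x = x, substrate = match.arg(substrate),
                 uptake_mode = match.arg(uptake_mode)),
            class = "glycolysis_route")
}

# look a reaction up by enzyme tag; error names the missing tag
.by_tag <- function(reactions, tag) {
  for (r in reactions) if (tag %in% r$tags) return(r)
  stop("glycolysis fixture is missing a reaction tagged '", tag, "'")
}

#' Net glycolysis stoichiometry as a function of the Ppdk fraction
#'
#' Composes the elementary glycolysis reactions (per mole of cellobiose:
#' uptake, PGI, PP_i-Pfk and aldolase/TPI twice, GAPDH/PGK/enolase four
#' times, then `4x` Ppdk plus `4(1 - x)` malate shunt at PEP), folds
#' adenylates and guanylates into ATP equivalents, and drops water. All
#' arithmetic is exact, so the result is affine in `x` componentwise.
#'
#' At `x = 1` on cellobiose this yields
#' `cellobiose + 6 PPi + 10 ADP_eq + 4 NAD+ -> 4 pyruvate + 10 ATP_eq + 2 Pi + 4 NADH + 4 H+`.
#'
#' @param route a [glycolysis_route()] (a bare number is accepted and
#'   treated as `x` with the defaults).
#' @param reactions elementary reaction list; defaults to the shipped
#'   fixture.
#' @return Folded stoichiometry map.
#' @export
glycolysis_net <- function(route = glycolysis_route(),
                           reactions = ppi_fixtures()$glycolysis_reactions) {
  if (is.numeric(route)) route <- glycolysis_route(route)
  stopifnot(inherits(route, "glycolysis_route"))
  xq <- as_rq(route$x)
  uptake <- if (route$uptake_mode == "hydrolysis_hexokinase") {
    list(cbh = rq(1), hk = rq(2))
  } else {
    list(cbp = rq(1), pgm = rq(1), hk = rq(1))
  }
  trunk <- list(pgi = rq(2), pfk_ppi = rq(2), fba = rq(2), tpi = rq(2),
                gapdh = rq(4), pgk = rq(4), eno = rq(4))
  split <- list(ppdk = rq(4) * xq,
                pepck = rq(4) * (rq(1) - xq),
                mdh = rq(4) * (rq(1) - xq),
                me = rq(4) * (rq(1) - xq))
  mults <- c(uptake, trunk, split)
  mults <- mults[vapply(mults, function(m) !rq_zero(m), logical(1))]
  rx <- lapply(names(mults), .by_tag, reactions = reactions)
  net <- combine(rx, do.call(c, unname(mults)))
  net <- fold_energy_equivalents(net)
  net <- stoich_drop(net, "h2o")
  if (route$substrate == "glucose_equivalent") {
    cb <- stoich_coef(net, "cb")
    net <- stoich_drop(net, "cb")
    net <- stoich_canonical(c(net * rq(1, 2), stoich("glucose_eq", cb)))
  }
  net
}

#' PP_i demand per mole of glucose equivalent
#'
#' Read off the reconstructed glycolysis net stoichiometry; equals
#' `1 + 2x` (PP_i-Pfk contributes 1, Ppdk `2x`).
#'
#' @inheritParams glycolysis_net
#' @param x Ppdk flux fraction in `[0, 1]`.
#' @return `rq` scalar, mol PP_i per mol glucose equivalent.
#' @export
ppi_demand_per_glucose_eq <- function(x, reactions = ppi_fixtures()$glycolysis_reactions) {
  net <- glycolysis_net(glycolysis_route(x, substrate = "glucose_equivalent"),
                        reactions = reactions)
  -stoich_coef(net, "ppi")
}

#' Energy scenarios for PP_i supply
#'
#' A scenario is the ATP-equivalent price `c` of supplying one PP_i. The
#' named scenarios are `"unknown_free"` (c = 0, PP_i supplied at no ATP
#' cost), `"membrane_ppase"` (c = 1/2: one ATP drives synthesis of two
#' PP_i through the proton gradient) and `"glycogen_cycle"` (c = 1: the
#' ADP-glucose synthase cycle forms one PP_i and ADP per ATP and P_i).
#' Any other non-negative cost is allowed.
#'
#' @param scenario a scenario name or a non-negative cost.
#' @return Object of class `energy_scenario` with fields `name` and
#'   `atp_cost_per_ppi` (`rq`).
#' @export
energy_scenario <- function(scenario = c("unknown_free", "membrane_ppase", "glycogen_cycle")) {
  if (is.numeric(scenario) || inherits(scenario, "rq")) {
    cost <- as_rq(scenario)
    if (length(cost) != 1L || cost < 0) stop("scenario cost must be a single c >= 0")
    return(structure(list(name = paste0("c=", format(cost)),
                          atp_cost_per_ppi = cost), class = "energy_scenario"))
  }
  name <- match.arg(scenario)
  cost <- switch(name, unknown_free = rq(0), membrane_ppase = rq(1, 2),
                 glycogen_cycle = rq(1))
  structure(list(name = name, atp_cost_per_ppi = cost), class = "energy_scenario")
}

#' Net ATP yield per glucose equivalent under a PP_i-supply scenario
#'
#' Derived, not hard-coded: the glycolysis net stoichiometry is composed
#' with an explicit PP_i-supply conversion of cost `c`
#' (`c ATP_eq + P_i -> c ADP_eq + PP_i`) at exactly the multiplier that
#' zeroes the PP_i demand, and the ATP_eq coefficient of the result is
#' returned. Equals `(3 + 2x) - (1 + 2x) c`.
#'
#' @param route a [glycolysis_route()] or a bare Ppdk fraction `x`.
#' @param scenario an [energy_scenario()], scenario name, or cost.
#' @inheritParams glycolysis_net
#' @return `rq` scalar, mol ATP_eq per mol glucose equivalent.
#' @examples
#' as.numeric(atp_yield(1, "unknown_free"))    # 5
#' as.numeric(atp_yield(1, "membrane_ppase"))  # 3.5
#' as.numeric(atp_yield(1, "glycogen_cycle"))  # 2
#' @export
atp_yield <- function(route = glycolysis_route(), scenario = "unknown_free",
                      reactions = ppi_fixtures()$glycolysis_reactions) {
  if (is.numeric(route)) route <- glycolysis_route(route)
  if (!inherits(scenario, "energy_scenario")) scenario <- energy_scenario(scenario)
  cc <- scenario$atp_cost_per_ppi
  route_glc <- glycolysis_route(route$x, substrate = "glucose_equivalent",
                                uptake_mode = route$uptake_mode)
  net <- glycolysis_net(route_glc, reactions = reactions)
  demand <- -stoich_coef(net, "ppi")
  supply <- stoich(c("atp_eq", "adp_eq", "pi", "ppi"),
                   c(-cc, cc, rq(-1), rq(1)))
  closed <- stoich_accumulate(net, supply, demand)
  stopifnot(rq_zero(stoich_coef(closed, "ppi")))
  stoich_coef(closed, "atp_eq")
}

#' ATP saved per glucose equivalent by cellodextrin phosphorolysis
#'
#' Of the `n` glucose units in a cellodextrin, `n - 1` enter glycolysis by
#' phosphoroclastic cleavage (to glucose-1-phosphate, sparing the NTP a
#' hexokinase would spend); the reducing-end unit still requires
#' hexokinase. The saving is therefore `(n - 1) / n` ATP_eq per glucose
#' equivalent: 0.5 for cellobiose, 0.83 for cellohexaose.
#'
#' @param n oligomer length, integer `>= 1`.
#' @return `rq` scalar.
#' @export
cellodextrin_atp_saving <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("oligomer length n must be a single integer >= 1")
  }
  rq(n - 1, n)
}

#' Growth parameters
#'
#' @param mu specific growth rate, 1/h.
#' @param yield biomass yield, g biomass per g substrate (in `(0, 1)`).
#' @param substrate_molar_mass g/mol (cellobiose: 342.30).
#' @return Object of class `growth_parameters`.
#' @export
growth_parameters <- function(mu, yield, substrate_molar_mass = 342.30) {
  stopifnot(is.numeric(mu), mu >= 0, is.numeric(yield), yield > 0, yield < 1,
            is.numeric(substrate_molar_mass), substrate_molar_mass > 0)
  structure(list(mu = mu, yield = yield,
                 substrate_molar_mass = substrate_molar_mass),
            class = "growth_parameters")
}

#' Specific PP_i demand flux
#'
#' The glycolytic PP_i requirement per gram of biomass per hour implied by
#' a growth rate, biomass yield and per-substrate PP_i stoichiometry:
#' `(mu / yield) / M * 1000 * ppi_per_substrate`.
#'
#' @param growth a [growth_parameters()] object.
#' @param ppi_per_substrate mol PP_i per mol substrate (e.g. `2` for
#'   cellobiose with the whole PEP-to-pyruvate flux through the malate
#'   shunt).
#' @return mmol PP_i per g biomass per h (numeric).
#' @examples
#' # Delta-ppdk quadruple knockout: mu = 0.30/h, Y = 0.18 g/g, Pfk the only
#' # PP_i sink (2 PP_i per cellobiose) -> about 9.7 mmol/g/h
#' specific_ppi_demand(growth_parameters(0.30, 0.18), 2)
#' @export
specific_ppi_demand <- function(growth, ppi_per_substrate) {
  stopifnot(inherits(growth, "growth_parameters"),
            is.numeric(ppi_per_substrate) || inherits(ppi_per_substrate, "rq"))
  p <- as.numeric(ppi_per_substrate)
  if (p < 0) stop("ppi_per_substrate must be >= 0")
  (growth$mu / growth$yield) / growth$substrate_molar_mass * 1000 * p
}

#' Glycogen specification and its anabolic PP_i contribution
#'
#' ADP-glucose synthase releases one PP_i per ADP-glucose formed. Two
#' accounting modes are provided because the bookkeeping is ambiguous:
#' `per_chain` charges one PP_i per glycogen chain of `chain_length`
#' glucose units (0.15 mmol/g at 25 % w/w glycogen and chains of 10),
#' `per_unit` charges one PP_i per glucose unit added (1.54 mmol/g for the
#' same composition). Both are reported by the reporting layer; `per_chain`
#' is the default.
#'
#' @param mass_fraction g glycogen per g biomass, in `[0, 1)`.
#' @param chain_length glucose units per chain, integer `>= 1`.
#' @param accounting_mode `"per_chain"` or `"per_unit"`.
#' @param anhydroglucose_mass g/mol of a glucosyl residue (162.14).
#' @return `glycogen_spec` object; `glycogen_ppi_contribution()` returns
#'   mmol PP_i per g biomass (numeric).
#' @export
glycogen_spec <- function(mass_fraction, chain_length = 10,
                          accounting_mode = c("per_chain", "per_unit"),
                          anhydroglucose_mass = 162.14) {
  stopifnot(is.numeric(mass_fraction), mass_fraction >= 0, mass_fraction < 1,
            is.numeric(chain_length), chain_length >= 1,
            chain_length == round(chain_length))
  structure(list(mass_fraction = mass_fraction, chain_length = chain_length,
                 accounting_mode = match.arg(accounting_mode),
                 anhydroglucose_mass = anhydroglucose_mass),
            class = "glycogen_spec")
}

#' @rdname glycogen_spec
#' @param spec a `glycogen_spec`.
#' @export
glycogen_ppi_contribution <- function(spec) {
  stopifnot(inherits(spec, "glycogen_spec"))
  units <- spec$mass_fraction * 1000 / spec$anhydroglucose_mass
  if (spec$accounting_mode == "per_chain") units / spec$chain_length else units
}
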