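#' Net-conversion target for the cycle search
#'
#' The default target is the qualifying PP_i-supplying conversion
#' `ATP + Pi -> ADP + PPi`. Because a mechanism may be *energetically more
#' beneficial* than the target (the membrane-bound pyrophosphatase can
#' drive two PP_i per ATP through the proton gradient), the default
#' ("relaxed") semantics are:
#'
#' * non-energy products (PP_i) are pinned exactly to the target;
#' * the folded ATP-equivalent cost may not exceed the target's cost
#'   (consume at most one ATP_eq per pinned PP_i);
#' * ADP and P_i float (ADP is tied to ATP by adenylate conservation);
#' * AMP, GTP and GDP must be balanced to zero inside the pathway — a
#'   steady-state cycle has to close its own nucleotide pools, which is
#'   why adenylate kinase and nucleoside-diphosphate kinase appear in the
#'   published cycles;
#' * NADH/NAD+ and NADPH/NADP+ may co-convert as equal-and-opposite pairs
#'   (transhydrogenation is allowed), H2O/H+/CO2 are unconstrained;
#' * every other metabolite is balanced to zero.
#'
#' With `strict = TRUE` every currency species named in `exchange` is
#' pinned to its coefficient instead (and unnamed energy nucleotides to
#' zero), which is the literal fixed-conversion search; it cannot find
#' mechanisms whose stoichiometry is better than the target.
#'
#' @param exchange stoichiometry map over currency metabolites.
#' @param free_coconversions list of metabolite-id pairs allowed any
#'   equal-and-opposite net exchange.
#' @param free_species currency ids left unconstrained.
#' @param strict pin the exchange exactly.
#' @return Object of class `conversion_target`.
#' @export
conversion_target <- function(exchange = stoich(c("atp", "pi", "adp", "ppi"),
                                                c(-1, -1, 1, 1)),
                              free_coconversions = list(c("nadh", "nad"),
                                                        c("nadph", "nadp")),
                              free_species = c("h2o", "h", "co2"),
                              strict = FALSE) {
  structure(list(exchange = stoich_canonical(exchange),
                 free_coconversions = free_coconversions,
                 free_species = free_species,
                 strict = isTRUE(strict)),
            class = "conversion_target")
}

#' Search configuration for the minimal-flux cycle finder
#'
#' @param flux_bound big-M bound on any single flux; solutions with an
#'   active flux within 1 % of it trigger a warning to raise the bound.
#' @param max_solutions maximum number of solutions enumerated.
#' @param forbidden_reactions reaction ids excluded from any support.
#' @param augmentation_pool optional list of `ppi_reaction` candidates.
#' @param max_added how many pool reactions one solution may use.
#' @param solver_tolerance numeric tolerance below which a flux counts as
#'   zero.
#' @return Object of class `search_config`.
#' @export
search_config <- function(flux_bound = 100, max_solutions = 10,
                          forbidden_reactions = character(),
                          augmentation_pool = NULL, max_added = 1,
                          solver_tolerance = 1e-7) {
  stopifnot(flux_bound > 0, max_solutions >= 1, solver_tolerance > 0)
  if (!is.null(augmentation_pool) && max_added > length(augmentation_pool)) {
    stop("max_added exceeds the augmentation pool size")
  }
  structure(list(flux_bound = flux_bound, max_solutions = max_solutions,
                 forbidden_reactions = forbidden_reactions,
                 augmentation_pool = augmentation_pool,
                 max_added = max_added,
                 solver_tolerance = solver_tolerance),
            class = "search_config")
}

# ---- LP assembly ---------------------------------------------------------

# split-variable stoichiometric matrix: one forward column per reaction,
# one reverse column per reversible reaction
.build_columns <- function(model) {
  rids <- model_reaction_ids(model)
  mets <- model$metabolites$id
  cols <- list(); col_rid <- character(0); col_dir <- numeric(0)
  for (r in model$reactions) {
    v <- numeric(length(mets)); names(v) <- mets
    v[names(r$stoich)] <- as.numeric(r$stoich)
    cols[[length(cols) + 1L]] <- v
    col_rid <- c(col_rid, r$id); col_dir <- c(col_dir, 1)
    if (r$reversible) {
      cols[[length(cols) + 1L]] <- -v
      col_rid <- c(col_rid, r$id); col_dir <- c(col_dir, -1)
    }
  }
  S <- do.call(cbind, cols)
  rownames(S) <- mets
  list(S = S, rid = col_rid, dir = col_dir)
}

# metabolite constraint classes for a target
.target_rows <- function(model, target) {
  mets <- model$metabolites
  ex <- target$exchange
  missing <- setdiff(names(ex), mets$id)
  if (length(missing)) {
    stop("target references metabolites absent from the model: ",
         paste(missing, collapse = ", "))
  }
  not_curr <- names(ex)[!mets$currency[match(names(ex), mets$id)]]
  if (length(not_curr)) {
    stop("target exchange metabolites must be currency-flagged: ",
         paste(not_curr, collapse = ", "))
  }
  energy <- intersect(.ENERGY_IDS, mets$id)
  paired <- unlist(target$free_coconversions)
  free <- target$free_species
  if (target$strict) {
    pinned_ids <- setdiff(names(ex), free)
    zero_extra <- setdiff(energy, c(pinned_ids, free))
    free_ids <- free
  } else {
    pinned_ids <- setdiff(names(ex), c(energy, free, "pi"))
    # AMP/GTP/GDP (and any energy species not in the exchange) must close
    zero_extra <- setdiff(energy, c("atp", "adp", "atp_eq", "adp_eq"))
    free_ids <- unique(c(free, "pi", "adp", "adp_eq"))
  }
  zero_ids <- setdiff(mets$id, c(pinned_ids, free_ids, paired, zero_extra,
                                 if (!target$strict) c("atp", "atp_eq")))
  zero_ids <- unique(c(zero_ids, zero_extra))
  list(pinned = pinned_ids, zero = zero_ids, free = free_ids,
       pairs = target$free_coconversions)
}

# folded ATP_eq coefficient of the target exchange
.target_atp_cost <- function(target) {
  folded <- fold_energy_equivalents(target$exchange)
  as.numeric(stoich_coef(folded, "atp_eq"))
}

# iteratively drop reactions touching a metabolite that must balance to
# zero but is covered by only one reaction (its flux is forced to zero);
# removes dead-end decoy chains before the LP sees them
.presolve <- function(model, zero_ids, drop = character()) {
  active <- setdiff(model_reaction_ids(model), drop)
  repeat {
    touched <- list()
    for (id in active) {
      for (m in names(model$reactions[[id]]$stoich)) {
        touched[[m]] <- c(touched[[m]], id)
      }
    }
    dead <- character(0)
    for (m in intersect(zero_ids, names(touched))) {
      if (length(touched[[m]]) == 1L) dead <- c(dead, touched[[m]])
    }
    dead <- unique(dead)
    if (length(dead) == 0L) return(active)
    active <- setdiff(active, dead)
    if (length(active) == 0L) return(active)
  }
}

# assemble and solve the minFlux LP restricted to `allowed` reactions
.minflux_lp <- function(model, target, config, allowed = model_reaction_ids(model),
                        presolve = TRUE) {
  rows <- .target_rows(model, target)
  if (presolve) allowed <- .presolve(model, rows$zero,
                                     drop = setdiff(model_reaction_ids(model), allowed))
  if (length(allowed) == 0L) return(list(status = "infeasible"))
  sub <- model
  sub$reactions <- model$reactions[allowed]
  cols <- .build_columns(sub)
  S <- cols$S
  ex <- target$exchange
  A_eq <- NULL; b_eq <- numeric(0)
  degenerate <- FALSE
  addrow <- function(v, rhs) {
    if (all(abs(v) < 1e-15)) {
      if (abs(rhs) > 1e-15) degenerate <<- TRUE
      return(invisible())
    }
    A_eq <<- rbind(A_eq, v); b_eq <<- c(b_eq, rhs)
  }
  for (m in rows$zero) if (m %in% rownames(S)) addrow(S[m, ], 0)
  for (m in rows$pinned) {
    if (!(m %in% rownames(S))) return(list(status = "infeasible"))
    addrow(S[m, ], as.numeric(stoich_coef(ex, m)))
  }
  for (p in rows$pairs) {
    p <- intersect(p, rownames(S))
    if (length(p) == 2L) addrow(S[p[1], ] + S[p[2], ], 0)
  }
  if (degenerate) return(list(status = "infeasible"))
  A_le <- NULL; b_le <- NULL
  if (!target$strict) {
    # folded ATP_eq consumption may not exceed the target's
    atp_net <- numeric(ncol(S))
    for (m in intersect(c("atp", "gtp", "atp_eq"), rownames(S))) {
      atp_net <- atp_net + S[m, ]
    }
    if ("amp" %in% rownames(S)) atp_net <- atp_net - S["amp", ]
    A_le <- rbind(-atp_net)
    b_le <- -.target_atp_cost(target)
  }
  sol <- solve_lp(rep(1, ncol(S)), A_eq = A_eq, b_eq = b_eq,
                  A_le = A_le, b_le = b_le)
  if (sol$status != "optimal") return(list(status = sol$status))
  list(status = "optimal", x = sol$x, value = sol$value, cols = cols,
       model = sub)
}

# net flux per reaction from split variables, snapped to bounded-denominator
# rationals where possible
.extract_fluxes <- function(lp, tol) {
  rid <- lp$cols$rid; dir <- lp$cols$dir
  ids <- unique(rid)
  v <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(rid)) v[rid[i]] <- v[rid[i]] + dir[i] * lp$x[i]
  v[abs(v) < tol] <- 0
  exact <- TRUE
  num <- den <- numeric(length(v))
  for (i in seq_along(v)) {
    fr <- .approx_fraction(round(v[i], 9), max_den = 48)
    if (is.null(fr)) { exact <- FALSE; break }
    num[i] <- fr[1]; den[i] <- fr[2]
  }
  if (exact) {
    q <- rq(num, den); names(q) <- ids
    list(fluxes = q, exact = TRUE)
  } else {
    list(fluxes = v, exact = FALSE)
  }
}

#' Minimal-total-flux pathway achieving a net conversion
#'
#' Solves the minFlux problem: fluxes are split into non-negative forward
#' and reverse parts (reverse fixed to zero for irreversible reactions),
#' internal metabolites are balanced, the target conversion is imposed
#' (see [conversion_target()] for the exact semantics), and the total
#' absolute flux is minimized. Returned solutions are snapped to rationals
#' and re-verified by exact substitution; infeasibility is reported as a
#' result, not an error.
#'
#' @param model a [metabolic_model()].
#' @param target a [conversion_target()].
#' @param config a [search_config()].
#' @param .force_zero internal: reaction ids clamped to zero flux.
#' @return A `pathway_solution` (fields `fluxes`, `support`, `objective`,
#'   `achieved`, `atp_per_ppi`, `qualifies`, `added_reactions`, `exact`)
#'   or an object of class `pathway_infeasible`.
#' @export
find_min_flux <- function(model, target = conversion_target(),
                          config = search_config(), .force_zero = character()) {
  drop <- union(config$forbidden_reactions, .force_zero)
  allowed <- setdiff(model_reaction_ids(model), drop)
  lp <- .minflux_lp(model, target, config, allowed = allowed)
  if (lp$status != "optimal") {
    if (lp$status == "unbounded") stop("minFlux LP unbounded; check flux_bound and model")
    return(structure(list(status = "infeasible"), class = "pathway_infeasible"))
  }
  fx <- .extract_fluxes(lp, config$solver_tolerance)
  fluxes <- fx$fluxes
  support <- names(fluxes)[abs(as.numeric(fluxes)) > config$solver_tolerance]
  if (any(abs(as.numeric(fluxes)) > 0.99 * config$flux_bound)) {
    warning("an active flux is within 1% of flux_bound; consider raising it")
  }
  fluxes <- fluxes[support]
  if (!fx$exact) {
    # keep raw floats, flagged; achieved computed numerically and snapped
    # coefficient-wise where possible
    warning("fluxes could not be snapped to bounded-denominator rationals; ",
            "returning floating-point solution")
    fluxes <- rq(round(fluxes[support] * 1e6)) / rq(1e6)
    names(fluxes) <- support
  }
  achieved <- if (length(support)) {
    combine(lp$model$reactions[support], fluxes)
  } else stoich()
  if (fx$exact) .verify_solution(model, target, achieved)
  cls <- tryCatch(classify_solution(achieved), error = function(e) NULL)
  structure(list(
    fluxes = fluxes, support = sort(support),
    objective = sum(abs(fluxes)),
    achieved = achieved,
    atp_per_ppi = cls,
    qualifies = if (is.null(cls)) NA else cls <= 1,
    added_reactions = character(0),
    exact = fx$exact), class = "pathway_solution")
}

# exact re-verification by substitution: pinned species match, zero species
# vanish, folded ATP cost within budget
.verify_solution <- function(model, target, achieved) {
  rows <- .target_rows(model, target)
  for (m in rows$zero) {
    if (!rq_zero(stoich_coef(achieved, m))) {
      stop("solution verification failed: metabolite '", m, "' not balanced")
    }
  }
  for (m in rows$pinned) {
    if (!(stoich_coef(achieved, m) == stoich_coef(target$exchange, m))) {
      stop("solution verification failed: pinned metabolite '", m, "' off target")
    }
  }
  if (!target$strict) {
    folded <- fold_energy_equivalents(achieved)
    cost <- stoich_coef(folded, "atp_eq")
    if (cost < as_rq(.target_atp_cost(target))) {
      stop("solution verification failed: ATP_eq budget exceeded")
    }
  }
  invisible(TRUE)
}

#' @export
print.pathway_solution <- function(x, ...) {
  cat("pathway solution: total flux", format(x$objective),
      "| support {", paste(x$support, collapse = ", "), "}\n")
  cat("  achieved:", format_reaction_equation(x$achieved), "\n")
  if (!is.null(x$atp_per_ppi)) {
    cat("  ATP_eq per PP_i:", format(x$atp_per_ppi),
        if (isTRUE(x$qualifies)) "(qualifies)" else "(does not qualify)", "\n")
  }
  if (length(x$added_reactions)) {
    cat("  added reactions:", paste(x$added_reactions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.pathway_infeasible <- function(x, ...) {
  cat("no pathway achieves the target conversion (infeasible)\n")
  invisible(x)
}

# lexicographic support order over model reaction indices
.support_key <- function(support, rids) {
  paste(sprintf("%04d", sort(match(support, rids))), collapse = ",")
}

#' Enumerate minimal-flux pathways by successive exclusion
#'
#' After each solution an integer cut excludes its support (and any
#' superset): at least one support member must be inactive in later
#' solutions. The cut is applied exactly by enumerating, for every
#' combination of one excluded member per previous solution, the LP with
#' those reactions clamped to zero, and keeping the best (objective, then
#' lexicographic support) candidate. Enumeration stops at
#' `config$max_solutions` or when every combination is infeasible.
#'
#' @inheritParams find_min_flux
#' @return List of `pathway_solution`, ordered by (objective,
#'   lexicographic support); no two share a support.
#' @export
enumerate_pathways <- function(model, target = conversion_target(),
                               config = search_config()) {
  rids <- model_reaction_ids(model)
  solutions <- list()
  repeat {
    if (length(solutions) >= config$max_solutions) break
    cuts <- lapply(solutions, function(s) s$support)
    combos <- if (length(cuts) == 0L) list(character(0)) else {
      grid <- do.call(expand.grid, c(lapply(cuts, function(x) x),
                                     list(stringsAsFactors = FALSE)))
      unique(lapply(seq_len(nrow(grid)), function(i)
        unique(unlist(grid[i, ], use.names = FALSE))))
    }
    best <- NULL; best_key <- NULL
    for (fz in combos) {
      sol <- find_min_flux(model, target, config, .force_zero = fz)
      if (inherits(sol, "pathway_infeasible")) next
      key <- .support_key(sol$support, rids)
      if (is.null(best) ||
          as.numeric(sol$objective) < as.numeric(best$objective) - config$solver_tolerance ||
          (abs(as.numeric(sol$objective) - as.numeric(best$objective)) <= config$solver_tolerance &&
           key < best_key)) {
        best <- sol; best_key <- key
      }
    }
    if (is.null(best)) break
    solutions[[length(solutions) + 1L]] <- best
  }
  solutions
}

#' ATP-equivalent cost per PP_i of an achieved conversion
#'
#' Folds the achieved net conversion into ATP equivalents and returns the
#' ATP_eq consumed per PP_i produced. A mechanism qualifies as a
#' PP_i supplier compatible with a high ATP-yielding glycolysis when the
#' ratio is at most 1.
#'
#' @param solution a `pathway_solution` or a bare stoichiometry map.
#' @return `rq` scalar cost ratio.
#' @examples
#' # direct NTP hydrolysis to NMP + PP_i costs 2 ATP_eq per PP_i
#' classify_solution(stoich(c("atp", "amp", "ppi"), c(-1, 1, 1)))
#' @export
classify_solution <- function(solution) {
  achieved <- if (inherits(solution, "pathway_solution")) solution$achieved else
    stoich_canonical(solution)
  if (length(achieved) == 0L) stop("empty achieved conversion")
  folded <- fold_energy_equivalents(achieved)
  ppi <- stoich_coef(folded, "ppi")
  if (!(ppi > 0)) stop("solution produces no PP_i")
  cost <- -stoich_coef(folded, "atp_eq")
  cost / ppi
}

#' Drop solutions whose support touches forbidden reactions
#'
#' @param solutions list of `pathway_solution`.
#' @param forbidden reaction ids.
#' @return Filtered list.
#' @export
filter_by_reactions <- function(solutions, forbidden) {
  Filter(function(s) length(intersect(s$support, forbidden)) == 0L, solutions)
}

#' Cycle search with a bounded number of added reactions
#'
#' Augments the model with candidate reactions from `pool` under the
#' constraint that a solution uses at most `config$max_added` of them
#' (imposed exactly by enumerating admissible pool subsets), then
#' enumerates pathways. Each solution reports which pool reactions it
#' used.
#'
#' @inheritParams find_min_flux
#' @param pool list of `ppi_reaction` candidates (may reference new
#'   metabolites).
#' @return List of `pathway_solution` ordered by (objective, support), at
#'   most `config$max_solutions`, deduplicated by support.
#' @export
augmented_search <- function(model, pool, target = conversion_target(),
                             config = search_config()) {
  pool_ids <- vapply(pool, function(r) r$id, character(1))
  k <- min(config$max_added, length(pool))
  subsets <- list(integer(0))
  if (k >= 1) {
    for (size in seq_len(k)) {
      subsets <- c(subsets, utils::combn(seq_along(pool), size, simplify = FALSE))
    }
  }
  aug <- model_add_reactions(model, pool)
  rids <- model_reaction_ids(aug)
  seen <- character(0); out <- list()
  for (idx in subsets) {
    banned <- pool_ids[setdiff(seq_along(pool), idx)]
    cfg <- config
    cfg$forbidden_reactions <- union(config$forbidden_reactions, banned)
    sols <- enumerate_pathways(aug, target, cfg)
    for (s in sols) {
      key <- .support_key(s$support, rids)
      if (key %in% seen) next
      seen <- c(seen, key)
      s$added_reactions <- intersect(s$support, pool_ids)
      out[[length(out) + 1L]] <- s
    }
  }
  ord <- order(vapply(out, function(s) as.numeric(s$objective), numeric(1)),
               vapply(out, function(s) .support_key(s$support, rids), character(1)))
  out <- out[ord]
  out[seq_len(min(length(out), config$max_solutions))]
}

#' Brute-force oracle: minimal feasible supports by subset enumeration
#'
#' Independent check of the minimal-flux search. Every reaction subset of
#' size at most `max_support_size` is tested for feasibility of the target
#' conversion (same constraint semantics as [find_min_flux()], no
#' objective); returned are the feasible subsets none of whose proper
#' subsets are feasible. Subsets of a found minimal support are never
#' feasible by construction and supersets are skipped, which keeps the
#' enumeration tractable.
#'
#' @inheritParams find_min_flux
#' @param max_support_size largest subset size tried; guard:
#'   `choose(n, max_support_size) <= 1e6`.
#' @return List of character vectors (sorted reaction ids).
#' @export
brute_force_oracle <- function(model, target = conversion_target(),
                               max_support_size = 6) {
  rids <- model_reaction_ids(model)
  n <- length(rids)
  if (n == 0L) return(list())
  if (choose(n, min(max_support_size, n)) > 1e6) {
    stop("subset enumeration guard exceeded: choose(", n, ", ",
         max_support_size, ") > 1e6")
  }
  rows <- .target_rows(model, target)
  # a subset must touch every pinned species to be feasible
  pinned <- rows$pinned
  touches <- lapply(rids, function(id) names(model$reactions[[id]]$stoich))
  names(touches) <- rids
  minimal <- list()
  cfg <- search_config()
  for (size in seq_len(min(max_support_size, n))) {
    for (sel in utils::combn(n, size, simplify = FALSE)) {
      ids <- rids[sel]
      if (any(vapply(minimal, function(ms) all(ms %in% ids), logical(1)))) next
      if (length(pinned) &&
          !all(pinned %in% unique(unlist(touches[ids])))) next
      lp <- .minflux_lp(model, target, cfg, allowed = ids, presolve = FALSE)
      if (lp$status == "optimal" && lp$value > cfg$solver_tolerance) {
        minimal[[length(minimal) + 1L]] <- sort(ids)
      }
    }
  }
  minimal
}
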