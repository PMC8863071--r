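#' Biomass composition with per-macromolecule PP_i stoichiometry
#'
#' Each macromolecule carries a mass fraction and an affine PP_i
#' stoichiometry `a + b x` (mmol PP_i per g biomass, `x` the Ppdk flux
#' fraction), optionally split into biosynthesis and polymerization parts.
#' Mass fractions plus the ash fraction must sum to 1 within `1e-6`.
#' Coefficients are held as exact rationals so the column sums reproduce
#' the component totals digit for digit.
#'
#' @param components data.frame with columns `name`, `mass_fraction`,
#'   `ppi_intercept`, `ppi_slope` and optionally `biosyn_intercept`,
#'   `biosyn_slope`, `polym_intercept` (NA where absent).
#' @param ash_fraction g per g biomass not covered by the macromolecules.
#' @return Object of class `biomass_composition`.
#' @export
biomass_composition <- function(components, ash_fraction) {
  need <- c("name", "mass_fraction", "ppi_intercept", "ppi_slope")
  stopifnot(all(need %in% names(components)))
  mf <- components$mass_fraction
  if (any(mf < 0 | mf > 1) || ash_fraction < 0 || ash_fraction > 1) {
    stop("mass fractions must lie in [0, 1]")
  }
  if (abs(sum(mf) + ash_fraction - 1) > 1e-6) {
    stop("mass fractions plus ash must sum to 1 (got ",
         format(sum(mf) + ash_fraction), ")")
  }
  structure(list(
    components = data.frame(name = as.character(components$name),
                            mass_fraction = mf, stringsAsFactors = FALSE),
    a = as_rq(components$ppi_intercept),
    b = as_rq(components$ppi_slope),
    biosyn_a = if ("biosyn_intercept" %in% names(components))
      components$biosyn_intercept else NULL,
    biosyn_b = if ("biosyn_slope" %in% names(components))
      components$biosyn_slope else NULL,
    polym_a = if ("polym_intercept" %in% names(components))
      components$polym_intercept else NULL,
    ash_fraction = ash_fraction), class = "biomass_composition")
}

#' Read a biomass-composition table
#'
#' Tab-separated columns `name  mass_fraction  ppi_intercept  ppi_slope
#' [biosyn_intercept  biosyn_slope  polym_intercept]`; `#` comments. The
#' ash fraction is inferred as `1 - sum(mass_fraction)`.
#'
#' @param path file path.
#' @return A [biomass_composition()].
#' @export
read_composition_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  getcol <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else "",
                               character(1))
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  df <- data.frame(name = getcol(1), mass_fraction = num(getcol(2)),
                   ppi_intercept = num(getcol(3)), ppi_slope = num(getcol(4)),
                   biosyn_intercept = num(getcol(5)), biosyn_slope = num(getcol(6)),
                   polym_intercept = num(getcol(7)), stringsAsFactors = FALSE)
  biomass_composition(df, ash_fraction = round(1 - sum(df$mass_fraction), 9))
}

#' Net biosynthetic PP_i at a given Ppdk fraction
#'
#' `sum_i (a_i + b_i x)` in mmol PP_i per g biomass; positive means
#' biosynthesis is a net PP_i producer. Exact in `x` (affine).
#'
#' @param composition a [biomass_composition()].
#' @param x Ppdk flux fraction in `[0, 1]`.
#' @return `rq` scalar.
#' @export
total_ppi <- function(composition, x) {
  stopifnot(inherits(composition, "biomass_composition"))
  if (!is.numeric(x) && !inherits(x, "rq")) stop("x must be numeric")
  if (length(x) != 1L || as.numeric(x) < 0 || as.numeric(x) > 1) {
    stop("x must be a single value in [0, 1]")
  }
  xq <- tryCatch(as_rq(x), error = function(e) NULL)
  A <- sum(composition$a); B <- sum(composition$b)
  # exact when x is exactly representable, plain double otherwise
  if (is.null(xq)) as.numeric(A) + as.numeric(B) * as.numeric(x) else A + B * xq
}

#' Fitted biosynthetic PP_i ledger
#'
#' Collapses a biomass composition into the affine ledger
#' `total(x) = A + B x` and its break-even Ppdk fraction `x*` (the root of
#' `total` inside `[0, 1]`, absent when the sign is constant). `predict()`
#' evaluates the ledger, `summary()` adds the catabolic partition and
#' anabolic coverage when given a context.
#'
#' @param composition a [biomass_composition()].
#' @return Object of class `ppi_ledger` with fields `A`, `B` (`rq`),
#'   `breakeven` (`rq` or `NULL`), `breakeven_percent` (floored whole
#'   percent or `NA`), `composition`.
#' @examples
#' \dontrun{
#' led <- ppi_ledger(ppi_fixtures()$biomass_composition)
#' print(led)            # A = 1.123, B = -7.266, x* ~ 0.1546 (15 %)
#' predict(led, x = 0.67)
#' }
#' @export
ppi_ledger <- function(composition) {
  A <- sum(composition$a)
  B <- sum(composition$b)
  xs <- breakeven_ppdk_fraction(composition)
  structure(list(A = A, B = B, breakeven = xs,
                 breakeven_percent = if (is.null(xs)) NA_integer_ else
                   as.integer(floor(100 * as.numeric(xs))),
                 composition = composition),
            class = "ppi_ledger")
}

#' @export
print.ppi_ledger <- function(x, ...) {
  cat("biosynthetic PP_i ledger: total(x) =", format(x$A), "+ (", format(x$B),
      ") x  [mmol PP_i / g biomass]\n")
  if (is.null(x$breakeven)) {
    cat("no break-even Ppdk fraction in [0, 1] (constant sign)\n")
  } else {
    cat(sprintf("break-even Ppdk fraction x* = %s (%.4f); net producer for x <= %d %%\n",
                format(x$breakeven), as.numeric(x$breakeven), x$breakeven_percent))
  }
  invisible(x)
}

#' @export
predict.ppi_ledger <- function(object, x = 0, ...) {
  vapply(x, function(xi) as.numeric(total_ppi(object$composition, xi)), numeric(1))
}

#' @export
coef.ppi_ledger <- function(object, ...) {
  c(intercept = as.numeric(object$A), slope = as.numeric(object$B))
}

#' Break-even Ppdk fraction
#'
#' The `x*` in `[0, 1]` at which net biosynthetic PP_i is zero. `NULL`
#' when the affine total has constant sign over `[0, 1]`.
#'
#' @inheritParams total_ppi
#' @return `rq` scalar or `NULL`.
#' @export
breakeven_ppdk_fraction <- function(composition) {
  A <- sum(composition$a)
  B <- sum(composition$b)
  if (rq_zero(B)) return(NULL)
  root <- -A / B
  if (root < 0 || root > 1) return(NULL)
  root
}

#' Catabolic context for the anabolic/catabolic partition
#'
#' @param yield biomass yield, g biomass per g substrate.
#' @param substrate_molar_mass g/mol.
#' @param unaccounted_fraction fraction of total substrate carbon not
#'   recovered in products or biomass, in `[0, 1)`.
#' @param anabolic_substrate_demand mmol substrate per g biomass consumed
#'   by biosynthesis.
#' @param ppi_per_substrate function of the Ppdk fraction `x` giving mol
#'   PP_i consumed in catabolism per mol substrate; the default `2 + 4x`
#'   is the cellobiose stoichiometry of the reconstructed glycolysis.
#' @return Object of class `catabolic_context`.
#' @export
catabolic_context <- function(yield, substrate_molar_mass = 342.30,
                              unaccounted_fraction = 0,
                              anabolic_substrate_demand = 0,
                              ppi_per_substrate = function(x) 2 + 4 * x) {
  stopifnot(yield > 0, substrate_molar_mass > 0,
            unaccounted_fraction >= 0, unaccounted_fraction < 1,
            anabolic_substrate_demand >= 0, is.function(ppi_per_substrate))
  structure(list(yield = yield, substrate_molar_mass = substrate_molar_mass,
                 unaccounted_fraction = unaccounted_fraction,
                 anabolic_substrate_demand = anabolic_substrate_demand,
                 ppi_per_substrate = ppi_per_substrate),
            class = "catabolic_context")
}

#' Substrate carbon partition
#'
#' Total substrate demand per gram of biomass, split into anabolic,
#' unaccounted and catabolic parts: `total = 1000 / (yield * M)` mmol/g,
#' `unaccounted = f * total`, `catabolic = total - anabolic - unaccounted`.
#'
#' @param context a [catabolic_context()].
#' @return Named numeric vector `total`, `anabolic`, `unaccounted`,
#'   `catabolic` in mmol substrate per g biomass.
#' @export
carbon_partition <- function(context) {
  stopifnot(inherits(context, "catabolic_context"))
  total <- 1000 / (context$yield * context$substrate_molar_mass)
  unacc <- context$unaccounted_fraction * total
  catab <- total - context$anabolic_substrate_demand - unacc
  if (catab < 0) {
    stop("inconsistent context: anabolic + unaccounted exceed total substrate demand")
  }
  c(total = total, anabolic = context$anabolic_substrate_demand,
    unaccounted = unacc, catabolic = catab)
}

#' Anabolic coverage of the catabolic PP_i demand
#'
#' Percentage of the catabolic PP_i requirement that net biosynthetic PP_i
#' can supply at Ppdk fraction `x`. When biosynthesis is itself a net PP_i
#' consumer (`x` above break-even) the coverage is 0 and the result
#' carries `attr(, "net_consumer") = TRUE`.
#'
#' @inheritParams total_ppi
#' @param context a [catabolic_context()].
#' @return Numeric percent with attribute `net_consumer`.
#' @export
anabolic_coverage <- function(composition, context, x) {
  part <- carbon_partition(context)
  demand <- part[["catabolic"]] * context$ppi_per_substrate(x)
  if (demand <= 0) stop("catabolic PP_i demand is zero")
  supply <- as.numeric(total_ppi(composition, x))
  if (supply < 0) {
    return(structure(0, net_consumer = TRUE))
  }
  structure(100 * supply / demand, net_consumer = FALSE)
}

#' Randomly perturb a biomass composition
#'
#' Robustness helper: each mass fraction is multiplied by an independent
#' uniform factor in `[1 - delta, 1 + delta]` (drawn on a grid of 1/1000
#' so coefficients stay exactly rational), the fractions are rescaled so
#' that together with the unchanged ash fraction they sum to 1, and each
#' macromolecule's PP_i coefficients are scaled proportionally to its mass
#' fraction change. Deterministic for a given seed; the caller's RNG state
#' is left untouched.
#'
#' @inheritParams total_ppi
#' @param relative_delta perturbation half-width, in `[0, 0.2]`.
#' @param seed integer seed.
#' @return A new [biomass_composition()].
#' @export
perturb_composition <- function(composition, relative_delta, seed) {
  stopifnot(relative_delta >= 0, relative_delta <= 0.2)
  if (relative_delta == 0) return(composition)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- nrow(composition$components)
  k <- round(relative_delta * 1000)
  u <- rq(sample.int(2L * k + 1L, n, replace = TRUE) - 1L - k, 1000) + rq(1)
  mf <- as_rq(composition$components$mass_fraction)
  mf_new <- mf * u
  factor <- u
  # the ash fraction absorbs the change; if it cannot (would go negative),
  # damp all fractions by a coarse rational factor first so coefficients
  # stay exactly representable
  ash_new <- rq(1) - sum(mf_new)
  if (ash_new < 0) {
    s <- rq(floor(1000 / as.numeric(sum(mf_new))), 1000)
    mf_new <- mf_new * s
    factor <- u * s
    ash_new <- rq(1) - sum(mf_new)
  }
  comp <- composition
  comp$components$mass_fraction <- as.numeric(mf_new)
  comp$ash_fraction <- as.numeric(ash_new)
  comp$a <- composition$a * factor
  comp$b <- composition$b * factor
  comp$biosyn_a <- NULL; comp$biosyn_b <- NULL; comp$polym_a <- NULL
  comp
}
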