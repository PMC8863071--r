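#' Exchangeable currency metabolites
#'
#' Default set of currency species that a net-conversion target may
#' exchange with the environment. Declared as data, not hard-coded into the
#' algorithms, so model files can override it.
#' @export
CURRENCY_IDS <- c("atp", "adp", "amp", "gtp", "gdp", "pi", "ppi",
                  "h2o", "h", "nad", "nadh", "nadp", "nadph", "co2",
                  "atp_eq", "adp_eq")

# adenylate / guanylate pools handled by energy-equivalent folding
.ENERGY_IDS <- c("atp", "adp", "amp", "gtp", "gdp", "atp_eq", "adp_eq")

#' Metabolite registry
#'
#' @param id character vector of unique, whitespace-free, case-sensitive
#'   tokens.
#' @param name free-text names.
#' @param P,C phosphorus / carbon atom counts; `NA` when unannotated.
#' @param currency logical, member of the exchangeable-currency set.
#' @return data.frame of class `ppi_metabolites`.
#' @export
metabolite_table <- function(id, name = id, P = NA_real_, C = NA_real_,
                             currency = id %in% CURRENCY_IDS) {
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate metabolite ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("\\s", id))) stop("metabolite ids must not contain whitespace")
  df <- data.frame(id = id, name = rep_len(name, n),
                   P = rep_len(as.numeric(P), n), C = rep_len(as.numeric(C), n),
                   currency = rep_len(as.logical(currency), n),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$P) & df$P < 0) || any(!is.na(df$C) & df$C < 0)) {
    stop("element counts must be non-negative")
  }
  class(df) <- c("ppi_metabolites", "data.frame")
  df
}

#' Stoichiometric model: metabolite registry plus ordered reactions
#'
#' @param metabolites a `ppi_metabolites` table, see [metabolite_table()].
#' @param reactions list of `ppi_reaction` objects with unique ids.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions) {
  stopifnot(inherits(metabolites, "ppi_metabolites"), is.list(reactions))
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  missing <- setdiff(used, metabolites$id)
  if (length(missing)) {
    stop("reactions reference unregistered metabolites: ",
         paste(missing, collapse = ", "))
  }
  names(reactions) <- ids
  structure(list(metabolites = metabolites, reactions = reactions),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) print(r)
  invisible(x)
}

model_reaction_ids <- function(model) names(model$reactions)

#' Add reactions (and any new metabolites) to a model
#'
#' New metabolites referenced by the added reactions are registered with
#' `NA` element counts and non-currency status unless present in `extra_mets`.
#'
#' @param model a `metabolic_model`.
#' @param reactions list of `ppi_reaction`.
#' @param extra_mets optional `ppi_metabolites` rows for new species.
#' @return The augmented `metabolic_model`.
#' @export
model_add_reactions <- function(model, reactions, extra_mets = NULL) {
  mets <- model$metabolites
  if (!is.null(extra_mets)) {
    new <- extra_mets[!(extra_mets$id %in% mets$id), , drop = FALSE]
    mets <- rbind(mets, new)
    class(mets) <- c("ppi_metabolites", "data.frame")
  }
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  unknown <- setdiff(used, mets$id)
  if (length(unknown)) {
    mets <- rbind(mets, metabolite_table(unknown))
    class(mets) <- c("ppi_metabolites", "data.frame")
  }
  metabolic_model(mets, c(model$reactions, reactions))
}

#' Check elemental balance of a net conversion
#'
#' Water and protons are excluded by default: the accounting conventions of
#' PP_i-dependent glycolysis track high-energy phosphate and carbon, and
#' net-conversion targets do not constrain H2O/H+.
#'
#' @param net stoichiometry map.
#' @param element `"phosphorus"` or `"carbon"`.
#' @param metabolites `ppi_metabolites` table carrying the counts.
#' @param exclude ids ignored in the balance (default water and protons).
#' @return `TRUE` iff the signed element sum is exactly zero.
#' @export
check_balance <- function(net, element = c("phosphorus", "carbon"),
                          metabolites, exclude = c("h2o", "h", "h_in", "h_out")) {
  element <- match.arg(element)
  col <- if (element == "phosphorus") "P" else "C"
  net <- stoich_drop(stoich_canonical(net), exclude)
  if (length(net) == 0L) return(TRUE)
  idx <- match(names(net), metabolites$id)
  counts <- metabolites[[col]][idx]
  bad <- names(net)[is.na(counts)]
  if (length(bad)) {
    stop("metabolites lacking ", element, " annotation: ",
         paste(bad, collapse = ", "))
  }
  total <- sum(net * rq(counts))
  total == 0
}

#' Fold adenylates and guanylates into ATP-equivalent currency
#'
#' GTP/GDP are merged into ATP_eq/ADP_eq through the nucleoside-diphosphate
#' kinase relation (ATP + GDP <-> ADP + GTP), and AMP is eliminated by
#' applying the adenylate-kinase reaction (2 ADP <-> ATP + AMP) at exactly
#' the multiplier that zeroes the AMP coefficient. The result carries only
#' `atp_eq`/`adp_eq` among the energy nucleotides, the operation is
#' idempotent, and the total count of high-energy phosphoanhydride bonds
#' (2 per NTP, 1 per NDP, 1 per PP_i) is conserved exactly.
#'
#' @param net stoichiometry map.
#' @return Folded stoichiometry map.
#' @examples
#' fold_energy_equivalents(stoich(c("atp", "amp", "ppi"), c(-1, 1, 1)))
#' # atp_eq -2, adp_eq +2, ppi +1: direct NTP -> NMP + PP_i hydrolysis costs
#' # two ATP equivalents per PP_i once adenylate kinase rebalances the pools.
#' @export
fold_energy_equivalents <- function(net) {
  s <- stoich_canonical(net)
  atp <- stoich_coef(s, "atp") + stoich_coef(s, "gtp") + stoich_coef(s, "atp_eq")
  adp <- stoich_coef(s, "adp") + stoich_coef(s, "gdp") + stoich_coef(s, "adp_eq")
  amp <- stoich_coef(s, "amp")
  rest <- stoich_drop(s, .ENERGY_IDS)
  # adenylate kinase at multiplier -amp: removes AMP, moves one high-energy
  # bond between the ATP and ADP pools
  atp <- atp - amp
  adp <- adp + amp + amp
  out <- c(rest, stoich(c("atp_eq", "adp_eq"), c(atp, adp)))
  stoich_canonical(out)
}

#' Total high-energy phosphoanhydride bond count of a map
#'
#' Bookkeeping helper: NTPs carry 2, NDPs and PP_i carry 1, NMPs and P_i 0.
#' [fold_energy_equivalents()] conserves this quantity exactly.
#'
#' @param net stoichiometry map.
#' @return An `rq` scalar.
#' @export
phosphoanhydride_count <- function(net) {
  w <- c(atp = 2, gtp = 2, atp_eq = 2, adp = 1, gdp = 1, adp_eq = 1,
         amp = 0, ppi = 1)
  s <- stoich_canonical(net)
  keep <- names(s) %in% names(w)
  if (!any(keep)) return(rq(0))
  s <- s[keep]
  sum(s * rq(w[names(s)]))
}

# ---- tab-separated model files ------------------------------------------

#' Read / write reaction and metabolite tables
#'
#' Reaction tables are tab-separated with columns
#' `id  equation  reversible(0/1)  enzyme  tags` (tags comma-separated,
#' may be empty); metabolite tables have columns
#' `id  name  P  C  currency(0/1)` where `P`/`C` may be empty. Lines
#' starting with `#` are comments. Files are UTF-8.
#'
#' @param path file path.
#' @return `read_reaction_table()` a list of `ppi_reaction`;
#'   `read_metabolite_table()` a `ppi_metabolites` table.
#' @export
read_reaction_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed reaction table line: '", lines[i], "'")
    tags <- if (length(f) >= 5L && nzchar(f[5])) strsplit(f[5], ",")[[1]] else character()
    out[[i]] <- parse_reaction_equation(f[2], id = f[1],
                                        reversible = f[3] %in% c("1", "true", "TRUE"),
                                        enzyme = if (length(f) >= 4L) f[4] else "",
                                        tags = trimws(tags))
  }
  names(out) <- vapply(out, function(r) r$id, character(1))
  out
}

#' @rdname read_reaction_table
#' @export
read_metabolite_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  getcol <- function(i, default = "") {
    vapply(f, function(x) if (length(x) >= i) x[i] else default, character(1))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  metabolite_table(id = getcol(1), name = getcol(2),
                   P = num_or_na(getcol(3)), C = num_or_na(getcol(4)),
                   currency = getcol(5) %in% c("1", "true", "TRUE"))
}

#' @rdname read_reaction_table
#' @param reactions list of `ppi_reaction`.
#' @export
write_reaction_table <- function(reactions, path) {
  lines <- vapply(reactions, function(r) {
    paste(r$id, format_reaction_equation(r$stoich, r$reversible),
          if (r$reversible) "1" else "0", r$enzyme,
          paste(r$tags, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("# id\tequation\treversible\tenzyme\ttags", lines), path)
  invisible(path)
}

#' @rdname read_reaction_table
#' @param metabolites `ppi_metabolites` table.
#' @export
write_metabolite_table <- function(metabolites, path) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE))
  lines <- paste(metabolites$id, metabolites$name, fmt(metabolites$P),
                 fmt(metabolites$C), as.integer(metabolites$currency),
                 sep = "\t")
  writeLines(c("# id\tname\tP\tC\tcurrency", lines), path)
  invisible(path)
}
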