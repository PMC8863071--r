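#' Stoichiometry maps
#'
#' A stoichiometry map ("stoich") is a named [rq] vector mapping metabolite
#' ids to signed rational coefficients: negative = consumed, positive =
#' produced. Zero entries are never stored, so two maps describing the same
#' net conversion compare identical.
#'
#' @param ids character vector of metabolite ids.
#' @param coefs coefficients; anything [as_rq()] accepts.
#' @return A named `rq` vector with no zero entries.
#' @examples
#' stoich(c("atp", "pi", "adp", "ppi"), c(-1, -1, 1, 1))
#' @export
stoich <- function(ids = character(), coefs = numeric()) {
  stopifnot(length(ids) == length(coefs))
  q <- as_rq(coefs)
  names(q) <- ids
  stoich_canonical(q)
}

#' @rdname stoich
#' @param q named `rq` vector to canonicalise (duplicates merged, zeros
#'   dropped, ids sorted).
#' @export
stoich_canonical <- function(q) {
  if (length(q) == 0L) return(structure(numeric(0), den = numeric(0),
                                        names = character(0), class = "rq"))
  ids <- sort(unique(names(q)), method = "radix")
  out <- rq(rep(0, length(ids)))
  names(out) <- ids
  for (i in seq_along(q)) {
    j <- match(names(q)[i], ids)
    out[j] <- out[j] + q[i]
  }
  keep <- !rq_zero(out)
  out[keep]
}

# a + m * b over rationals
stoich_accumulate <- function(a, b, m = rq(1)) {
  stoich_canonical(c(a, m * b))
}

#' @rdname stoich
#' @param x object to test.
#' @export
is_stoich <- function(x) inherits(x, "rq") && (length(x) == 0L || !is.null(names(x)))

#' @rdname stoich
#' @param s stoichiometry map.
#' @param id metabolite id whose coefficient to extract (`rq(0)` when
#'   absent).
#' @export
stoich_coef <- function(s, id) {
  i <- match(id, names(s))
  if (is.na(i)) rq(0) else s[i]
}

#' @rdname stoich
#' @param a,b stoichiometry maps to compare for exact equality.
#' @export
stoich_equal <- function(a, b) {
  a <- stoich_canonical(a); b <- stoich_canonical(b)
  length(a) == length(b) && all(names(a) == names(b)) && all(a == b)
}

#' @rdname stoich
#' @export
stoich_drop <- function(s, ids) {
  s[!(names(s) %in% ids)]
}

#' Reactions
#'
#' A reaction couples an id and stoichiometry map with a reversibility flag
#' and optional enzyme label and tags. Every reaction must both consume and
#' produce something.
#'
#' @param id reaction id (token, no whitespace).
#' @param stoich a stoichiometry map, see [stoich()].
#' @param reversible logical.
#' @param enzyme free-text enzyme label.
#' @param tags character vector of tags.
#' @return An object of class `ppi_reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE, enzyme = "", tags = character()) {
  stopifnot(is.character(id), length(id) == 1L, !grepl("\\s", id))
  s <- stoich_canonical(stoich)
  if (!any(s < 0) || !any(s > 0)) {
    stop("reaction '", id, "' has net-empty or one-sided stoichiometry")
  }
  structure(list(id = id, stoich = s, reversible = isTRUE(reversible),
                 enzyme = enzyme, tags = as.character(tags)),
            class = "ppi_reaction")
}

#' @export
print.ppi_reaction <- function(x, ...) {
  cat(x$id, ": ", format_reaction_equation(x$stoich, x$reversible),
      if (nzchar(x$enzyme)) paste0("  [", x$enzyme, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Parse a reaction equation
#'
#' Grammar: `term (+ term)* (-> | <->) term (+ term)*` where a term is an
#' optional positive rational coefficient (integer, fraction like `3/2`, or
#' short decimal) followed by a metabolite id. Left-hand terms get negative
#' coefficients, right-hand positive; a metabolite appearing on both sides
#' keeps its net coefficient. `<->` marks the reaction reversible and
#' overrides the `reversible` argument.
#'
#' @param text equation string, e.g. `"atp + pi -> adp + ppi"`.
#' @param id reaction id.
#' @param reversible reversibility flag used with the `->` arrow.
#' @inheritParams reaction
#' @return A `ppi_reaction`.
#' @examples
#' parse_reaction_equation("g1p + atp -> adpg + ppi", "ags", enzyme = "Ags")
#' @export
parse_reaction_equation <- function(text, id, reversible = FALSE,
                                    enzyme = "", tags = character()) {
  stopifnot(is.character(text), length(text) == 1L)
  rev_arrow <- grepl("<->", text, fixed = TRUE)
  sides <- if (rev_arrow) strsplit(text, "<->", fixed = TRUE)[[1]] else
    strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("malformed reaction equation (expected exactly one '->' or '<->'): '",
         text, "'")
  }
  lhs <- .parse_side(sides[1], text)
  rhs <- .parse_side(sides[2], text)
  net <- stoich_canonical(c(-lhs, rhs))
  if (length(net) == 0L) {
    stop("net-empty stoichiometry in reaction '", id, "': '", text, "'")
  }
  reaction(id, net, reversible = rev_arrow || isTRUE(reversible),
           enzyme = enzyme, tags = tags)
}

.coef_re <- "^(?:[0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?)$"

.parse_side <- function(side, text) {
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  ids <- character(0)
  coefs <- list()
  for (tm in terms) {
    toks <- strsplit(trimws(tm), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) stop("empty term in reaction equation: '", text, "'")
    if (length(toks) == 2L) {
      if (!grepl(.coef_re, toks[1])) {
        stop("malformed coefficient token '", toks[1], "' in '", text, "'")
      }
      cf <- rq_parse(toks[1])
      met <- toks[2]
    } else if (length(toks) == 1L) {
      cf <- rq(1)
      met <- toks[1]
    } else {
      stop("malformed term '", trimws(tm), "' in '", text, "'")
    }
    if (grepl(.coef_re, met)) {
      stop("expected metabolite id, found number '", met, "' in '", text, "'")
    }
    if (cf <= 0) stop("non-positive coefficient in '", text, "'")
    ids <- c(ids, met)
    coefs <- c(coefs, list(cf))
  }
  q <- do.call(c, coefs)
  names(q) <- ids
  q
}

#' Format a stoichiometry map as an equation string
#'
#' Inverse of [parse_reaction_equation()]: negative entries become the
#' left-hand side, positive the right. Parsing the result reproduces the
#' map exactly.
#'
#' @param s stoichiometry map.
#' @param reversible use `<->` instead of `->`.
#' @return A single string.
#' @export
format_reaction_equation <- function(s, reversible = FALSE) {
  s <- stoich_canonical(s)
  fmt1 <- function(q) {
    cf <- abs(q)
    term <- names(q)
    pre <- format(cf)
    ifelse(pre == "1", term, paste(pre, term))
  }
  lhs <- s[s < 0]
  rhs <- s[s > 0]
  paste(paste(fmt1(lhs), collapse = " + "),
        if (reversible) "<->" else "->",
        paste(fmt1(rhs), collapse = " + "))
}

#' Compose reactions into a net conversion
#'
#' Entrywise rational sum of multiplier-scaled reaction stoichiometries,
#' with exact cancellation; zero entries are dropped. This realises lumped
#' reactions. A negative multiplier runs the reaction in reverse, which is
#' an error for irreversible reactions.
#'
#' @param reactions list of `ppi_reaction`.
#' @param multipliers rational multipliers, same length (default all 1).
#' @return A stoichiometry map.
#' @examples
#' ags  <- parse_reaction_equation("g1p + atp -> adpg + ppi", "ags")
#' glgA <- parse_reaction_equation("adpg -> glyc + adp", "glgA")
#' glgP <- parse_reaction_equation("glyc + pi -> g1p", "glgP")
#' combine(list(ags, glgA, glgP))   # atp + pi -> adp + ppi
#' @export
combine <- function(reactions, multipliers = rep(1, length(reactions))) {
  stopifnot(length(reactions) == length(multipliers))
  if (length(reactions) == 0L) return(stoich())
  m <- as_rq(multipliers)
  out <- stoich()
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    stopifnot(inherits(r, "ppi_reaction"))
    if (m[i] < 0 && !r$reversible) {
      stop("reaction '", r$id, "' is irreversible but was given multiplier ",
           format(m[i]))
    }
    out <- stoich_accumulate(out, r$stoich, m[i])
  }
  out
}
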