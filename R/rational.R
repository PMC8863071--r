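#' Exact rational vectors
#'
#' Stoichiometric coefficients are kept as exact rationals so that reaction
#' composition and energy-equivalent folding cancel without floating-point
#' residue. An `rq` vector stores integral numerators as its data and the
#' (positive, reduced) denominators in an attribute; numerators and
#' denominators are doubles but always hold exact integers, which is safe up
#' to 2^53. Arithmetic that would leave that range aborts rather than
#' silently losing exactness.
#'
#' @param num numeric vector of integral numerators (or a fraction when
#'   `den` is given).
#' @param den numeric vector of integral denominators, recycled against
#'   `num`. Must be non-zero.
#' @return An `rq` vector.
#' @examples
#' rq(1, 2) + rq(1, 3)   # 5/6
#' sum(rq(c(1, -1), c(3, 3)))
#' @export
rq <- function(num, den = 1) {
  if (length(num) == 0L) {
    return(structure(numeric(0), den = numeric(0), class = "rq"))
  }
  n <- length(num)
  den <- rep_len(as.numeric(den), n)
  num <- as.numeric(num)
  if (any(den == 0)) stop("rational with zero denominator")
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rq() expects integral numerators and denominators")
  }
  .rq_reduce(num, den)
}

.RQ_MAX <- 2^52

.rq_reduce <- function(num, den, nms = NULL) {
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  if (any(abs(num) > .RQ_MAX) || any(den > .RQ_MAX)) {
    stop("rational overflow: coefficient outside exact integer range")
  }
  structure(num, den = den, names = nms, class = "rq")
}

# vectorised Euclid on non-negative integral doubles
.gcd <- function(a, b) {
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(t != 0, t, a)
  }
  a
}

.rq_num <- function(x) as.numeric(unclass(x))
.rq_den <- function(x) attr(x, "den")

#' @export
as.double.rq <- function(x, ...) .rq_num(x) / .rq_den(x)

#' Convert to an exact rational vector
#'
#' Integers convert exactly. Fractional doubles are converted by
#' continued-fraction approximation with a bounded denominator and the
#' conversion is rejected unless it is exact at that bound; this admits the
#' usual short decimals and simple fractions (0.5, 0.21, 2/3 within 1e-12)
#' while refusing genuinely irrational input.
#'
#' @param x numeric or `rq` vector, or character like `"3/2"`.
#' @param max_den largest denominator accepted when converting fractional
#'   doubles.
#' @return An `rq` vector.
#' @export
as_rq <- function(x, max_den = 1e6) {
  if (inherits(x, "rq")) return(x)
  if (is.character(x)) return(rq_parse(x))
  nms <- names(x)
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    fr <- .approx_fraction(x[[i]], max_den)
    if (is.null(fr)) {
      stop(sprintf("cannot represent %g exactly as a rational with denominator <= %g",
                   x[[i]], max_den))
    }
    num[i] <- fr[1]
    den[i] <- fr[2]
  }
  .rq_reduce(num, den, nms)
}

# best rational approximation by continued fractions; NULL unless exact
.approx_fraction <- function(x, max_den, tol = 1e-9) {
  if (x == round(x)) return(c(x, 1))
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) return(NULL)
    if (abs(x - h / k) < tol / k) return(c(h, k))
    frac <- b - a
    if (frac < 1e-14) return(NULL)
    b <- 1 / frac
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
  }
}

#' @rdname as_rq
#' @export
rq_parse <- function(x) {
  nms <- names(x)
  parts <- regmatches(x, regexec("^\\s*(-?[0-9]+(?:\\.[0-9]+)?)(?:\\s*/\\s*(-?[0-9]+))?\\s*$", x))
  num <- den <- numeric(length(x))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) == 0L || p[2] == "") stop("malformed rational: '", x[[i]], "'")
    if (grepl(".", p[2], fixed = TRUE)) {
      dec <- sub("^-?[0-9]+\\.", "", p[2])
      den[i] <- 10^nchar(dec)
      num[i] <- round(as.numeric(p[2]) * den[i])
    } else {
      num[i] <- as.numeric(p[2])
      den[i] <- 1
    }
    if (p[3] != "") den[i] <- den[i] * as.numeric(p[3])
  }
  .rq_reduce(num, den, nms)
}

.rq_coerce2 <- function(e) {
  if (inherits(e, "rq")) return(e)
  if (is.numeric(e)) {
    if (any(e != round(e))) {
      stop("implicit coercion of fractional doubles to rq is not allowed; use as_rq()")
    }
    return(rq(e))
  }
  stop("cannot combine rq with ", class(e)[1])
}

#' @export
Ops.rq <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(.rq_reduce(-.rq_num(.rq_coerce2(e1)),
                                           .rq_den(.rq_coerce2(e1)),
                                           names(e1)))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rq")
  }
  a <- .rq_coerce2(e1); b <- .rq_coerce2(e2)
  an <- .rq_num(a); ad <- .rq_den(a)
  bn <- .rq_num(b); bd <- .rq_den(b)
  n <- max(length(an), length(bn))
  an <- rep_len(an, n); ad <- rep_len(ad, n)
  bn <- rep_len(bn, n); bd <- rep_len(bd, n)
  nms <- if (!is.null(names(e1)) && length(e1) == n) names(e1) else
    if (!is.null(names(e2)) && length(e2) == n) names(e2) else NULL
  # gcd-aware forms keep intermediates near the lcm scale instead of the
  # denominator product, postponing overflow
  g <- .gcd(ad, bd)
  gm1 <- .gcd(abs(an), bd); gm1[gm1 == 0] <- 1
  gm2 <- .gcd(abs(bn), ad); gm2[gm2 == 0] <- 1
  switch(.Generic,
    "+" = .rq_reduce(an * (bd / g) + bn * (ad / g), (ad / g) * bd, nms),
    "-" = .rq_reduce(an * (bd / g) - bn * (ad / g), (ad / g) * bd, nms),
    "*" = .rq_reduce((an / gm1) * (bn / gm2), (ad / gm2) * (bd / gm1), nms),
    "/" = {
      if (any(bn == 0)) stop("rational division by zero")
      .rq_reduce(an * bd, ad * bn, nms)
    },
    "==" = an * bd == bn * ad,
    "!=" = an * bd != bn * ad,
    "<"  = an * bd <  bn * ad,
    "<=" = an * bd <= bn * ad,
    ">"  = an * bd >  bn * ad,
    ">=" = an * bd >= bn * ad,
    stop("operation ", .Generic, " not defined for rq")
  )
}

#' @export
Math.rq <- function(x, ...) {
  if (.Generic == "abs") return(.rq_reduce(abs(.rq_num(x)), .rq_den(x), names(x)))
  stop("function ", .Generic, " not defined for rq")
}

#' @export
Summary.rq <- function(..., na.rm = FALSE) {
  args <- lapply(list(...), .rq_coerce2)
  x <- do.call(c, args)
  switch(.Generic,
    sum = {
      out <- rq(0)
      for (i in seq_along(x)) out <- out + x[i]
      out
    },
    min = x[which.min(as.numeric(x))],
    max = x[which.max(as.numeric(x))],
    stop("function ", .Generic, " not defined for rq")
  )
}

#' @export
length.rq <- function(x) length(unclass(x))

#' @export
`[.rq` <- function(x, i) {
  if (is.character(i)) i <- match(i, names(x))
  if (is.logical(i)) i <- which(rep_len(i, length(x)))
  structure(unclass(x)[i], den = .rq_den(x)[i],
            names = names(x)[i], class = "rq")
}

#' @export
`[<-.rq` <- function(x, i, value) {
  value <- .rq_coerce2(value)
  num <- .rq_num(x); den <- .rq_den(x); nms <- names(x)
  num[i] <- .rq_num(value)
  den[i] <- .rq_den(value)
  structure(num, den = den, names = nms, class = "rq")
}

#' @export
c.rq <- function(...) {
  args <- lapply(list(...), .rq_coerce2)
  structure(unlist(lapply(args, .rq_num)),
            den = unlist(lapply(args, .rq_den)),
            names = {
              nm <- unlist(lapply(args, function(a) {
                if (is.null(names(a))) rep("", length(a)) else names(a)
              }))
              if (all(nm == "")) NULL else nm
            },
            class = "rq")
}

#' @export
rep.rq <- function(x, ...) {
  idx <- rep(seq_along(x), ...)
  x[idx]
}

#' @export
format.rq <- function(x, ...) {
  num <- .rq_num(x); den <- .rq_den(x)
  ifelse(den == 1, format(num, scientific = FALSE, trim = TRUE),
         paste0(format(num, scientific = FALSE, trim = TRUE), "/",
                format(den, scientific = FALSE, trim = TRUE)))
}

#' @export
print.rq <- function(x, ...) {
  out <- format(x)
  names(out) <- names(x)
  print(out, quote = FALSE)
  invisible(x)
}

#' @export
as.character.rq <- function(x, ...) format(x)

#' Test rational entries for exact zero
#' @param x an `rq` vector.
#' @return Logical vector.
#' @export
rq_zero <- function(x) .rq_num(x) == 0
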