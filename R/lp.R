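# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Written in-package because the stoichiometric LPs this package solves are
# small (tens of rows and columns) but highly degenerate (many zero
# right-hand sides), a regime where naive pivoting rules cycle or stall.
# Bland's rule guarantees termination; solutions are later snapped to
# rationals and re-verified exactly by the callers.

#' Solve a small linear program
#'
#' Minimizes `obj %*% x` subject to `A_eq x = b_eq`, `A_le x <= b_le`,
#' `x >= 0`.
#'
#' @param obj objective coefficients.
#' @param A_eq,b_eq equality constraints (may be NULL).
#' @param A_le,b_le inequality constraints (may be NULL).
#' @param tol pivot / feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x`, `value`.
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     tol = 1e-9) {
  n <- length(obj)
  A <- matrix(0, 0, n); b <- numeric(0)
  if (!is.null(A_le) && nrow(A_le) > 0) {
    # slack variables turn inequalities into equalities
    ns <- nrow(A_le)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(A_le, diag(ns)))
    b <- c(b, b_le)
    obj <- c(obj, rep(0, ns))
  }
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    A_eq2 <- cbind(A_eq, matrix(0, nrow(A_eq), ncol(A) - n))
    A <- rbind(A_eq2, A)
    b <- c(b_eq, b)
  }
  m <- nrow(A); nv <- ncol(A)
  if (m == 0L) {
    return(list(status = "optimal", x = rep(0, n), value = 0))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1: artificial basis
  Tm <- cbind(A, diag(m), b)
  basis <- nv + seq_len(m)
  cost1 <- c(rep(0, nv), rep(1, m))
  res <- .simplex_iterate(Tm, basis, cost1, tol)
  if (res$status == "unbounded") return(list(status = "infeasible"))
  Tm <- res$Tm; basis <- res$basis
  if (sum(cost1[basis] * Tm[, ncol(Tm)]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  # drive remaining artificials out of the basis; drop redundant rows
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > nv) {
      piv <- which(abs(Tm[i, seq_len(nv)]) > tol)
      if (length(piv) == 0L) { keep[i] <- FALSE; next }
      Tm <- .pivot(Tm, i, piv[1])
      basis[i] <- piv[1]
    }
  }
  Tm <- Tm[keep, , drop = FALSE]
  basis <- basis[keep]
  # bar artificial columns from phase 2
  Tm <- Tm[, c(seq_len(nv), ncol(Tm)), drop = FALSE]
  cost2 <- c(obj)
  res <- .simplex_iterate(Tm, basis, cost2, tol)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  Tm <- res$Tm; basis <- res$basis
  x <- rep(0, nv)
  x[basis] <- Tm[, ncol(Tm)]
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(obj[seq_len(nv)] * x))
}

.pivot <- function(Tm, r, cidx) {
  Tm[r, ] <- Tm[r, ] / Tm[r, cidx]
  other <- setdiff(seq_len(nrow(Tm)), r)
  if (length(other)) {
    Tm[other, ] <- Tm[other, , drop = FALSE] -
      outer(Tm[other, cidx], Tm[r, ])
  }
  Tm
}

.simplex_iterate <- function(Tm, basis, cost, tol, max_iter = 20000L) {
  m <- nrow(Tm); ncols <- ncol(Tm) - 1L
  for (iter in seq_len(max_iter)) {
    # reduced costs: r = c - c_B' B^-1 A (computed from the current tableau)
    cb <- cost[basis]
    red <- cost - as.vector(crossprod(Tm[, seq_len(ncols), drop = FALSE], cb))
    red[basis] <- 0
    entering <- which(red < -tol)
    if (length(entering) == 0L) {
      return(list(status = "optimal", Tm = Tm, basis = basis))
    }
    j <- min(entering)                       # Bland: smallest index enters
    col <- Tm[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "unbounded", Tm = Tm, basis = basis))
    }
    ratio <- Tm[pos, ncols + 1L] / col[pos]
    best <- pos[ratio <= min(ratio) + tol]
    r <- best[which.min(basis[best])]        # Bland: smallest basis leaves
    Tm <- .pivot(Tm, r, j)
    basis[r] <- j
  }
  stop("simplex failed to converge")
}
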