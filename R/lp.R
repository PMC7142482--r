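# Dense two-phase primal simplex for the small linear programs arising in
# flux analysis. Bland's rule (smallest-index entering and leaving choices)
# guarantees termination on the degenerate polytopes that steady-state
# networks routinely produce (zero-width bounds, all-zero right-hand sides).
# Problems are solved in standard form: min c'x s.t. A x = b, x >= 0.

SIMPLEX_TOL <- 1e-9

# one pivoting pass over a tableau already in canonical form
# (A[, basis] = I, b >= 0). Returns the optimal tableau or "unbounded".
simplexPivot <- function(A, b, cost, basis) {
  m <- nrow(A)
  repeat {
    red <- cost - as.numeric(matrix(cost[basis], 1) %*% A)
    enter <- which(red < -SIMPLEX_TOL)
    if (!length(enter))
      return(list(A = A, b = b, basis = basis, status = "optimal"))
    enter <- enter[1]                       # Bland: smallest index enters
    col <- A[, enter]
    ratios <- ifelse(col > SIMPLEX_TOL, b / col, Inf)
    if (all(!is.finite(ratios)))
      return(list(status = "unbounded"))
    rows <- which(ratios <= min(ratios) + SIMPLEX_TOL &
                  is.finite(ratios))
    leave <- rows[which.min(basis[rows])]   # Bland: smallest basic leaves
    piv <- A[leave, enter]
    A[leave, ] <- A[leave, ] / piv
    b[leave] <- b[leave] / piv
    for (i in seq_len(m)) {
      if (i == leave) next
      f <- A[i, enter]
      if (abs(f) > 1e-13) {
        A[i, ] <- A[i, ] - f * A[leave, ]
        b[i] <- b[i] - f * b[leave]
        if (b[i] < 0 && b[i] > -1e-10) b[i] <- 0
      }
    }
    basis[leave] <- enter
  }
}

# min cost'x s.t. A x = b, x >= 0 (b of any sign)
# -> list(x, value, status in {"optimal", "infeasible", "unbounded"})
simplexLP <- function(cost, A, b) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (m == 0L)
    return(list(x = rep(0, n), value = 0, status = "optimal"))
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1: artificial basis
  A1 <- cbind(A, diag(m))
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- simplexPivot(A1, b, cost1, basis)
  if (p1$status != "optimal" || sum(p1$b[p1$basis > n]) > 1e-7)
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  A1 <- p1$A; b <- p1$b; basis <- p1$basis
  # drive leftover artificials out of the basis or drop redundant rows
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    cand <- which(abs(A1[i, seq_len(n)]) > SIMPLEX_TOL)
    if (length(cand)) {
      enter <- cand[1]
      piv <- A1[i, enter]
      A1[i, ] <- A1[i, ] / piv; b[i] <- b[i] / piv
      for (k in seq_len(m)) {
        if (k == i) next
        f <- A1[k, enter]
        if (abs(f) > 1e-13) {
          A1[k, ] <- A1[k, ] - f * A1[i, ]
          b[k] <- b[k] - f * b[i]
        }
      }
      basis[i] <- enter
    } else keep[i] <- FALSE                  # redundant constraint row
  }
  A2 <- A1[keep, seq_len(n), drop = FALSE]
  b2 <- b[keep]; basis2 <- basis[keep]
  p2 <- simplexPivot(A2, b2, cost, basis2)
  if (p2$status != "optimal")
    return(list(x = NULL, value = NA_real_, status = "unbounded"))
  x <- rep(0, n)
  x[p2$basis] <- p2$b
  list(x = x, value = sum(cost * x), status = "optimal")
}
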