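# Independent oracles used to cross-check the package's numerical routines.
# Each is a direct, brute-force computation that shares no code path with
# the implementation it verifies.

# candidate lags in the implementation's tie-break order
oracleLagOrder <- function(maxShift) {
  lags <- 0L
  for (k in seq_len(maxShift)) lags <- c(lags, -k, k)
  lags
}

# exhaustive circular cross-correlation search: returns the corrective lag
# (the shift to apply to s so it best matches ref)
exhaustiveLagOracle <- function(sInt, refInt, maxShift = 50L) {
  n <- length(sInt)
  best <- NULL; bestVal <- -Inf
  for (d in oracleLagOrder(min(maxShift, n - 1L))) {
    idx <- ((seq_len(n) - 1L - d) %% n) + 1L
    v <- sum(sInt * refInt[idx])
    if (is.infinite(bestVal) || v > bestVal + 1e-12 * max(1, abs(bestVal))) {
      bestVal <- v; best <- d
    }
  }
  -best
}

# one-way ANOVA F from explicit sums of squares
handFStatistic <- function(y, g) {
  g <- factor(g)
  means <- tapply(y, g, mean)
  counts <- tapply(y, g, length)
  ssb <- sum(counts * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (nlevels(g) - 1)
  msw <- ssw / (length(y) - nlevels(g))
  if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
}

# exhaustive hypergeometric upper tail: probability that a random
# |selected|-subset of the universe overlaps the pathway in >= k elements
enumerateHyperP <- function(universe, pathway, selectedSize, k) {
  if (k == 0L) return(1.0)
  combos <- utils::combn(length(universe), selectedSize)
  hits <- 0L
  pwIdx <- which(universe %in% pathway)
  for (j in seq_len(ncol(combos)))
    if (sum(combos[, j] %in% pwIdx) >= k) hits <- hits + 1L
  hits / ncol(combos)
}

# ---- tiny-LP vertex enumeration ---------------------------------------------
# Optimum of obj'v over {Aeq v = 0, lb <= v <= ub, ineqA'v >= ineqB} found by
# enumerating basic solutions: every vertex satisfies n linearly independent
# active constraints, so stack the equality rows with each combination of
# candidate actives (variable at a bound, or the inequality tight), solve,
# and keep the feasible solution with the best objective.
vertexOptimum <- function(obj, Aeq, lb, ub, ineqA = NULL, ineqB = NULL,
                         maximize = FALSE, tol = 1e-7) {
  n <- length(lb)
  Aeq <- as.matrix(Aeq)
  if (nrow(Aeq)) {
    q <- qr(t(Aeq))
    keep <- sort(q$pivot[seq_len(q$rank)])
    Aeq <- Aeq[keep, , drop = FALSE]
  }
  r <- nrow(Aeq)
  k <- n - r
  cands <- list()
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    cands[[length(cands) + 1L]] <- list(row = e, rhs = lb[i])
    if (ub[i] > lb[i])
      cands[[length(cands) + 1L]] <- list(row = e, rhs = ub[i])
  }
  if (!is.null(ineqA))
    cands[[length(cands) + 1L]] <- list(row = ineqA, rhs = ineqB)
  combos <- if (k == 0L) matrix(integer(0), nrow = 0, ncol = 1)
            else utils::combn(length(cands), k)
  bestVal <- if (maximize) -Inf else Inf
  bestV <- NULL
  for (j in seq_len(ncol(combos))) {
    sel <- combos[, j]
    M <- rbind(Aeq, t(vapply(cands[sel], `[[`, numeric(n), "row")))
    rhs <- c(rep(0, r), vapply(cands[sel], `[[`, numeric(1), "rhs"))
    if (k == 0L) { M <- Aeq; rhs <- rep(0, r) }
    if (qr(M)$rank < n) next
    v <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (nrow(Aeq) && max(abs(Aeq %*% v)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    if (!is.null(ineqA) && sum(ineqA * v) < ineqB - tol) next
    val <- sum(obj * v)
    if ((maximize && val > bestVal) || (!maximize && val < bestVal)) {
      bestVal <- val; bestV <- v
    }
  }
  list(value = bestVal, v = bestV,
       feasible = !is.null(bestV))
}

# FBA optimum by vertex enumeration
fbaOracle <- function(model) {
  n <- length(reactionIds(model))
  obj <- as.numeric(reactionIds(model) == objectiveReaction(model))
  lb <- pmax(model@lb, -1e3); ub <- pmin(model@ub, 1e3)
  vertexOptimum(obj, as.matrix(stoichiometry(model)), lb, ub,
                maximize = TRUE)
}

# GIMME inconsistency minimum by enumerating flux-direction patterns of the
# penalized reversible reactions; each pattern leaves a linear objective,
# solved by vertex enumeration under the maintained-objective constraint.
gimmeOracle <- function(model, rxnExpr, cutoff = 50,
                        objectiveFraction = 0.9) {
  rxnExpr <- rxnExpr[reactionIds(model)]
  zstar <- fbaOracle(model)$value
  stopifnot(zstar > 0)
  n <- length(reactionIds(model))
  lb <- pmax(model@lb, -1e3); ub <- pmin(model@ub, 1e3)
  S <- as.matrix(stoichiometry(model))
  w <- ifelse(!is.na(rxnExpr) & rxnExpr < cutoff, cutoff - rxnExpr, 0)
  iObj <- which(reactionIds(model) == objectiveReaction(model))
  ineqA <- numeric(n); ineqA[iObj] <- 1
  revPen <- which(w > 0 & lb < 0)
  signGrid <- if (length(revPen) == 0L) matrix(1, 1, 0)
              else as.matrix(expand.grid(rep(list(c(1, -1)),
                                             length(revPen))))
  best <- Inf
  for (p in seq_len(nrow(signGrid))) {
    lb2 <- lb; ub2 <- ub
    objv <- w
    for (t in seq_along(revPen)) {
      i <- revPen[t]
      if (signGrid[p, t] > 0) lb2[i] <- max(lb2[i], 0)
      else { ub2[i] <- min(ub2[i], 0); objv[i] <- -w[i] }
    }
    res <- vertexOptimum(objv, S, lb2, ub2, ineqA = ineqA,
                         ineqB = objectiveFraction * zstar,
                         maximize = FALSE)
    if (res$feasible && res$value < best) best <- res$value
  }
  best
}

# mean silhouette of a 2-group split on a 1-D score vector
silhouette1d <- function(scores, isGroup) {
  cl <- as.integer(isGroup) + 1L
  mean(cluster::silhouette(cl, dist(scores))[, "sil_width"])
}
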