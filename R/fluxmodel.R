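#' Constraint-based flux modeling
#'
#' Flux balance analysis (FBA) maximizes a designated objective
#' (biomass/maintenance) reaction over the steady-state polytope
#' `S v = 0, lb <= v <= ub`. GIMME builds a context-specific solution from
#' protein presence: reactions whose mapped expression falls below a cutoff
#' are penalized in proportion to the flux they carry (reversible reactions
#' are split into non-negative forward/backward parts so |v| is linear), and
#' the total penalty — the inconsistency score — is minimized subject to the
#' objective staying above a set fraction of its FBA optimum. Expression is
#' mapped onto reactions through boolean gene-protein-reaction rules with
#' AND as min and OR as max; in the boolean presence scheme observed genes
#' score 100 and unobserved 0.
#'
#' @name flux-modeling
NULL

# ---- GPR parsing ------------------------------------------------------------

tokenizeGPR <- function(rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) return(data.frame(token = character(0), pos = integer(0)))
  data.frame(token = regmatches(rule, gregexpr(pat, rule))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a gene-protein-reaction rule
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := '(' expr ')' | gene-id`; keywords are case-insensitive. An
#' empty or whitespace rule returns `NULL` (no gene association).
#'
#' @param rule rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return A nested list tree with nodes `list(op = "and"/"or", args = ...)`
#'   and leaves `list(op = "gene", id = ...)`, or `NULL` for an empty rule.
#' @export
parseGPR <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- tokenizeGPR(rule)
  i <- 1L
  peek <- function() if (i <= nrow(toks)) tolower(toks$token[i]) else ""
  fail <- function(msg) {
    pos <- if (i <= nrow(toks)) toks$pos[i] else nchar(rule) + 1L
    stop(sprintf("GPR parse error at position %d: %s (rule: '%s')",
                 pos, msg, rule), call. = FALSE)
  }
  parseExpr <- function() {
    node <- parseTerm()
    while (peek() == "or") {
      i <<- i + 1L
      node <- list(op = "or", args = list(node, parseTerm()))
    }
    node
  }
  parseTerm <- function() {
    node <- parseFactor()
    while (peek() == "and") {
      i <<- i + 1L
      node <- list(op = "and", args = list(node, parseFactor()))
    }
    node
  }
  parseFactor <- function() {
    tk <- peek()
    if (tk == "") fail("unexpected end of rule")
    if (tk == "(") {
      i <<- i + 1L
      node <- parseExpr()
      if (peek() != ")") fail("expected ')'")
      i <<- i + 1L
      return(node)
    }
    if (tk %in% c(")", "and", "or")) fail(sprintf("unexpected '%s'", tk))
    node <- list(op = "gene", id = toks$token[i])
    i <<- i + 1L
    node
  }
  tree <- parseExpr()
  if (i <= nrow(toks)) fail(sprintf("unexpected '%s'", toks$token[i]))
  tree
}

# genes referenced by a parsed rule tree
gprGenes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$id)
  unique(unlist(lapply(tree$args, gprGenes)))
}

evalGPRTree <- function(tree, values) {
  if (tree$op == "gene") {
    v <- values[tree$id]
    return(if (is.na(v)) 0 else unname(v))
  }
  vals <- vapply(tree$args, evalGPRTree, numeric(1), values = values)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Map gene expression onto reactions through GPR rules
#'
#' AND (enzyme complex) takes the minimum of its gene values, OR (isozymes)
#' the maximum. Reactions without a rule (spontaneous/transport) get `NA`,
#' an "unconstrained" marker treated as high expression downstream — no
#' protein evidence can be absent for them. Genes missing from the profile
#' are treated as 0.
#'
#' @param model a [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class] or named numeric vector.
#' @return Named numeric vector, one value (or `NA`) per reaction.
#' @export
reactionExpression <- function(model, profile) {
  values <- if (is(profile, "ExpressionProfile")) profile@values else profile
  missing <- setdiff(model@genes, names(values))
  if (length(missing))
    message("genes absent from profile treated as 0: ",
            paste(missing, collapse = ", "))
  out <- setNames(rep(NA_real_, length(model@reactions)), model@reactions)
  for (j in seq_along(model@reactions)) {
    tree <- parseGPR(model@gpr[j])
    if (!is.null(tree)) out[j] <- evalGPRTree(tree, values)
  }
  out
}

# ---- model validation -------------------------------------------------------

# collect structural failures; used both by validity and validateModel()
validateModelStructure <- function(m) {
  msgs <- character(0)
  nr <- length(m@reactions); nm <- length(m@metabolites)
  if (nrow(m@S) != nm || ncol(m@S) != nr)
    msgs <- c(msgs, sprintf("S is %dx%d but model declares %d metabolites x %d reactions",
                            nrow(m@S), ncol(m@S), nm, nr))
  if (length(m@lb) != nr || length(m@ub) != nr)
    msgs <- c(msgs, "lb/ub length must equal the number of reactions")
  else if (any(m@lb > m@ub))
    msgs <- c(msgs, paste0("lb > ub for reaction(s): ",
                           paste(m@reactions[m@lb > m@ub], collapse = ", ")))
  if (length(m@gpr) != nr)
    msgs <- c(msgs, "gpr length must equal the number of reactions")
  if (anyDuplicated(m@reactions))
    msgs <- c(msgs, "reaction ids must be unique")
  if (anyDuplicated(m@metabolites))
    msgs <- c(msgs, "metabolite ids must be unique")
  if (length(m@objective) != 1L)
    msgs <- c(msgs, "exactly one objective reaction is required")
  else if (!is.na(m@objective) && !(m@objective %in% m@reactions))
    msgs <- c(msgs, sprintf("objective reaction '%s' not in model",
                            m@objective))
  if (length(m@gpr) == nr) {
    for (j in seq_len(nr)) {
      tree <- tryCatch(parseGPR(m@gpr[j]), error = function(e) e)
      if (inherits(tree, "error")) {
        msgs <- c(msgs, sprintf("reaction '%s': %s", m@reactions[j],
                                conditionMessage(tree)))
      } else {
        und <- setdiff(gprGenes(tree), m@genes)
        if (length(und))
          msgs <- c(msgs, sprintf("reaction '%s' references undeclared gene(s): %s",
                                  m@reactions[j], paste(und, collapse = ", ")))
      }
    }
  }
  msgs
}

#' Validate a metabolic model, collecting all failures
#'
#' @param model a [MetabolicModel-class].
#' @return Invisibly `TRUE`; stops with the full failure list otherwise.
#' @export
validateModel <- function(model) {
  msgs <- validateModelStructure(model)
  if (length(msgs))
    stop("model validation failed:\n  - ", paste(msgs, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

# ---- linear programming -----------------------------------------------------

# bound applied in place of +/-Inf so the LP stays bounded
BIG_BOUND <- 1e3

# solve max/min obj'v s.t. S v = 0, lb <= v <= ub, optional extra
# inequality ineqA v >= ineqB. Returns list(v, value, status).
solveFluxLP <- function(obj, S, lb, ub, maximize = TRUE,
                        ineqA = NULL, ineqB = NULL) {
  lb <- pmax(lb, -BIG_BOUND); ub <- pmin(ub, BIG_BOUND)
  n <- length(lb)
  S <- as.matrix(S)
  # variables fixed by their bounds are substituted out: the simplex code
  # cannot take zero-width <= rows
  free <- which(ub - lb > 1e-12)
  tol <- 1e-8
  if (length(free) == 0L) {
    v <- lb
    feas <- max(abs(S %*% v)) <= tol &&
      (is.null(ineqA) || sum(ineqA * v) >= ineqB - tol)
    return(list(v = if (feas) v else rep(NA_real_, n),
                value = if (feas) sum(obj * v) else NA_real_,
                status = if (feas) "optimal" else "infeasible"))
  }
  # standard form over x = v[free] - lb[free] >= 0:
  #   S_free x = -S lb                (mass balance)
  #   x_i + s_i = (ub - lb)_i         (upper bounds, slack s >= 0)
  #   a'x  - t  = ineqB - a'lb        (optional >=, surplus t >= 0)
  nf <- length(free)
  hasIneq <- !is.null(ineqA)
  meq <- nrow(S)
  ncols <- 2L * nf + as.integer(hasIneq)
  A <- matrix(0, meq + nf + as.integer(hasIneq), ncols)
  A[seq_len(meq), seq_len(nf)] <- S[, free, drop = FALSE]
  b <- c(as.numeric(-S %*% lb), (ub - lb)[free],
         if (hasIneq) ineqB - sum(ineqA * lb))
  for (i in seq_len(nf)) {
    A[meq + i, i] <- 1
    A[meq + i, nf + i] <- 1
  }
  if (hasIneq) {
    A[meq + nf + 1L, seq_len(nf)] <- ineqA[free]
    A[meq + nf + 1L, 2L * nf + 1L] <- -1
  }
  cost <- c(if (maximize) -obj[free] else obj[free], rep(0, ncols - nf))
  res <- simplexLP(cost, A, b)
  if (res$status != "optimal")
    return(list(v = rep(NA_real_, n), value = NA_real_,
                status = res$status))
  v <- lb
  v[free] <- res$x[seq_len(nf)] + lb[free]
  list(v = v, value = sum(obj * v), status = "optimal")
}

#' Flux balance analysis
#'
#' Maximizes flux through the model's objective reaction subject to
#' steady-state mass balance and the flux bounds. Infeasible or unbounded
#' problems are reported through the solution status, never as an error.
#'
#' @param model a valid [MetabolicModel-class].
#' @return A [FluxSolution-class].
#' @export
fba <- function(model) {
  validateModel(model)
  n <- length(model@reactions)
  obj <- as.numeric(model@reactions == model@objective)
  sol <- solveFluxLP(obj, model@S, model@lb, model@ub, maximize = TRUE)
  fl <- setNames(if (sol$status == "optimal") sol$v else rep(NA_real_, n),
                 model@reactions)
  new("FluxSolution", fluxes = fl,
      objectiveValue = if (sol$status == "optimal")
        unname(fl[model@objective]) else NA_real_,
      status = sol$status, inconsistencyScore = NA_real_)
}

#' GIMME context-specific flux optimization
#'
#' Splits every reaction into non-negative forward/backward parts and solves
#' the linear program minimizing `sum_i (cutoff - expr_i) * |v_i|` over
#' reactions whose mapped expression is below the cutoff, subject to mass
#' balance, the flux bounds, and the objective staying at or above
#' `objectiveFraction` times its FBA optimum. Reactions without a GPR rule
#' (`NA` expression) are never penalized. The attained penalty is the
#' inconsistency score: 0 means the context's proteins can carry the
#' required objective without using any low-evidence reaction.
#'
#' @param model a valid [MetabolicModel-class] whose FBA optimum is > 0.
#' @param rxnExpr named per-reaction expression from [reactionExpression()]
#'   (or an [ExpressionProfile-class]/named gene vector, mapped internally).
#' @param cutoff expression cutoff; with the boolean 100/0 presence scheme
#'   any value strictly between 0 and 100 selects the same reaction set.
#' @param objectiveFraction required fraction of the FBA optimum, in (0, 1].
#' @return A [FluxSolution-class] with `inconsistencyScore` set.
#' @export
gimme <- function(model, rxnExpr, cutoff = 50, objectiveFraction = 0.9) {
  validateModel(model)
  if (objectiveFraction <= 0 || objectiveFraction > 1)
    stop("objectiveFraction must be in (0, 1]")
  if (is(rxnExpr, "ExpressionProfile") ||
      (!is.null(names(rxnExpr)) && !all(names(rxnExpr) %in% model@reactions)))
    rxnExpr <- reactionExpression(model, rxnExpr)
  if (is.null(names(rxnExpr))) {
    if (length(rxnExpr) != length(model@reactions))
      stop("unnamed rxnExpr must have one value per reaction")
    names(rxnExpr) <- model@reactions
  }
  rxnExpr <- rxnExpr[model@reactions]
  base <- fba(model)
  if (solverStatus(base) != "optimal")
    stop("base FBA is ", solverStatus(base),
         "; cannot form the GIMME problem")
  zstar <- objectiveValue(base)
  if (zstar <= 0)
    stop("FBA objective is not positive; the objective cannot be maintained")

  n <- length(model@reactions)
  lb <- pmax(model@lb, -BIG_BOUND); ub <- pmin(model@ub, BIG_BOUND)
  # split v = f - b with f in [0, max(ub,0)], b in [0, max(-lb,0)]
  fUb <- pmax(ub, 0); bUb <- pmax(-lb, 0)
  S <- as.matrix(model@S)
  Ssplit <- cbind(S, -S)
  penalty <- ifelse(!is.na(rxnExpr) & rxnExpr < cutoff,
                    cutoff - rxnExpr, 0)
  objSplit <- c(penalty, penalty)
  iObj <- which(model@reactions == model@objective)
  ineq <- numeric(2 * n); ineq[iObj] <- 1; ineq[n + iObj] <- -1
  sol <- solveFluxLP(objSplit, Ssplit, lb = rep(0, 2 * n),
                     ub = c(fUb, bUb), maximize = FALSE,
                     ineqA = ineq, ineqB = objectiveFraction * zstar)
  if (sol$status != "optimal")
    return(new("FluxSolution",
               fluxes = setNames(rep(NA_real_, n), model@reactions),
               objectiveValue = NA_real_, status = sol$status,
               inconsistencyScore = NA_real_))
  f <- sol$v[seq_len(n)]; b <- sol$v[n + seq_len(n)]
  v <- f - b
  score <- sum(penalty * (f + b))
  new("FluxSolution", fluxes = setNames(v, model@reactions),
      objectiveValue = unname(v[iObj]), status = "optimal",
      inconsistencyScore = score)
}

#' Extract the active subnetwork of a flux solution
#'
#' Restricts the model to reactions carrying flux above the tolerance,
#' keeps the metabolites those reactions touch, and flags dead-end
#' metabolites — those participating in only one active reaction.
#'
#' @param model a [MetabolicModel-class].
#' @param solution an optimal [FluxSolution-class] for `model`.
#' @param tol absolute flux threshold for activity.
#' @return `list(model = restricted MetabolicModel, deadEnds = character)`.
#' @export
contextSubnetwork <- function(model, solution, tol = 1e-9) {
  if (solverStatus(solution) != "optimal")
    stop("subnetwork extraction requires an optimal solution")
  v <- fluxes(solution)[model@reactions]
  active <- which(abs(v) > tol)
  S <- as.matrix(model@S)
  Ssub <- S[, active, drop = FALSE]
  metUsed <- which(rowSums(Ssub != 0) > 0)
  Ssub <- Ssub[metUsed, , drop = FALSE]
  degree <- rowSums(Ssub != 0)
  deadEnds <- model@metabolites[metUsed][degree == 1]
  obj <- if (model@objective %in% model@reactions[active])
    model@objective else NA_character_
  genesKept <- unique(unlist(lapply(model@gpr[active],
                                    function(r) gprGenes(parseGPR(r)))))
  sub <- new("MetabolicModel",
             metabolites = model@metabolites[metUsed],
             reactions = model@reactions[active],
             S = methods::as(methods::as(Matrix::Matrix(Ssub, sparse = TRUE),
                                         "generalMatrix"), "CsparseMatrix"),
             lb = model@lb[active], ub = model@ub[active],
             gpr = model@gpr[active],
             genes = if (length(genesKept)) genesKept else character(0),
             objective = obj)
  list(model = sub, deadEnds = deadEnds)
}
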