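#' Relative metabolite quantification
#'
#' Each sample spectrum is modelled as a non-negative linear combination of
#' the library's unit-intensity standard spectra. The coefficient vector is
#' initialised by a partial-least-squares regression of the spectrum on the
#' library (negative entries clipped to zero) and refined by
#' Levenberg-Marquardt least squares under the exact reparameterization
#' `c = u^2`, which keeps the damped Gauss-Newton iteration unconstrained
#' while enforcing `c >= 0` at every step. Because standards share the
#' unit-total-intensity scale, the fitted coefficients are relative
#' concentrations comparable across metabolites and samples.
#'
#' @name quantification
NULL

# condition number of the library design via its singular values
libraryCondition <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (min(d) <= 0) Inf else max(d) / min(d)
}

checkGrid <- function(library, s) {
  if (length(s@ppm) != length(library@ppm) ||
      max(abs(s@ppm - library@ppm)) > 1e-9)
    stop("spectrum is not on the library grid")
}

#' PLS starting point for the constrained fit
#'
#' Runs a NIPALS PLS1 regression of the spectrum on the library rows
#' (grid points as observations, metabolites as predictors) and clips
#' negative coefficients to zero. This is only a starting point: the
#' constrained refinement carries the accuracy.
#'
#' @param library a [SpectralLibrary-class].
#' @param s a [Spectrum-class] on the library grid.
#' @param nComponents number of latent components,
#'   `1..nrow(librarySpectra(library))`.
#' @return Non-negative numeric coefficient vector, one per metabolite.
#' @export
plsInitialize <- function(library, s,
                          nComponents = min(10L, nrow(library@spectra))) {
  checkGrid(library, s)
  p <- nrow(library@spectra)
  if (nComponents < 1L || nComponents > p)
    stop("nComponents must be between 1 and the number of metabolites")
  X <- t(library@spectra)                     # grid points x metabolites
  y <- s@intensity
  xm <- colMeans(X); ym <- mean(y)
  X0 <- sweep(X, 2, xm); y0 <- y - ym
  W <- matrix(0, p, nComponents)
  P <- matrix(0, p, nComponents)
  q <- numeric(nComponents)
  used <- 0L
  for (a in seq_len(nComponents)) {
    w <- crossprod(X0, y0)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break                     # response exhausted
    w <- w / nw
    t_ <- X0 %*% w
    tt <- sum(t_^2)
    if (tt < 1e-28) break
    pv <- crossprod(X0, t_) / tt
    qa <- sum(y0 * t_) / tt
    X0 <- X0 - t_ %*% t(pv)
    y0 <- y0 - qa * t_
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    used <- a
  }
  if (used == 0L) return(setNames(rep(0, p), rownames(library@spectra)))
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  beta <- tryCatch(W %*% solve(crossprod(P, W), q),
                   error = function(e) W %*% q)  # fall back on rank loss
  beta <- as.numeric(beta)
  setNames(pmax(beta, 0), rownames(library@spectra))
}

#' Fit non-negative concentrations to one spectrum
#'
#' Minimises `||s - c' * library||^2` subject to `c >= 0` by
#' Levenberg-Marquardt on the squared parameterization `c = u^2`, starting
#' from `u = sqrt(init)` (tiny floors keep coordinates off the `u = 0`
#' stationary point). The forward model is linear, so the constrained
#' optimum coincides with the active-set non-negative least-squares
#' solution; the analytic Jacobian `-2 u_j M_j` is supplied to the solver.
#'
#' @param library a [SpectralLibrary-class].
#' @param s a [Spectrum-class] on the library grid.
#' @param init starting coefficients; defaults to [plsInitialize()].
#' @param maxIter iteration cap.
#' @param ftol relative cost-change convergence tolerance.
#' @return `list(coefficients = named non-negative vector,
#'   diagnostics = FitDiagnostics)`.
#' @export
fitConcentrations <- function(library, s, init = NULL, maxIter = 500L,
                              ftol = 1e-10) {
  checkGrid(library, s)
  M <- library@spectra                        # metabolites x grid
  if (is.null(init)) init <- plsInitialize(library, s)
  init <- pmax(as.numeric(init), 0)
  kappa <- libraryCondition(M)
  if (is.finite(kappa) && kappa > 1e8)
    warning(sprintf("library is nearly collinear (condition number %.3g)",
                    kappa))
  y <- s@intensity
  p <- nrow(M)
  scale0 <- max(init, 1e-3)
  u <- sqrt(init + 1e-8 * scale0)             # floor: avoid u=0 trap
  # Coordinates pinned at the c = 0 boundary make the squared
  # parameterization converge only linearly, so the LM core runs inside an
  # active-set outer loop: after each LM pass, coordinates whose cost
  # gradient points into the boundary (dC/dc_j > 0 at c_j ~ 0) are fixed at
  # zero and the remainder refit; zeroed coordinates re-enter if their
  # gradient turns negative. The loop leaves the LM solution untouched when
  # no boundary coordinate exists.
  active <- rep(TRUE, p)
  totalIter <- 0L; info <- 0L
  for (round in seq_len(6L)) {
    resFn <- function(ua) {
      c <- numeric(p); c[active] <- ua^2
      y - as.numeric(crossprod(M, c))
    }
    jacFn <- function(ua) -2 * sweep(t(M[active, , drop = FALSE]), 2, ua,
                                     `*`)
    # the first pass only has to localize the boundary set, so it gets a
    # short iteration budget; refits on the reduced support converge fast
    roundIter <- if (round == 1L) min(as.integer(maxIter), 60L)
                 else as.integer(maxIter)
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = u[active], fn = resFn, jac = jacFn,
      control = minpack.lm::nls.lm.control(
        maxiter = roundIter, ftol = ftol, ptol = 1e-12,
        gtol = 0)))
    u[active] <- abs(as.numeric(fit$par))
    totalIter <- totalIter + as.integer(fit$niter)
    info <- fit$info
    cvec <- numeric(p); cvec[active] <- u[active]^2
    r <- y - as.numeric(crossprod(M, cvec))
    g <- -2 * as.numeric(M %*% r)             # dC/dc_j
    tolG <- 1e-8 * max(1, max(abs(g)))
    drop <- active & g > tolG & cvec < 1e-2 * max(cvec, scale0)
    reenter <- !active & g < -tolG
    if (!any(drop) && !any(reenter)) break
    u[drop] <- 0; active[drop] <- FALSE
    u[reenter] <- sqrt(1e-6 * scale0); active[reenter] <- TRUE
  }
  cvec <- numeric(p); cvec[active] <- u[active]^2
  coef <- setNames(cvec, rownames(M))
  rFinal <- y - as.numeric(crossprod(M, cvec))
  diag <- new("FitDiagnostics",
              residualNorm = sqrt(sum(rFinal^2)),
              iterations = totalIter,
              converged = info %in% 1:4,
              initialVector = as.numeric(init))
  list(coefficients = coef, diagnostics = diag)
}

# the normalization-relevant part of a processing history
normalizationSignature <- function(s) {
  paste(grep("^normalize", s@history, value = TRUE), collapse = ";")
}

#' Quantify a cohort of spectra against a library
#'
#' Fits every spectrum with [fitConcentrations()] and assembles the
#' samples-by-metabolites [ConcentrationTable-class]. All spectra must carry
#' identical normalization histories: mixing normalization modes would put
#' samples on incompatible scales, so the function refuses.
#'
#' @param library a [SpectralLibrary-class].
#' @param spectra list of preprocessed [Spectrum-class] objects.
#' @param plsComponents components passed to [plsInitialize()].
#' @return A [ConcentrationTable-class]; per-sample [FitDiagnostics-class]
#'   are stored in `metadata(x)$diagnostics`.
#' @export
quantifyCohort <- function(library, spectra,
                           plsComponents = min(10L,
                                               nrow(library@spectra))) {
  nm <- rownames(library@spectra)
  if (length(spectra) == 0L) {
    empty <- matrix(numeric(0), 0, length(nm),
                    dimnames = list(NULL, nm))
    return(ConcentrationTable(empty))
  }
  sigs <- vapply(spectra, normalizationSignature, character(1))
  if (length(unique(sigs)) > 1L)
    stop("spectra carry mixed normalization histories (",
         paste(unique(sigs), collapse = " vs "),
         "); preprocess the cohort with one normalization mode")
  vals <- matrix(0, length(spectra), length(nm),
                 dimnames = list(NULL, nm))
  diags <- vector("list", length(spectra))
  ids <- character(length(spectra))
  meta <- data.frame(cellLine = character(length(spectra)),
                     sourceType = character(length(spectra)),
                     replicate = integer(length(spectra)))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    init <- plsInitialize(library, s, plsComponents)
    fit <- fitConcentrations(library, s, init = init)
    vals[i, ] <- fit$coefficients
    diags[[i]] <- fit$diagnostics
    ids[i] <- if (is.na(s@sampleId)) sprintf("sample%d", i) else s@sampleId
    meta$cellLine[i] <- s@cellLine
    meta$sourceType[i] <- s@sourceType
    meta$replicate[i] <- s@replicate
  }
  rownames(vals) <- make.unique(ids)
  ct <- ConcentrationTable(vals, sampleData = meta)
  S4Vectors::metadata(ct)$diagnostics <- setNames(diags, rownames(vals))
  ct
}
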