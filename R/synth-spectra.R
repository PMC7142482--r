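#' Synthetic NMR spectra with known ground truth
#'
#' Because measured 1D proton spectra of cell, media and vesicle extracts are
#' rarely redistributable, the package ships a simulator that emulates them:
#' pure-metabolite reference spectra built from Lorentzian lines (the natural
#' NMR line shape) and normalized to unit total intensity, mixtures with known
#' non-negative concentrations plus Gaussian noise, per-metabolite chemical
#' shift jitter and low-order polynomial baseline drift, and replicate cohorts
#' with planted group-level effects over a cell-line-by-source design.
#'
#' @name synthetic-spectra
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Define a Lorentzian peak
#'
#' @param center chemical shift of the peak maximum (ppm).
#' @param amplitude relative intensity, > 0.
#' @param fwhm full width at half maximum (ppm), > 0.
#' @return A validated peak definition (list).
#' @export
peakSpec <- function(center, amplitude = 1, fwhm = 0.02) {
  stopifnot(is.finite(center), amplitude > 0, fwhm > 0)
  structure(list(center = center, amplitude = amplitude, fwhm = fwhm),
            class = "peakSpec")
}

#' Define a metabolite as a set of peaks
#'
#' @param name metabolite identifier.
#' @param peaks list of [peakSpec()] definitions (at least one).
#' @return A validated metabolite definition (list).
#' @export
metaboliteDef <- function(name, peaks) {
  if (length(peaks) < 1L) stop("metabolite '", name, "' has an empty peak list")
  if (!all(vapply(peaks, inherits, logical(1), "peakSpec")))
    stop("peaks must be built with peakSpec()")
  structure(list(name = as.character(name), peaks = peaks),
            class = "metaboliteDef")
}

# Lorentzian with unit peak height: L(x) = (w/2)^2 / ((x-c)^2 + (w/2)^2)
lorentzian <- function(x, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - center)^2 + hw2)
}

#' The default simulation grid
#'
#' 32768 points spanning -0.5 to 10 ppm, the spectral region conventionally
#' retained for aqueous-extract metabolomics.
#'
#' @param n number of grid points.
#' @param from,to grid limits (ppm).
#' @return Numeric ppm axis.
#' @export
defaultGrid <- function(n = 32768L, from = -0.5, to = 10) {
  seq(from, to, length.out = n)
}

#' Built-in metabolite definitions
#'
#' Twenty metabolites commonly profiled in glioma cell, media and vesicle
#' extracts, with literature-typical proton chemical shifts and synthetic
#' (not database-derived) amplitudes and linewidths.
#'
#' @param n how many of the definitions to return (1..20).
#' @return Named list of [metaboliteDef()] objects.
#' @export
defaultMetabolites <- function(n = 20L) {
  p <- function(c, a = 1, w = 0.02) peakSpec(c, a, w)
  defs <- list(
    metaboliteDef("lactate",      list(p(1.33, 3, 0.018), p(4.11, 1, 0.02))),
    metaboliteDef("alanine",      list(p(1.48, 3, 0.018), p(3.78, 1, 0.02))),
    metaboliteDef("acetate",      list(p(1.92, 3, 0.016))),
    metaboliteDef("glutamate",    list(p(2.05, 2, 0.025), p(2.34, 2, 0.025),
                                       p(3.75, 1, 0.02))),
    metaboliteDef("glutamine",    list(p(2.13, 2, 0.025), p(2.45, 2, 0.025),
                                       p(3.77, 1, 0.02))),
    metaboliteDef("succinate",    list(p(2.41, 4, 0.016))),
    metaboliteDef("citrate",      list(p(2.54, 2, 0.02), p(2.66, 2, 0.02))),
    metaboliteDef("creatine",     list(p(3.03, 3, 0.016), p(3.93, 2, 0.018))),
    metaboliteDef("choline",      list(p(3.19, 9, 0.014))),
    metaboliteDef("phosphocholine", list(p(3.22, 9, 0.014), p(4.16, 2, 0.02))),
    metaboliteDef("glucose",      list(p(3.40, 2, 0.03), p(3.70, 3, 0.03),
                                       p(5.23, 1, 0.018))),
    metaboliteDef("myo_inositol", list(p(3.52, 4, 0.025), p(4.06, 1, 0.02))),
    metaboliteDef("glycine",      list(p(3.55, 2, 0.014))),
    metaboliteDef("taurine",      list(p(3.25, 2, 0.02), p(3.42, 2, 0.02))),
    metaboliteDef("malate",       list(p(2.37, 1, 0.022), p(2.67, 1, 0.022),
                                       p(4.30, 1, 0.02))),
    metaboliteDef("fumarate",     list(p(6.51, 2, 0.014))),
    metaboliteDef("glutathione",  list(p(2.16, 2, 0.025), p(2.95, 2, 0.022),
                                       p(4.56, 1, 0.02))),
    metaboliteDef("valine",       list(p(0.99, 3, 0.016), p(1.04, 3, 0.016),
                                       p(2.27, 1, 0.02))),
    metaboliteDef("isoleucine",   list(p(0.94, 3, 0.016), p(1.01, 3, 0.016))),
    metaboliteDef("leucine",      list(p(0.96, 6, 0.016), p(1.71, 3, 0.02)))
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  stopifnot(n >= 1L, n <= length(defs))
  defs[seq_len(n)]
}

#' Simulate a pure-metabolite reference spectrum
#'
#' Sums one Lorentzian per peak and normalizes the result to a total summed
#' intensity of one, the convention used for library standards so that fitted
#' coefficients are comparable across metabolites.
#'
#' @param metabolite a [metaboliteDef()].
#' @param grid strictly monotonic ppm axis.
#' @return A [Spectrum-class] with unit total intensity.
#' @examples
#' s <- makeReferenceSpectrum(defaultMetabolites(1)[[1]], defaultGrid(4096))
#' sum(intensity(s))  # 1
#' @export
makeReferenceSpectrum <- function(metabolite, grid) {
  if (!inherits(metabolite, "metaboliteDef"))
    stop("metabolite must be a metaboliteDef")
  if (length(metabolite$peaks) < 1L)
    stop("metabolite '", metabolite$name, "' has an empty peak list")
  y <- rep(0, length(grid))
  for (pk in metabolite$peaks)
    y <- y + pk$amplitude * lorentzian(grid, pk$center, pk$fwhm)
  tot <- sum(y)
  if (tot <= 0) stop("reference spectrum has nonpositive total intensity")
  Spectrum(grid, y / tot, sampleId = metabolite$name,
           history = "makeReferenceSpectrum")
}

#' Build a SpectralLibrary from metabolite definitions
#'
#' @param defs list of [metaboliteDef()] objects.
#' @param grid shared ppm axis.
#' @return A [SpectralLibrary-class].
#' @export
makeSpectralLibrary <- function(defs, grid) {
  mat <- t(vapply(defs, function(d)
    intensity(makeReferenceSpectrum(d, grid)), numeric(length(grid))))
  rownames(mat) <- vapply(defs, `[[`, character(1), "name")
  SpectralLibrary(mat, grid)
}

# integer-bin shift with boundary-value fill (shared with alignment)
shiftVector <- function(y, lag) {
  n <- length(y)
  lag <- as.integer(lag)
  if (lag == 0L) return(y)
  if (abs(lag) >= n) return(rep(if (lag > 0) y[1] else y[n], n))
  if (lag > 0) c(rep(y[1], lag), y[seq_len(n - lag)])
  else c(y[(1 - lag):n], rep(y[n], -lag))
}

#' Simulate a mixture spectrum with known concentrations
#'
#' The mixture is a non-negative linear combination of the reference spectra,
#' each optionally rigidly shifted by a per-metabolite jitter (emulating
#' pH-driven chemical-shift variation), plus a smooth polynomial baseline and
#' additive Gaussian noise. The ground-truth concentration vector is returned
#' verbatim alongside the spectrum.
#'
#' @param defs list of [metaboliteDef()] objects.
#' @param concentrations non-negative vector, one per metabolite.
#' @param grid ppm axis.
#' @param noiseSd standard deviation of additive Gaussian noise.
#' @param shiftJitterSd standard deviation of per-metabolite shift (ppm);
#'   realised shifts are rounded to whole grid bins.
#' @param baselineAmp amplitude of a random cubic baseline (0 = none).
#' @param seed integer seed; required so simulations are reproducible.
#' @param sampleId,cellLine,sourceType,replicate metadata for the spectrum.
#' @return `list(spectrum = Spectrum, truth = named numeric)`.
#' @export
makeMixture <- function(defs, concentrations, grid, noiseSd = 0,
                        shiftJitterSd = 0, baselineAmp = 0, seed,
                        sampleId = NA_character_, cellLine = NA_character_,
                        sourceType = NA_character_, replicate = NA_integer_) {
  if (length(concentrations) != length(defs))
    stop("concentrations length must match the number of metabolites")
  if (any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (missing(seed)) stop("a seed is required")
  refs <- lapply(defs, function(d) intensity(makeReferenceSpectrum(d, grid)))
  nm <- vapply(defs, `[[`, character(1), "name")
  dppm <- mean(diff(grid))
  y <- withSeed(seed, {
    jitterBins <- if (shiftJitterSd > 0)
      as.integer(round(rnorm(length(defs), 0, shiftJitterSd) / dppm))
    else rep(0L, length(defs))
    acc <- rep(0, length(grid))
    for (i in seq_along(defs))
      acc <- acc + concentrations[i] * shiftVector(refs[[i]], jitterBins[i])
    if (baselineAmp > 0) {
      u <- seq(-1, 1, length.out = length(grid))
      coefs <- runif(4, -1, 1) * baselineAmp
      acc <- acc + coefs[1] + coefs[2] * u + coefs[3] * u^2 + coefs[4] * u^3
    }
    if (noiseSd > 0) acc <- acc + rnorm(length(grid), 0, noiseSd)
    acc
  })
  truth <- setNames(as.numeric(concentrations), nm)
  sp <- Spectrum(grid, y, sampleId = sampleId, cellLine = cellLine,
                 sourceType = sourceType, replicate = replicate,
                 history = sprintf(
                   "makeMixture(seed=%d,noiseSd=%g,jitterSd=%g,baseline=%g)",
                   seed, noiseSd, shiftJitterSd, baselineAmp))
  list(spectrum = sp, truth = truth)
}

#' Describe a replicate cohort with planted group effects
#'
#' Groups follow the cell-line-by-source layout of a cell / media /
#' extracellular-vesicle study (lines LN18, A172, U118 and NHA control).
#' Effects are multiplicative factors applied to a group's mean level of one
#' metabolite; replicate-to-replicate biological variation is lognormal.
#'
#' @param groups data.frame with columns `cellLine` and `sourceType`.
#' @param replicatesPerGroup replicates per group (>= 1).
#' @param baseConcentrations named non-negative vector of mean levels.
#' @param effects named list: `effects[["LINE.source"]]` is a named vector of
#'   multiplicative factors (> 0) for that group, e.g.
#'   `list("U118.EV" = c(lactate = 3))`.
#' @param biologicalCV lognormal coefficient of variation between replicates.
#' @param noiseSd,shiftJitterSd,baselineAmp passed to [makeMixture()].
#' @param seed integer seed.
#' @return A validated design (list) for [makeCohort()].
#' @export
cohortDesign <- function(groups, replicatesPerGroup = 3L, baseConcentrations,
                         effects = list(), biologicalCV = 0.1, noiseSd = 0,
                         shiftJitterSd = 0, baselineAmp = 0, seed) {
  stopifnot(is.data.frame(groups),
            all(c("cellLine", "sourceType") %in% names(groups)))
  if (replicatesPerGroup < 1L) stop("replicatesPerGroup must be >= 1")
  if (any(baseConcentrations < 0))
    stop("baseConcentrations must be non-negative")
  if (is.null(names(baseConcentrations)))
    stop("baseConcentrations must be named by metabolite")
  for (g in names(effects))
    if (any(effects[[g]] <= 0)) stop("effect factors must be > 0")
  if (missing(seed)) stop("a seed is required")
  structure(list(groups = groups,
                 replicatesPerGroup = as.integer(replicatesPerGroup),
                 baseConcentrations = baseConcentrations, effects = effects,
                 biologicalCV = biologicalCV, noiseSd = noiseSd,
                 shiftJitterSd = shiftJitterSd, baselineAmp = baselineAmp,
                 seed = as.integer(seed)),
            class = "cohortDesign")
}

#' Simulate a cohort of spectra with ground truth
#'
#' @param design a [cohortDesign()].
#' @param defs metabolite definitions; names must cover
#'   `design$baseConcentrations`.
#' @param grid ppm axis.
#' @return `list(spectra = list of Spectrum, truth = ConcentrationTable)`.
#' @export
makeCohort <- function(design, defs, grid = defaultGrid()) {
  stopifnot(inherits(design, "cohortDesign"))
  nm <- vapply(defs, `[[`, character(1), "name")
  base <- design$baseConcentrations
  if (!all(names(base) %in% nm))
    stop("baseConcentrations name(s) missing from metabolite definitions: ",
         paste(setdiff(names(base), nm), collapse = ", "))
  baseFull <- setNames(rep(0, length(nm)), nm)
  baseFull[names(base)] <- base

  nGroups <- nrow(design$groups)
  nRep <- design$replicatesPerGroup
  nSamples <- nGroups * nRep
  spectra <- vector("list", nSamples)
  truth <- matrix(0, nSamples, length(nm),
                  dimnames = list(NULL, nm))
  meta <- data.frame(sampleId = character(nSamples),
                     cellLine = character(nSamples),
                     sourceType = character(nSamples),
                     replicate = integer(nSamples))
  k <- 0L
  for (g in seq_len(nGroups)) {
    line <- design$groups$cellLine[g]
    src <- design$groups$sourceType[g]
    gkey <- paste(line, src, sep = ".")
    eff <- setNames(rep(1, length(nm)), nm)
    if (gkey %in% names(design$effects)) {
      ev <- design$effects[[gkey]]
      eff[names(ev)] <- ev
    }
    for (r in seq_len(nRep)) {
      k <- k + 1L
      sid <- sprintf("%s_%s_r%d", line, src, r)
      repSeed <- design$seed + 1000L * k
      conc <- withSeed(repSeed, {
        cv <- design$biologicalCV
        noiseFac <- if (cv > 0) rlnorm(length(nm), 0, cv) else rep(1, length(nm))
        baseFull * eff * noiseFac
      })
      mx <- makeMixture(defs, conc, grid, noiseSd = design$noiseSd,
                        shiftJitterSd = design$shiftJitterSd,
                        baselineAmp = design$baselineAmp,
                        seed = repSeed + 1L, sampleId = sid, cellLine = line,
                        sourceType = src, replicate = r)
      spectra[[k]] <- mx$spectrum
      truth[k, ] <- mx$truth
      meta$sampleId[k] <- sid
      meta$cellLine[k] <- line
      meta$sourceType[k] <- src
      meta$replicate[k] <- r
    }
  }
  rownames(truth) <- meta$sampleId
  ct <- ConcentrationTable(truth, sampleData = meta[, -1])
  list(spectra = spectra, truth = ct)
}
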