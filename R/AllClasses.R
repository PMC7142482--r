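#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom stats fft sd var cor prcomp hclust dist as.dist phyper setNames
#'   rnorm rlnorm runif quantile median p.adjust
#' @importFrom utils head tail read.delim write.table read.csv write.csv
NULL

#' Spectrum: a one-dimensional NMR spectrum
#'
#' A chemical-shift axis (ppm) with matched intensities plus sample metadata
#' and a processing history. Every transforming operation appends a record to
#' the history, so the full preprocessing chain can be reconstructed from the
#' object itself.
#'
#' @slot ppm numeric, strictly monotonic chemical-shift axis (ppm).
#' @slot intensity numeric, same length as `ppm`.
#' @slot sampleId character(1) sample identifier.
#' @slot cellLine character(1), e.g. one of LN18, A172, U118, NHA.
#' @slot sourceType character(1), one of cell, EV, media (or NA).
#' @slot replicate integer(1) replicate index.
#' @slot history character, audit trail of applied transformations.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    sampleId = "character",
    cellLine = "character",
    sourceType = "character",
    replicate = "integer",
    history = "character"
  ),
  prototype(
    sampleId = NA_character_, cellLine = NA_character_,
    sourceType = NA_character_, replicate = NA_integer_,
    history = character(0)
  )
)

setValidity("Spectrum", function(object) {
  msgs <- character(0)
  if (length(object@ppm) != length(object@intensity))
    msgs <- c(msgs, "ppm and intensity must have the same length")
  if (length(object@ppm) < 2L)
    msgs <- c(msgs, "a Spectrum needs at least 2 points")
  d <- diff(object@ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msgs <- c(msgs, "ppm axis must be strictly monotonic")
  if (length(msgs)) msgs else TRUE
})

#' Fid: a complex time-domain NMR signal
#'
#' @slot signal complex free-induction-decay values.
#' @slot dwell numeric(1), seconds per point (> 0).
#'
#' @exportClass Fid
setClass("Fid",
  representation(signal = "complex", dwell = "numeric"))

setValidity("Fid", function(object) {
  msgs <- character(0)
  if (length(object@signal) < 2L) msgs <- c(msgs, "signal needs >= 2 points")
  if (length(object@dwell) != 1L || !is.finite(object@dwell) ||
      object@dwell <= 0)
    msgs <- c(msgs, "dwell must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' SpectralLibrary: standard spectra on a shared grid
#'
#' Matrix of pure-metabolite standard spectra, one row per metabolite, each
#' normalized to a total summed intensity of one. Serves as the design matrix
#' for relative quantification.
#'
#' @slot spectra numeric matrix, metabolites x grid points; rownames are the
#'   metabolite names.
#' @slot ppm shared chemical-shift axis, length `ncol(spectra)`.
#'
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
  representation(spectra = "matrix", ppm = "numeric"))

setValidity("SpectralLibrary", function(object) {
  msgs <- character(0)
  if (ncol(object@spectra) != length(object@ppm))
    msgs <- c(msgs, "spectra columns must match ppm length")
  nm <- rownames(object@spectra)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msgs <- c(msgs, "spectra must have non-empty rownames")
  else if (anyDuplicated(nm))
    msgs <- c(msgs, "metabolite names must be unique")
  rs <- rowSums(object@spectra)
  if (length(rs) && any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, "each library row must have total intensity 1 (+/- 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' ConcentrationTable: samples x metabolites relative concentrations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"concentration"` (metabolites in rows, samples in columns, following the
#' features-by-samples convention) with sample metadata (`cellLine`,
#' `sourceType`, `replicate`) in `colData`. All values are non-negative:
#' concentrations are relative measures on the common standard scale of the
#' spectral library.
#'
#' @exportClass ConcentrationTable
setClass("ConcentrationTable",
  contains = "SummarizedExperiment")

setValidity("ConcentrationTable", function(object) {
  msgs <- character(0)
  if (!"concentration" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'concentration' is required")
  else {
    v <- SummarizedExperiment::assay(object, "concentration")
    if (any(!is.na(v) & v < 0))
      msgs <- c(msgs, "concentrations must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' MetabolicModel: a stoichiometric metabolic network
#'
#' Stoichiometric matrix, flux bounds, gene-protein-reaction (GPR) boolean
#' rules and a designated objective (biomass/maintenance) reaction. The
#' stoichiometric matrix is stored sparse so genome-scale reconstructions
#' (Recon3D-class, ~10k reactions) can be represented.
#'
#' @slot metabolites character metabolite ids (rows of S).
#' @slot reactions character reaction ids (columns of S).
#' @slot S sparse stoichiometric matrix, metabolites x reactions.
#' @slot lb,ub numeric per-reaction flux bounds, `lb <= ub`.
#' @slot gpr character per-reaction boolean rule over gene ids ("" = none).
#' @slot genes character declared gene ids.
#' @slot objective character(1) id of the objective reaction (NA allowed for
#'   an extracted subnetwork whose objective carried no flux).
#'
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    metabolites = "character",
    reactions = "character",
    S = "dgCMatrix",
    lb = "numeric",
    ub = "numeric",
    gpr = "character",
    genes = "character",
    objective = "character"
  ))

setValidity("MetabolicModel", function(object) {
  msgs <- validateModelStructure(object)
  if (length(msgs)) msgs else TRUE
})

#' ExpressionProfile: gene id to expression value
#'
#' In the boolean presence scheme used for context-specific flux simulation,
#' observed genes carry the value 100 and unobserved genes 0.
#'
#' @slot values named non-negative numeric vector, names are gene ids.
#'
#' @exportClass ExpressionProfile
setClass("ExpressionProfile", representation(values = "numeric"))

setValidity("ExpressionProfile", function(object) {
  msgs <- character(0)
  if (length(object@values) && is.null(names(object@values)))
    msgs <- c(msgs, "values must be named by gene id")
  if (any(object@values < 0)) msgs <- c(msgs, "expression values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' FluxSolution: a solved flux distribution
#'
#' @slot fluxes named numeric, one flux per reaction.
#' @slot objectiveValue numeric(1).
#' @slot status character(1): "optimal", "infeasible" or "unbounded".
#' @slot inconsistencyScore numeric(1); the GIMME penalty at the optimum
#'   (NA for plain FBA solutions).
#'
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(
    fluxes = "numeric",
    objectiveValue = "numeric",
    status = "character",
    inconsistencyScore = "numeric"
  ),
  prototype(inconsistencyScore = NA_real_))

setValidity("FluxSolution", function(object) {
  ok <- object@status %in% c("optimal", "infeasible", "unbounded")
  if (!ok) return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' FitDiagnostics: bookkeeping from a constrained library fit
#'
#' @slot residualNorm numeric(1), Euclidean norm of the final residual.
#' @slot iterations integer(1).
#' @slot converged logical(1).
#' @slot initialVector numeric, the PLS starting point actually used.
#'
#' @exportClass FitDiagnostics
setClass("FitDiagnostics",
  representation(
    residualNorm = "numeric",
    iterations = "integer",
    converged = "logical",
    initialVector = "numeric"
  ))

setValidity("FitDiagnostics", function(object) {
  if (length(object@residualNorm) == 1L && !is.na(object@residualNorm) &&
      object@residualNorm < 0)
    return("residualNorm must be >= 0")
  TRUE
})
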