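#' Accessors for nmrflux classes
#'
#' `ppm()`, `intensity()`, `processingHistory()` access a [Spectrum-class];
#' `libraryNames()` and `librarySpectra()` a [SpectralLibrary-class];
#' `concentrations()` returns the samples x metabolites matrix of a
#' [ConcentrationTable-class] (the transpose of its stored assay);
#' `fluxes()` the named flux vector, `objectiveValue()`, `solverStatus()` and
#' `inconsistencyScore()` the remaining slots of a [FluxSolution-class];
#' `reactionIds()`, `metaboliteIds()`, `geneIds()`, `stoichiometry()`,
#' `bounds()` and `objectiveReaction()` the parts of a
#' [MetabolicModel-class].
#'
#' @param object an nmrflux object.
#' @return The slot contents, in user-facing orientation.
#' @name accessors
#' @aliases ppm intensity processingHistory libraryNames librarySpectra concentrations
#'   fluxes objectiveValue solverStatus inconsistencyScore reactionIds
#'   metaboliteIds geneIds stoichiometry bounds objectiveReaction
#'   expressionValues
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("processingHistory", function(object) standardGeneric("processingHistory"))
#' @rdname accessors
#' @export
setGeneric("libraryNames", function(object) standardGeneric("libraryNames"))
#' @rdname accessors
#' @export
setGeneric("librarySpectra", function(object) standardGeneric("librarySpectra"))
#' @rdname accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @rdname accessors
#' @export
setGeneric("inconsistencyScore",
  function(object) standardGeneric("inconsistencyScore"))
#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setGeneric("objectiveReaction",
  function(object) standardGeneric("objectiveReaction"))
#' @rdname accessors
#' @export
setGeneric("expressionValues",
  function(object) standardGeneric("expressionValues"))

#' @rdname accessors
setMethod("ppm", "Spectrum", function(object) object@ppm)
#' @rdname accessors
setMethod("intensity", "Spectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("processingHistory", "Spectrum", function(object) object@history)
#' @rdname accessors
setMethod("libraryNames", "SpectralLibrary",
  function(object) rownames(object@spectra))
#' @rdname accessors
setMethod("librarySpectra", "SpectralLibrary", function(object) object@spectra)
#' @rdname accessors
setMethod("ppm", "SpectralLibrary", function(object) object@ppm)
#' @rdname accessors
setMethod("concentrations", "ConcentrationTable",
  function(object) t(SummarizedExperiment::assay(object, "concentration")))
#' @rdname accessors
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)
#' @rdname accessors
setMethod("objectiveValue", "FluxSolution",
  function(object) object@objectiveValue)
#' @rdname accessors
setMethod("solverStatus", "FluxSolution", function(object) object@status)
#' @rdname accessors
setMethod("inconsistencyScore", "FluxSolution",
  function(object) object@inconsistencyScore)
#' @rdname accessors
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions)
#' @rdname accessors
setMethod("metaboliteIds", "MetabolicModel",
  function(object) object@metabolites)
#' @rdname accessors
setMethod("geneIds", "MetabolicModel", function(object) object@genes)
#' @rdname accessors
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)
#' @rdname accessors
setMethod("bounds", "MetabolicModel",
  function(object) data.frame(reaction = object@reactions,
                              lb = object@lb, ub = object@ub))
#' @rdname accessors
setMethod("objectiveReaction", "MetabolicModel",
  function(object) object@objective)
#' @rdname accessors
setMethod("expressionValues", "ExpressionProfile",
  function(object) object@values)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@ppm)
  cat(sprintf("Spectrum '%s': %d points, %.2f..%.2f ppm\n",
              ifelse(is.na(object@sampleId), "<unnamed>", object@sampleId),
              length(object@ppm), rng[1], rng[2]))
  if (!is.na(object@cellLine))
    cat(sprintf("  cellLine=%s source=%s replicate=%s\n", object@cellLine,
                object@sourceType, object@replicate))
  if (length(object@history))
    cat("  history:", paste(object@history, collapse = " | "), "\n")
})

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d complex points, dwell %.3g s (%.3g s total)\n",
              length(object@signal), object@dwell,
              object@dwell * length(object@signal)))
})

setMethod("show", "SpectralLibrary", function(object) {
  cat(sprintf("SpectralLibrary: %d metabolites on %d grid points (%.2f..%.2f ppm)\n",
              nrow(object@spectra), length(object@ppm),
              min(object@ppm), max(object@ppm)))
  cat("  metabolites:", paste(head(rownames(object@spectra), 8),
                              collapse = ", "),
      if (nrow(object@spectra) > 8) "..." else "", "\n")
})

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites, %d reactions, %d genes\n",
              length(object@metabolites), length(object@reactions),
              length(object@genes)))
  cat("  objective:", object@objective, "\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution (%s): objective %.6g", object@status,
              object@objectiveValue))
  if (!is.na(object@inconsistencyScore))
    cat(sprintf(", inconsistency score %.6g", object@inconsistencyScore))
  cat("\n")
})

setMethod("show", "ExpressionProfile", function(object) {
  v <- object@values
  cat(sprintf("ExpressionProfile: %d genes (%d nonzero)\n",
              length(v), sum(v > 0)))
})

setMethod("show", "FitDiagnostics", function(object) {
  cat(sprintf("FitDiagnostics: residual %.4g after %d iterations (%s)\n",
              object@residualNorm, object@iterations,
              if (isTRUE(object@converged)) "converged" else "not converged"))
})
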