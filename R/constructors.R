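#' Construct a Spectrum
#'
#' @param ppm strictly monotonic chemical-shift axis (ppm).
#' @param intensity intensities, same length as `ppm`.
#' @param sampleId,cellLine,sourceType,replicate optional sample metadata.
#' @param history character vector of processing records.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(seq(0, 10, length.out = 64), rep(1, 64), sampleId = "demo")
#' @export
Spectrum <- function(ppm, intensity, sampleId = NA_character_,
                     cellLine = NA_character_, sourceType = NA_character_,
                     replicate = NA_integer_, history = character(0)) {
  new("Spectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleId = as.character(sampleId), cellLine = as.character(cellLine),
      sourceType = as.character(sourceType),
      replicate = as.integer(replicate), history = as.character(history))
}

#' Construct a free-induction decay
#'
#' @param signal complex (or numeric, promoted to complex) time-domain values.
#' @param dwell seconds per point, > 0.
#' @return A [Fid-class] object.
#' @export
Fid <- function(signal, dwell) {
  new("Fid", signal = as.complex(signal), dwell = as.numeric(dwell))
}

#' Construct a SpectralLibrary from a matrix of standards
#'
#' Rows are renormalized to total summed intensity one, the convention under
#' which fitted coefficients share a common relative-concentration scale.
#'
#' @param spectra metabolites x grid matrix with rownames.
#' @param ppm shared chemical-shift axis.
#' @return A [SpectralLibrary-class].
#' @export
SpectralLibrary <- function(spectra, ppm) {
  spectra <- as.matrix(spectra)
  rs <- rowSums(spectra)
  if (any(rs <= 0)) stop("library rows must have positive total intensity")
  new("SpectralLibrary", spectra = spectra / rs, ppm = as.numeric(ppm))
}

#' Construct a ConcentrationTable
#'
#' @param values samples x metabolites non-negative matrix; rownames are
#'   sample ids and colnames metabolite names.
#' @param sampleData optional data.frame of per-sample metadata (columns such
#'   as `cellLine`, `sourceType`, `replicate`), rows matching `values` rows.
#' @return A [ConcentrationTable-class].
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("ala", "gly")))
#' ConcentrationTable(m)
#' @export
ConcentrationTable <- function(values, sampleData = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0L)
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("values must have metabolite colnames")
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = rownames(values))
  else
    sampleData <- S4Vectors::DataFrame(sampleData,
                                       row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = t(values)), colData = sampleData)
  new("ConcentrationTable", se)
}

#' Construct a MetabolicModel
#'
#' @param metabolites,reactions,genes character id vectors.
#' @param S stoichiometric matrix (metabolites x reactions), dense or sparse.
#' @param lb,ub per-reaction flux bounds.
#' @param gpr per-reaction boolean rules over gene ids; "" for none.
#' @param objective id of the objective reaction.
#' @return A [MetabolicModel-class].
#' @export
MetabolicModel <- function(metabolites, reactions, S, lb, ub,
                           gpr = rep("", length(reactions)),
                           genes = character(0), objective) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  new("MetabolicModel", metabolites = as.character(metabolites),
      reactions = as.character(reactions), S = S,
      lb = as.numeric(lb), ub = as.numeric(ub), gpr = as.character(gpr),
      genes = as.character(genes), objective = as.character(objective))
}

#' Construct an ExpressionProfile from a named vector
#'
#' @param values named non-negative numeric vector (gene id -> value).
#' @return An [ExpressionProfile-class].
#' @export
ExpressionProfile <- function(values) {
  new("ExpressionProfile", values = values)
}

# internal: append a history record and return the modified spectrum
addHistory <- function(s, record) {
  s@history <- c(s@history, record)
  s
}
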