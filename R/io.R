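#' Spectrum and table input/output
#'
#' Spectra travel as two-column TSV files (`ppm`, `intensity`), one file per
#' sample, with a companion metadata CSV (`sampleId`, `cellLine`,
#' `sourceType`, `replicate`). A minimal JCAMP-DX reader covers the
#' fixed-point `XYDATA=(X++(Y..Y))` dialect. Concentration tables are CSV
#' with a header row of metabolite names; expression profiles are
#' `gene,value` CSV; flux solutions are written as
#' `reaction,flux,expression,penalized` CSV.
#'
#' @name file-io
NULL

#' @rdname file-io
#' @param s a [Spectrum-class].
#' @param path file path.
#' @return `writeSpectrumTSV` invisibly returns `path`; readers return the
#'   parsed object.
#' @export
writeSpectrumTSV <- function(s, path) {
  df <- data.frame(ppm = s@ppm, intensity = s@intensity)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname file-io
#' @param sampleId,cellLine,sourceType,replicate metadata attached to the
#'   spectrum read from `path`.
#' @export
readSpectrumTSV <- function(path, sampleId = NA_character_,
                            cellLine = NA_character_,
                            sourceType = NA_character_,
                            replicate = NA_integer_) {
  df <- read.delim(path, header = TRUE)
  if (ncol(df) < 2L) stop("expected two columns (ppm, intensity): ", path)
  Spectrum(df[[1]], df[[2]], sampleId = sampleId, cellLine = cellLine,
           sourceType = sourceType, replicate = replicate,
           history = sprintf("readSpectrumTSV(%s)", basename(path)))
}

#' @rdname file-io
#' @export
readJCAMP <- function(path, sampleId = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  getField <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  npoints <- as.integer(getField("NPOINTS"))
  firstx <- as.numeric(getField("FIRSTX"))
  lastx <- as.numeric(getField("LASTX"))
  xfac <- as.numeric(getField("XFACTOR")); if (is.na(xfac)) xfac <- 1
  yfac <- as.numeric(getField("YFACTOR")); if (is.na(yfac)) yfac <- 1
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA= block in ", path)
  end <- grep("^##END=", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  block <- lines[(start[1] + 1L):(end - 1L)]
  ys <- unlist(lapply(block, function(l) {
    v <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    as.numeric(v[-1]) * yfac            # first value per line is X
  }))
  if (is.na(npoints) || is.na(firstx) || is.na(lastx))
    stop("JCAMP header must provide NPOINTS, FIRSTX and LASTX")
  if (length(ys) != npoints)
    stop(sprintf("JCAMP: NPOINTS=%d but %d Y values found", npoints,
                 length(ys)))
  x <- seq(firstx * xfac, lastx * xfac, length.out = npoints)
  if (x[1] > x[npoints]) { x <- rev(x); ys <- rev(ys) }
  Spectrum(x, ys, sampleId = sampleId,
           history = sprintf("readJCAMP(%s)", basename(path)))
}

#' @rdname file-io
#' @param ct a [ConcentrationTable-class].
#' @param metadataPath optional CSV path for the sample metadata.
#' @export
writeConcentrationTable <- function(ct, path, metadataPath = NULL) {
  m <- concentrations(ct)
  df <- data.frame(sampleId = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(ct))
    write.csv(data.frame(sampleId = rownames(m), cd, check.names = FALSE),
              metadataPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname file-io
#' @export
readConcentrationTable <- function(path, metadataPath = NULL) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sampleData <- NULL
  if (!is.null(metadataPath)) {
    md <- read.csv(metadataPath, check.names = FALSE)
    sampleData <- md[match(rownames(m), md$sampleId), -1, drop = FALSE]
  }
  ConcentrationTable(m, sampleData = sampleData)
}

#' @rdname file-io
#' @export
readExpressionCSV <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2L) stop("expected columns gene,value: ", path)
  ExpressionProfile(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

#' @rdname file-io
#' @param solution a [FluxSolution-class].
#' @param rxnExpr optional per-reaction expression to record alongside.
#' @param cutoff expression cutoff used to mark penalized reactions.
#' @export
writeFluxCSV <- function(solution, path, rxnExpr = NULL, cutoff = 50) {
  fl <- fluxes(solution)
  df <- data.frame(reaction = names(fl), flux = unname(fl))
  if (!is.null(rxnExpr)) {
    e <- rxnExpr[names(fl)]
    df$expression <- unname(e)
    df$penalized <- !is.na(e) & e < cutoff
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
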