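#' Spectral alignment
#'
#' Chemical shifts drift slightly between samples (pH, ionic strength), so
#' spectra are aligned before multivariate analysis. Two methods are
#' provided: global alignment of one spectrum to a reference by FFT
#' cross-correlation, and interval-wise co-shifting of a set of spectra,
#' where each spectrum is independently shifted inside user-chosen intervals
#' towards a common target. Shifts are whole grid bins; vacated edge points
#' are filled with the boundary value so that normalized spectra are not
#' contaminated with zeros.
#'
#' @name alignment
NULL

# candidate lags ordered for the tie-break: smallest |lag|, then negative
orderedLags <- function(maxShift) {
  lags <- 0L
  for (k in seq_len(maxShift)) lags <- c(lags, -k, k)
  lags
}

#' Shift a spectrum by a whole number of grid bins
#'
#' Positive lags move intensities towards higher indices; vacated points are
#' filled with the boundary value.
#'
#' @param s a [Spectrum-class].
#' @param lag integer number of bins.
#' @return The shifted [Spectrum-class].
#' @export
shiftSpectrum <- function(s, lag) {
  s@intensity <- shiftVector(s@intensity, lag)
  addHistory(s, sprintf("shiftSpectrum(lag=%d)", as.integer(lag)))
}

# circular cross-correlation values for the ordered candidate lags.
# cc[d] = sum_t s[t] * ref[t - d]; the corrective lag applied to s is -d.
fftCrossCorrelation <- function(sInt, refInt) {
  n <- length(sInt)
  Re(fft(fft(sInt) * Conj(fft(refInt)), inverse = TRUE)) / n
}

#' Align one spectrum to a reference by FFT cross-correlation
#'
#' Finds the integer displacement of `s` relative to `reference` as the
#' argmax of their circular cross-correlation (computed via the FFT), then
#' shifts `s` by the opposite lag. Ties in the correlation are broken towards
#' the smallest absolute lag, then the negative one, so the result is
#' deterministic even for featureless spectra.
#'
#' @param s a [Spectrum-class] to align.
#' @param reference a [Spectrum-class] on the identical grid.
#' @param maxShift largest displacement considered (bins).
#' @return `list(spectrum = aligned Spectrum, lag = applied integer lag)`.
#' @export
alignFFT <- function(s, reference, maxShift = 50L) {
  if (length(s@ppm) != length(reference@ppm) ||
      max(abs(s@ppm - reference@ppm)) > 1e-9)
    stop("spectra must share an identical ppm grid")
  n <- length(s@intensity)
  maxShift <- min(as.integer(maxShift), n - 1L)
  cc <- fftCrossCorrelation(s@intensity, reference@intensity)
  best <- NULL; bestVal <- -Inf
  for (d in orderedLags(maxShift)) {
    idx <- (d %% n) + 1L
    if (is.infinite(bestVal) ||
        cc[idx] > bestVal + 1e-12 * max(1, abs(bestVal))) {
      bestVal <- cc[idx]; best <- d
    }
  }
  lag <- -best
  out <- shiftSpectrum(s, lag)
  out@history[length(out@history)] <- sprintf("alignFFT(lag=%d)", lag)
  list(spectrum = out, lag = lag)
}

# best corrective lag for one segment against a target segment, by
# exhaustive search over boundary-filled shifts
bestSegmentLag <- function(seg, targetSeg, maxShift) {
  best <- 0L; bestVal <- -Inf
  for (lag in orderedLags(maxShift)) {
    v <- sum(shiftVector(seg, lag) * targetSeg)
    if (is.infinite(bestVal) || v > bestVal + 1e-12 * max(1, abs(bestVal))) {
      bestVal <- v; best <- lag
    }
  }
  best
}

#' Interval-wise co-shifting of a set of spectra
#'
#' For each interval, every spectrum is independently shifted by the integer
#' lag (bounded by `maxShift`) that maximizes its correlation with the target
#' spectrum restricted to that interval; points outside the intervals are
#' untouched. The target is the pointwise median (default) or mean of the
#' set, or one of its members.
#'
#' @param spectra list of [Spectrum-class] on a shared grid.
#' @param intervals list of ppm intervals `c(lo, hi)`; must not overlap.
#' @param target `"median"`, `"mean"`, or `"index"`.
#' @param index target spectrum index when `target = "index"`.
#' @param maxShift largest displacement considered (bins).
#' @return The list of aligned spectra, with an attribute `"lags"` holding
#'   the spectra x intervals matrix of applied lags.
#' @export
alignIcoshift <- function(spectra, intervals, target = c("median", "mean",
                                                         "index"),
                          index = 1L, maxShift = 50L) {
  target <- match.arg(target)
  if (length(spectra) == 0L) return(spectra)
  grid <- spectra[[1]]@ppm
  for (s in spectra)
    if (length(s@ppm) != length(grid) || max(abs(s@ppm - grid)) > 1e-9)
      stop("all spectra must share an identical ppm grid")
  if (length(intervals)) {
    spans <- t(vapply(intervals, range, numeric(2)))
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)]))
      stop("intervals must not overlap")
  }
  mat <- do.call(rbind, lapply(spectra, slot, "intensity"))
  targetVec <- switch(target,
    median = apply(mat, 2, median),
    mean = colMeans(mat),
    index = mat[index, ])
  lags <- matrix(0L, length(spectra), length(intervals))
  for (j in seq_along(intervals)) {
    sel <- which(grid >= min(intervals[[j]]) & grid <= max(intervals[[j]]))
    if (length(sel) < 2L) next
    tseg <- targetVec[sel]
    for (i in seq_along(spectra)) {
      lag <- bestSegmentLag(mat[i, sel], tseg, maxShift)
      lags[i, j] <- lag
      if (lag != 0L) mat[i, sel] <- shiftVector(mat[i, sel], lag)
    }
  }
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    s@intensity <- mat[i, ]
    s <- addHistory(s, sprintf("alignIcoshift(target=%s,lags=[%s])", target,
                               paste(lags[i, ], collapse = ",")))
    out[[i]] <- s
  }
  attr(out, "lags") <- lags
  out
}
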