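#' Spectral preprocessing
#'
#' Mirrors the conventional 1D proton workflow for aqueous extracts:
#' exponential apodization of the time-domain signal, Fourier transform,
#' normalization (by the reference peak around 0 ppm, or by total spectral
#' area over -0.5..10 ppm), and removal of undesired regions. Phase
#' correction is a no-op hook ([phaseCorrect()]): simulated spectra are
#' generated already phased, and the hook marks where a real-data extension
#' would act.
#'
#' @name preprocessing
NULL

# trapezoidal integral of y over x restricted to [window[1], window[2]]
integrateWindow <- function(x, y, window) {
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  keep <- x >= min(window) & x <= max(window)
  if (sum(keep) < 2L) return(0)
  xs <- x[keep]; ys <- y[keep]
  sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
}

#' Exponential apodization (line broadening)
#'
#' Multiplies the free-induction decay pointwise by `exp(-pi * lb * t)` with
#' `t = k * dwell`, trading resolution for signal-to-noise. `lb` is the line
#' broadening in Hz; `lb = 1` is the conventional "exp 1" setting.
#'
#' @param fid a [Fid-class].
#' @param lb line broadening (Hz), >= 0.
#' @return The apodized [Fid-class].
#' @export
apodizeExponential <- function(fid, lb = 1) {
  if (length(lb) != 1L || !is.finite(lb) || lb < 0)
    stop("lb must be a single number >= 0")
  k <- seq_along(fid@signal) - 1L
  Fid(fid@signal * exp(-pi * lb * k * fid@dwell), fid@dwell)
}

#' Fourier transform a FID onto a ppm axis
#'
#' Computes the discrete Fourier transform of the time-domain signal and maps
#' the (fftshifted) frequency axis onto chemical shift given the spectrometer
#' frequency and a reference offset. The default returns the real
#' (absorption) part; `mode = "modulus"` returns the magnitude spectrum, for
#' which the transform conserves signal energy.
#'
#' @param fid a [Fid-class].
#' @param frequencyMHz spectrometer frequency (MHz); 600 by default.
#' @param refPpm chemical shift assigned to zero frequency.
#' @param mode `"real"` or `"modulus"`.
#' @return A [Spectrum-class] with ascending ppm axis.
#' @export
fourierSpectrum <- function(fid, frequencyMHz = 600, refPpm = 0,
                            mode = c("real", "modulus")) {
  mode <- match.arg(mode)
  n <- length(fid@signal)
  ft <- fft(fid@signal)
  # fftshift: frequencies above Nyquist wrap to negative, axis ascends
  k <- seq_len(n) - 1L
  half <- ceiling(n / 2)
  freq <- ifelse(k < half, k, k - n) / (n * fid@dwell)
  ord <- order(freq)
  vals <- ft[ord]
  y <- if (mode == "real") Re(vals) else Mod(vals)
  ppmAxis <- refPpm + freq[ord] / frequencyMHz
  Spectrum(ppmAxis, y, history = sprintf("fourierSpectrum(mode=%s)", mode))
}

#' Normalize by the reference (DSS) peak
#'
#' Divides all intensities by the integrated intensity over the reference
#' window (DSS resonates at 0 ppm), putting spectra on a common
#' reference-concentration scale.
#'
#' @param s a [Spectrum-class].
#' @param refWindow ppm interval of the reference peak.
#' @return The normalized [Spectrum-class].
#' @export
normalizeReferencePeak <- function(s, refWindow = c(-0.05, 0.05)) {
  a <- integrateWindow(s@ppm, s@intensity, refWindow)
  if (!is.finite(a) || a <= 0)
    stop("nonpositive reference-peak integral; cannot normalize")
  s@intensity <- s@intensity / a
  addHistory(s, sprintf("normalizeReferencePeak(window=[%g,%g])",
                        refWindow[1], refWindow[2]))
}

#' Normalize by total spectral area
#'
#' Scales the spectrum so the integral over the analysis region (by default
#' -0.5..10 ppm) equals one, the convention used for library standards.
#'
#' @param s a [Spectrum-class].
#' @param region ppm interval included in the normalization.
#' @return The normalized [Spectrum-class].
#' @export
normalizeTotalArea <- function(s, region = c(-0.5, 10)) {
  a <- integrateWindow(s@ppm, s@intensity, region)
  if (!is.finite(a) || a <= 0)
    stop("nonpositive total area; cannot normalize")
  s@intensity <- s@intensity / a
  addHistory(s, sprintf("normalizeTotalArea(region=[%g,%g])",
                        region[1], region[2]))
}

#' Keep only a chemical-shift interval
#'
#' @param s a [Spectrum-class].
#' @param keep ppm interval to retain (inclusive).
#' @return The trimmed [Spectrum-class].
#' @export
trimRegion <- function(s, keep) {
  sel <- s@ppm >= min(keep) & s@ppm <= max(keep)
  if (sum(sel) < 2L) stop("trim would leave fewer than 2 points")
  s@ppm <- s@ppm[sel]
  s@intensity <- s@intensity[sel]
  addHistory(s, sprintf("trimRegion(keep=[%g,%g])", min(keep), max(keep)))
}

#' Remove a chemical-shift interval (e.g. the residual water region)
#'
#' Drops all points strictly inside the open interval; equivalent to trimming
#' the spectrum on either side of the window and rejoining.
#'
#' @param s a [Spectrum-class].
#' @param window open ppm interval to remove; the default is the residual
#'   water region.
#' @return The [Spectrum-class] without the excluded points.
#' @export
excludeRegion <- function(s, window = c(4.5, 5.0)) {
  sel <- !(s@ppm > min(window) & s@ppm < max(window))
  if (sum(sel) < 2L) stop("exclusion would leave fewer than 2 points")
  s@ppm <- s@ppm[sel]
  s@intensity <- s@intensity[sel]
  addHistory(s, sprintf("excludeRegion(window=[%g,%g])",
                        min(window), max(window)))
}

#' Phase correction hook
#'
#' A no-op placeholder marking where global/manual phase correction would act
#' on measured data; simulated spectra are generated already phased.
#'
#' @param s a [Spectrum-class].
#' @param phi0 zero-order phase (radians); recorded but not applied.
#' @return The unchanged [Spectrum-class] with a history record.
#' @export
phaseCorrect <- function(s, phi0 = 0) {
  addHistory(s, sprintf("phaseCorrect(phi0=%g,noop)", phi0))
}
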