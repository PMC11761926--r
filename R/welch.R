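#' Welch estimation parameters
#'
#' Parameters of the Welch overlapped-periodogram estimator used for both
#' power spectral densities and magnitude-squared coherence. The defaults
#' (2 s symmetric Hamming window, 25% overlap) give, on a 30 s trial sampled
#' at 1200 Hz, 19 segments of 2400 samples and a 0.5 Hz frequency grid.
#'
#' `overlap` is a fraction of the window length; the hop between successive
#' segments is `W - round(overlap * W)` samples, where `W` is the window
#' length in samples. Trailing samples that do not fill a complete window are
#' discarded.
#'
#' @param window_duration Window length in seconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param fs Sampling rate in Hz.
#' @param detrend Per-segment detrending: `"none"` (default) or `"constant"`
#'   (subtract the segment mean before windowing).
#' @return An object of class `welch_params`.
#' @export
welch_params <- function(window_duration = 2, overlap = 0.25, fs = 1200,
                         detrend = c("none", "constant")) {
  detrend <- match.arg(detrend)
  stopifnot(window_duration > 0, fs > 0, overlap >= 0, overlap < 1)
  W <- window_duration * fs
  if (abs(W - round(W)) > 1e-8) {
    stop("window_duration * fs must be an integer sample count")
  }
  W <- as.integer(round(W))
  structure(
    list(window_duration = window_duration, overlap = overlap, fs = fs,
         window_samples = W, step = W - as.integer(round(overlap * W)),
         detrend = detrend),
    class = "welch_params"
  )
}

#' @export
print.welch_params <- function(x, ...) {
  cat(sprintf(
    "Welch parameters: %g s Hamming window (%d samples), %g%% overlap, fs = %g Hz\n",
    x$window_duration, x$window_samples, 100 * x$overlap, x$fs))
  cat(sprintf("  hop %d samples, frequency resolution %g Hz\n",
              x$step, 1 / x$window_duration))
  invisible(x)
}

#' Number of complete Welch segments
#'
#' `floor((n - W) / S) + 1` with window length `W` and hop `S`; a trailing
#' partial segment is discarded. With a 30 s trial at 1200 Hz and the default
#' 2 s / 25%-overlap parameters this is 19 segments.
#'
#' @param n Signal length in samples.
#' @param params A [welch_params()] object.
#' @return Integer segment count.
#' @export
segment_count <- function(n, params = welch_params()) {
  stopifnot(inherits(params, "welch_params"))
  if (n < params$window_samples) {
    stop(sprintf("signal too short for Welch segmentation: %d samples < %d window samples",
                 n, params$window_samples))
  }
  as.integer(floor((n - params$window_samples) / params$step) + 1L)
}

# Symmetric Hamming window, 0.54 - 0.46*cos(2*pi*n/(N-1)), n = 0..N-1.
hamming_window <- function(N) {
  if (N == 1) return(1)
  n <- seq_len(N) - 1
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

# One-sided frequency grid for a window of W samples at rate fs.
welch_grid <- function(W, fs) {
  seq(0, floor(W / 2)) * fs / W
}

# FFTs of all windowed segments of x: complex matrix, (W/2+1) x L.
# Shared by PSD, cross-spectrum and MSC computations so that both channels
# of a pair are always segmented identically.
segment_ffts <- function(x, params) {
  W <- params$window_samples
  L <- segment_count(length(x), params)
  starts <- (seq_len(L) - 1L) * params$step
  w <- hamming_window(W)
  seg <- matrix(0, nrow = W, ncol = L)
  for (j in seq_len(L)) {
    s <- x[(starts[j] + 1L):(starts[j] + W)]
    if (params$detrend == "constant") s <- s - mean(s)
    seg[, j] <- s * w
  }
  X <- stats::mvfft(seg)
  X[seq_len(floor(W / 2) + 1L), , drop = FALSE]
}

# One-sided density scaling: 1/(fs * sum(w^2)), interior bins doubled.
onesided_scale <- function(W, fs) {
  w <- hamming_window(W)
  scale <- 1 / (fs * sum(w^2))
  half <- floor(W / 2) + 1L
  mult <- rep(2, half)
  mult[1] <- 1
  if (W %% 2 == 0) mult[half] <- 1
  list(scale = scale, mult = mult)
}

#' Welch power spectral density
#'
#' One-sided PSD estimate by averaging windowed, overlapped periodograms.
#' Satisfies a Parseval-style consistency: the integral of the density over
#' the one-sided grid approximates the signal variance for broadband,
#' zero-mean input.
#'
#' @param x Numeric signal.
#' @param params A [welch_params()] object.
#' @return An object of class `psd_estimate`: list with `freq` (Hz),
#'   `density` (units^2/Hz), `L` (segment count), `params`.
#' @export
welch_psd <- function(x, params = welch_params()) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  L <- segment_count(length(x), params)
  if (L < 2) {
    stop("fewer than 2 Welch segments available; provide a longer signal")
  }
  X <- segment_ffts(x, params)
  sc <- onesided_scale(params$window_samples, params$fs)
  dens <- rowMeans(abs(X)^2) * sc$scale * sc$mult
  structure(
    list(freq = welch_grid(params$window_samples, params$fs),
         density = dens, L = L, params = params),
    class = "psd_estimate"
  )
}

#' Welch auto- and cross-spectra of a signal pair
#'
#' Averaged one-sided auto-spectra `Pxx`, `Pyy` and complex cross-spectrum
#' `Pxy` over identically segmented, Hamming-windowed, Fourier-transformed
#' segments of the two signals.
#'
#' @param x,y Equal-length numeric signals.
#' @param params A [welch_params()] object.
#' @return List with `freq`, `Pxx`, `Pyy` (real, nonnegative), `Pxy`
#'   (complex), `L`.
#' @export
welch_cross_spectra <- function(x, y, params = welch_params()) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length for cross-spectral estimation")
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  L <- segment_count(length(x), params)
  if (L < 2) {
    stop("fewer than 2 Welch segments available; provide longer signals")
  }
  X <- segment_ffts(x, params)
  Y <- segment_ffts(y, params)
  sc <- onesided_scale(params$window_samples, params$fs)
  m <- sc$scale * sc$mult
  list(freq = welch_grid(params$window_samples, params$fs),
       Pxx = rowMeans(abs(X)^2) * m,
       Pyy = rowMeans(abs(Y)^2) * m,
       Pxy = rowMeans(Conj(X) * Y) * m,
       L = L)
}

#' Magnitude-squared coherence spectrum
#'
#' MSC between two signals on the Welch frequency grid:
#' `Cxy(f) = |Pxy(f)|^2 / (Pxx(f) * Pyy(f))`. Values lie in `[0, 1]` by the
#' Cauchy-Schwarz inequality applied to the segment-averaged spectra; no
#' post-hoc clipping is applied. Bins where an auto-spectrum vanishes are
#' reported as `NA` (undefined), never coerced to 0 or 1. At least two
#' segments are required: with a single segment MSC is identically 1.
#'
#' @param x,y Equal-length numeric signals.
#' @param params A [welch_params()] object.
#' @return An object of class `coherence_spectrum`: list with `freq`, `msc`,
#'   `L`, `Pxx`, `Pyy`, `Pxy`, `params`.
#' @export
msc_spectrum <- function(x, y, params = welch_params()) {
  cs <- welch_cross_spectra(x, y, params)
  denom <- cs$Pxx * cs$Pyy
  msc <- rep(NA_real_, length(denom))
  ok <- denom > 0
  msc[ok] <- Mod(cs$Pxy[ok])^2 / denom[ok]
  structure(
    list(freq = cs$freq, msc = msc, L = cs$L,
         Pxx = cs$Pxx, Pyy = cs$Pyy, Pxy = cs$Pxy, params = params),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "MSC spectrum: %d bins, 0-%g Hz (resolution %g Hz), L = %d segments\n",
    length(x$freq), max(x$freq), x$freq[2] - x$freq[1], x$L))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted arithmetic mean of the MSC spectrum over the bins falling in a
#' half-open band `[lo, hi)`. Undefined (`NA`) bins are excluded from the
#' mean and counted.
#'
#' @param spectrum A `coherence_spectrum` from [msc_spectrum()].
#' @param lo,hi Band edges in Hz (half-open, `lo <= f < hi`).
#' @return List with `value` (mean MSC), `n_bins` (bins in band),
#'   `n_undefined` (excluded bins).
#' @export
band_average <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "coherence_spectrum"), lo < hi)
  sel <- spectrum$freq >= lo & spectrum$freq < hi
  if (!any(sel)) {
    stop(sprintf("band [%g, %g) contains no frequency bins", lo, hi))
  }
  vals <- spectrum$msc[sel]
  n_undef <- sum(is.na(vals))
  if (n_undef == length(vals)) {
    stop(sprintf("band [%g, %g) contains only undefined bins", lo, hi))
  }
  list(value = mean(vals, na.rm = TRUE),
       n_bins = sum(sel), n_undefined = n_undef)
}

#' Zero-coherence significance bound
#'
#' The `1 - alpha` quantile of estimated MSC between independent signals when
#' the estimate averages `L` independent segments: `1 - alpha^(1/(L - 1))`.
#' Estimates below this bound are consistent with zero true coherence. Used
#' for quality control and simulation checks, not for the group-level
#' inference.
#'
#' @param L Segment count (>= 2).
#' @param alpha Significance level in (0, 1).
#' @return Threshold in (0, 1), decreasing in `L`.
#' @examples
#' zero_coherence_bound(19)  # ~0.153
#' @export
zero_coherence_bound <- function(L, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(L < 2)) stop("zero-coherence bound requires L >= 2 segments")
  1 - alpha^(1 / (L - 1))
}
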