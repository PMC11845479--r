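# Segmental spectral machinery shared by the feature extractor and the
# quality indices: Hanning-windowed one-sided periodograms with power
# (sum w^2) normalisation, so that integrating the PSD over frequency
# recovers the mean signal power (a^2/2 for a pure tone of amplitude a).

#' Frequency bands used throughout the package
#'
#' Clinical EEG bands as used for ECT seizure analysis:
#' delta 0.7-3.5 Hz, theta 3.5-8 Hz, alpha 8-13 Hz, beta 13-25 Hz.
#' Band membership of an FFT bin is half-open: `low <= f < high`.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.7, 3.5), theta = c(3.5, 8),
       alpha = c(8, 13),    beta  = c(13, 25))
}

#' One-sided power spectral density of one segment
#'
#' Hanning-windowed periodogram with `sum(w^2)` normalisation. With a
#' 256-sample window at 200 Hz the resolution is 200/256 ~ 0.78 Hz. The
#' segment mean is removed before windowing, so DC offset cannot leak
#' into the delta band through the window's main lobe.
#'
#' @param x numeric vector of samples (one channel of one segment).
#' @param sampling_rate sampling frequency in Hz.
#' @return A list with `freq` (Hz) and `psd` (uV^2/Hz), one-sided.
#' @export
segment_psd <- function(x, sampling_rate) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # periodic Hanning
  s2 <- sum(w^2)
  X <- stats::fft(x * w)
  half <- seq_len(floor(n / 2) + 1L)
  p <- (Mod(X[half])^2) / (sampling_rate * s2)
  # one-sided doubling, except DC and (for even n) Nyquist
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(half)] <- 1
  list(freq = (half - 1) * sampling_rate / n, psd = p * dbl)
}

#' Band power of one segment
#'
#' Integrates the one-sided PSD over a frequency band, assigning each FFT
#' bin to the half-open interval `[low, high)`.
#'
#' @param x numeric sample vector.
#' @param sampling_rate Hz.
#' @param band `c(low, high)` in Hz; defaults to the full 0.7-25 Hz range.
#' @return Band power in uV^2.
#' @export
band_power <- function(x, sampling_rate, band = c(0.7, 25)) {
  sp <- segment_psd(x, sampling_rate)
  sel <- sp$freq >= band[1] & sp$freq < band[2]
  df <- sampling_rate / length(x)
  sum(sp$psd[sel]) * df
}

#' Band powers of one segment for all clinical bands
#'
#' @inheritParams band_power
#' @param bands named list of bands as from [eeg_bands()].
#' @return Named numeric vector: one power per band (uV^2) plus `total`
#'   (0.7-25 Hz).
#' @export
band_powers <- function(x, sampling_rate, bands = eeg_bands()) {
  sp <- segment_psd(x, sampling_rate)
  df <- sampling_rate / length(x)
  out <- vapply(bands, function(b) {
    sum(sp$psd[sp$freq >= b[1] & sp$freq < b[2]]) * df
  }, numeric(1))
  total <- sum(sp$psd[sp$freq >= 0.7 & sp$freq < 25]) * df
  c(out, total = total)
}

# Welch magnitude-squared coherence between two channels over one analysis
# window, using Hanning sub-windows of `nper` samples with 50% overlap.
# Returns mean coherence over [0.7, 25) Hz.
welch_coherence <- function(x, y, sampling_rate, nper = 256L,
                            band = c(0.7, 25)) {
  n <- length(x)
  step <- nper %/% 2L
  starts <- seq(1L, n - nper + 1L, by = step)
  if (length(starts) < 2L)
    stop("welch_coherence: window too short for coherence averaging")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)
  half <- seq_len(nper %/% 2L + 1L)
  sxx <- syy <- numeric(length(half))
  sxy <- complex(length(half))
  for (s in starts) {
    xs <- x[s:(s + nper - 1L)] * w
    ys <- y[s:(s + nper - 1L)] * w
    X <- stats::fft(xs)[half]; Y <- stats::fft(ys)[half]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  freq <- (half - 1) * sampling_rate / nper
  coh <- Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.xmin)
  sel <- freq >= band[1] & freq < band[2]
  mean(coh[sel])
}
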