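#' Zero-phase band-pass filter
#'
#' Filters a single-channel series to the analysis band by masking in
#' the frequency domain: the DFT is multiplied by a gain that is 1
#' inside [low, high], falls to 0 over a cosine roll-off of
#' \code{rolloff} Hz outside each edge, and is 0 elsewhere (the mean /
#' DC component is always removed). Frequency-domain masking is exactly
#' zero-phase, so lag relationships between channels filtered the same
#' way — on which Granger-causal estimates depend — are not distorted.
#'
#' @param x numeric series (length >= 32).
#' @param band c(low, high) in Hz, strictly inside (0, Nyquist).
#' @param sampling_interval seconds per sample (default 2, Nyquist
#'   0.25 Hz).
#' @param rolloff transition width in Hz (default 0.01).
#' @return filtered series, same length, zero mean.
#' @export
bandpass_filter <- function(x, band = c(0.05, 0.15), sampling_interval = 2,
                            rolloff = 0.01) {
  x <- as.numeric(x)
  stop_if_not_finite(x, "time course")
  n <- length(x)
  stopifnot(n >= 32L)
  nyq <- 1 / (2 * sampling_interval)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  freqs <- (seq_len(n) - 1) / (n * sampling_interval)
  freqs <- pmin(freqs, 1 / sampling_interval - freqs)  # fold to [0, Nyquist]
  gain <- numeric(n)
  inb <- freqs >= band[1] & freqs <= band[2]
  gain[inb] <- 1
  lo_ramp <- freqs >= band[1] - rolloff & freqs < band[1]
  gain[lo_ramp] <- 0.5 * (1 + cos(pi * (band[1] - freqs[lo_ramp]) / rolloff))
  hi_ramp <- freqs > band[2] & freqs <= band[2] + rolloff
  gain[hi_ramp] <- 0.5 * (1 + cos(pi * (freqs[hi_ramp] - band[2]) / rolloff))
  gain[1] <- 0
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Welch averaged-periodogram power spectral density
#'
#' Hann-tapered modified periodograms of 50\%-overlapping segments,
#' averaged; one-sided density scaled so that the integral of the
#' density over frequency approximates the series variance (Parseval).
#' This is the standard variance/resolution trade-off for short
#' resting-state series (64-sample segments on a 256-sample series give
#' 7 averaged segments).
#'
#' @param x numeric series.
#' @param sampling_interval seconds per sample.
#' @param segment_length samples per segment (default 64; truncated to
#'   the series length if longer).
#' @param overlap fractional segment overlap (default 0.5).
#' @return object of class \code{psd_spectrum}: list with
#'   \code{frequencies} (Hz, excluding DC) and \code{density} (units^2
#'   per Hz).
#' @export
welch_psd <- function(x, sampling_interval = 2, segment_length = 64L,
                      overlap = 0.5) {
  x <- as.numeric(x)
  stop_if_not_finite(x, "time course")
  n <- length(x)
  nseg <- min(segment_length, n)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  fs <- 1 / sampling_interval
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 * scale
    half <- P[2:(nf + 1)]
    # one-sided doubling (Nyquist bin, if present as bin nf+1 of an even
    # nseg, is not doubled)
    dbl <- rep(2, nf)
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + half * dbl
  }
  density <- acc / length(starts)
  freqs <- (1:nf) * fs / nseg
  structure(list(frequencies = freqs, density = density,
                 method = sprintf("Welch, Hann, %d-sample segments, %d%% overlap",
                                  nseg, round(100 * overlap))),
            class = "psd_spectrum")
}

#' @export
print.psd_spectrum <- function(x, ...) {
  cat(sprintf("PSD (%s): %d frequencies %.4f-%.4f Hz\n", x$method,
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Mean power spectral density within a band
#'
#' Average of the [welch_psd()] density over the grid frequencies inside
#' [low, high]; the per-subject spectral summary compared between groups.
#'
#' @inheritParams welch_psd
#' @param band c(low, high) in Hz.
#' @param ... passed to [welch_psd()].
#' @return mean density in the band (units^2 per Hz).
#' @export
mean_band_psd <- function(x, band = c(0.05, 0.15), sampling_interval = 2, ...) {
  psd <- welch_psd(x, sampling_interval = sampling_interval, ...)
  inb <- psd$frequencies >= band[1] & psd$frequencies <= band[2]
  if (!any(inb))
    stop("no PSD grid points inside the band (series too short)",
         call. = FALSE)
  mean(psd$density[inb])
}
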