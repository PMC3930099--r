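#' Frequency-bin grid for GPDC spectra
#'
#' Bin centres covering the analysis band at a fixed pitch; with the
#' defaults (0.05-0.15 Hz at 0.002 Hz pitch) this is the 50-centre grid
#' 0.051, 0.053, ..., 0.149 Hz.
#'
#' @param low,high band edges in Hz.
#' @param width bin width in Hz.
#' @return numeric vector of bin centres (Hz).
#' @export
gpdc_bins <- function(low = 0.05, high = 0.15, width = 0.002) {
  stopifnot(low < high, width > 0)
  seq(low + width / 2, high - width / 2, by = width)
}

#' Generalised partial directed coherence spectrum of a VAR model
#'
#' For each frequency bin centre f (normalised frequency
#' \eqn{\lambda = f \Delta t} cycles per sample) the transfer polynomial
#' \eqn{\bar a_{ij}(\lambda) = \delta_{ij} - \sum_{l=1}^p a_{ij}^{(l)}
#' e^{-i 2\pi\lambda l}} is evaluated and the squared-modulus GPDC from
#' channel j to channel i is
#' \deqn{|\pi_{ij}(\lambda)|^2 = \frac{|\bar a_{ij}(\lambda)|^2 / \sigma_i^2}
#'   {\sum_{m=1}^k |\bar a_{mj}(\lambda)|^2 / \sigma_m^2}.}
#' The inverse residual-standard-deviation weighting makes the measure
#' invariant to channel scale; by construction every value lies in
#' [0, 1] and each source column sums to 1 over targets (including the
#' diagonal term, which is not a directed path).
#'
#' @param model a \code{var_model}.
#' @param bins frequency bin centres in Hz (default [gpdc_bins()]);
#'   must lie strictly inside (0, Nyquist).
#' @param sampling_interval seconds per sample (default 2).
#' @param squared return the squared modulus (default, interpretable as
#'   a proportion of sent power) or the amplitude \eqn{|\pi_{ij}|}.
#' @return object of class \code{gpdc_spectrum}: list with \code{values}
#'   (k-by-k-by-nbins array, target i in rows, source j in columns),
#'   \code{bins} (Hz), \code{squared}, \code{sampling_interval}.
#' @export
gpdc_spectrum <- function(model, bins = gpdc_bins(), sampling_interval = 2,
                          squared = TRUE) {
  stopifnot(inherits(model, "var_model"))
  nyq <- 1 / (2 * sampling_interval)
  if (any(bins <= 0 | bins >= nyq))
    stop("frequency bins must lie strictly inside (0, Nyquist = ", nyq, " Hz)",
         call. = FALSE)
  sig2 <- diag(model$Sigma)
  if (any(sig2 <= 0)) stop("zero residual variance", call. = FALSE)
  k <- model$k
  vals <- array(NA_real_, c(k, k, length(bins)))
  w <- 1 / sig2                       # 1 / sigma_i^2
  for (b in seq_along(bins)) {
    lambda <- bins[b] * sampling_interval
    abar <- diag(1 + 0i, k)
    for (l in seq_len(model$p))
      abar <- abar - model$A[[l]] * exp(-2i * pi * lambda * l)
    num <- Mod(abar)^2 * w            # |abar_ij|^2 / sigma_i^2
    den <- colSums(num)               # per source column j
    vals[, , b] <- sweep(num, 2, den, `/`)
  }
  if (!squared) vals <- sqrt(vals)
  structure(list(values = vals, bins = bins, squared = squared,
                 sampling_interval = sampling_interval),
            class = "gpdc_spectrum")
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  k <- dim(x$values)[1]
  off <- x$values
  for (b in seq_len(dim(off)[3])) diag(off[, , b]) <- NA
  cat(sprintf("GPDC spectrum (%s): k = %d, %d bins %.3f-%.3f Hz\n",
              if (x$squared) "squared modulus" else "amplitude",
              k, length(x$bins), min(x$bins), max(x$bins)))
  cat(sprintf("  off-diagonal range: %.4f-%.4f\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Plot a GPDC spectrum
#'
#' One panel per ordered path (target row, source column), GPDC against
#' frequency; diagonal panels are left blank (not directed paths).
#'
#' @param x a \code{gpdc_spectrum}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gpdc_spectrum <- function(x, ...) {
  k <- dim(x$values)[1]
  op <- graphics::par(mfrow = c(k, k), mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { graphics::plot.new(); next }
    graphics::plot(x$bins, x$values[i, j, ], type = "l", ylim = c(0, 1),
                   xlab = "", ylab = "", main = sprintf("%d → %d", j, i),
                   ...)
  }
  invisible(x)
}

#' Band-limited GPDC spectrum for one subject's time courses
#'
#' The full per-subject pipeline for one subject: band-pass each channel
#' to the analysis band, fit a VAR of the given order, and evaluate the
#' GPDC spectrum on the binned grid spanning the band.
#'
#' @param timecourses channels-by-time matrix.
#' @param order VAR order p (typically from [select_order_group()]).
#' @param band analysis band c(low, high) in Hz (default 0.05-0.15).
#' @param sampling_interval seconds per sample.
#' @param bin_width frequency bin width in Hz (default 0.002, giving 50
#'   bins over the default band).
#' @param squared squared-modulus (default) or amplitude values.
#' @param filter band-pass the channels before fitting (default TRUE,
#'   appropriate for broadband recorded signals). Set FALSE for series
#'   that are already stationary zero-mean realisations of a
#'   finite-order VAR (e.g. synthetic cohorts): band-limiting such
#'   series makes the VAR misspecified — the filtered process has no
#'   finite autoregressive representation — which inflates the selected
#'   order and can induce spurious reverse-direction coupling.
#' @return a \code{gpdc_spectrum} (see [gpdc_spectrum()]).
#' @export
subject_gpdc <- function(timecourses, order, band = c(0.05, 0.15),
                         sampling_interval = 2, bin_width = 0.002,
                         squared = TRUE, filter = TRUE) {
  Y <- as.matrix(timecourses)
  if (filter)
    Y <- t(apply(Y, 1, bandpass_filter, band = band,
                 sampling_interval = sampling_interval))
  model <- fit_var(Y, order)
  gpdc_spectrum(model, bins = gpdc_bins(band[1], band[2], bin_width),
                sampling_interval = sampling_interval, squared = squared)
}

#' Per-subject GPDC spectra for a whole cohort
#'
#' Applies [subject_gpdc()] to every subject; the VAR order is selected
#' once at group level by BIC on the band-passed series unless supplied.
#'
#' @param cohort a \code{cohort} (see [generate_cohort()]) or list of
#'   channels-by-time matrices.
#' @param order VAR order; \code{NULL} selects it with
#'   [select_order_group()] on the band-passed time courses.
#' @param p_max candidate order bound when selecting.
#' @inheritParams subject_gpdc
#' @return list with \code{spectra} (per-subject \code{gpdc_spectrum}),
#'   \code{order} used, and \code{labels} (group labels when the input
#'   is a cohort).
#' @export
cohort_gpdc <- function(cohort, order = NULL, band = c(0.05, 0.15),
                        sampling_interval = 2, bin_width = 0.002,
                        p_max = 5L, squared = TRUE, filter = TRUE) {
  if (inherits(cohort, "cohort")) {
    tcs <- lapply(cohort$subjects, `[[`, "timecourses")
    labels <- cohort_labels(cohort)
    sampling_interval <- cohort$sampling_interval
  } else {
    tcs <- cohort
    labels <- NULL
  }
  filt <- if (filter) lapply(tcs, function(Y)
    t(apply(as.matrix(Y), 1, bandpass_filter, band = band,
            sampling_interval = sampling_interval)))
  else lapply(tcs, as.matrix)
  if (is.null(order))
    order <- select_order_group(filt, p_max = p_max)$order
  spectra <- lapply(filt, function(Y)
    gpdc_spectrum(fit_var(Y, order),
                  bins = gpdc_bins(band[1], band[2], bin_width),
                  sampling_interval = sampling_interval, squared = squared))
  list(spectra = spectra, order = order, labels = labels)
}
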