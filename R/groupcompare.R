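#' Normality gate for choosing parametric vs non-parametric tests
#'
#' Routes a sample to non-parametric testing when its shape precludes a
#' normality assumption: non-parametric iff |skewness| > 2 or kurtosis
#' > 7. Kurtosis is on the Pearson (non-excess) scale, so a normal
#' sample sits near 3; both inequalities are strict, so boundary values
#' stay parametric.
#'
#' @param values numeric sample (n >= 4, non-zero variance).
#' @param skew_cutoff,kurt_cutoff rule cut-offs (defaults 2 and 7).
#' @return list with \code{route} ("parametric" or "nonparametric"),
#'   \code{skewness} and \code{kurtosis}.
#' @export
normality_gate <- function(values, skew_cutoff = 2, kurt_cutoff = 7) {
  x <- as.numeric(values)
  stopifnot(length(x) >= 4L)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) stop("zero-variance sample", call. = FALSE)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2      # Pearson scale: normal ~ 3
  list(route = if (abs(skew) > skew_cutoff || kurt > kurt_cutoff)
    "nonparametric" else "parametric",
    skewness = skew, kurtosis = kurt)
}

#' Two-group Kruskal-Wallis test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value
#' on 1 degree of freedom (two groups). Delegates to
#' [stats::kruskal.test()].
#'
#' @param group_a,group_b numeric samples (each n >= 2).
#' @return list with \code{H} and \code{p_value}.
#' @export
kruskal_wallis <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (length(unique(c(a, b))) == 1L)
    stop("all values tied across both groups", call. = FALSE)
  kt <- stats::kruskal.test(list(a, b))
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

# Vectorised two-group Kruskal-Wallis over the columns of two matrices
# (subjects x bins). Same statistic as stats::kruskal.test with tie
# correction; used where thousands of bin-wise tests are needed.
kw_columns <- function(A, B) {
  na <- nrow(A); nb <- nrow(B); N <- na + nb
  X <- rbind(A, B)
  H <- p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    Ra <- sum(r[seq_len(na)])
    Rb <- sum(r) - Ra
    h <- 12 / (N * (N + 1)) * (Ra^2 / na + Rb^2 / nb) - 3 * (N + 1)
    ties <- table(X[, j])
    cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
    H[j] <- if (cf > 0) h / cf else NA_real_
    p[j] <- stats::pchisq(H[j], df = 1, lower.tail = FALSE)
  }
  list(H = H, p = p)
}

#' Bin-wise group test with the spectral-clustering (5-bin run) rule
#'
#' For every ordered path j to i and every frequency bin, GPDC values
#' are compared between the two groups with a Kruskal-Wallis test. A
#' between-group difference is reported as significant for a path only
#' when at least \code{run_length} neighbouring bins are below
#' \code{alpha} with a consistent effect direction; this run criterion
#' suppresses isolated-bin false positives. Each maximal qualifying run
#' becomes one significant band with its frequency extent.
#'
#' @param gpdc_a,gpdc_b lists of \code{gpdc_spectrum} objects (per
#'   subject) for groups A and B, sharing channels and bins.
#' @param run_length minimum neighbouring significant bins (default 5).
#' @param alpha per-bin significance level (default .05, i.e. the 95
#'   percent threshold).
#' @return data.frame of class \code{path_band_result} with one row per
#'   (path, band): source, target, band_low_hz, band_high_hz, n_bins,
#'   min_p, direction ("A>B" or "B>A"). Zero rows when nothing passes.
#' @export
binwise_cluster_test <- function(gpdc_a, gpdc_b, run_length = 5L,
                                 alpha = 0.05) {
  stopifnot(length(gpdc_a) >= 2L, length(gpdc_b) >= 2L)
  bins <- gpdc_a[[1L]]$bins
  k <- dim(gpdc_a[[1L]]$values)[1]
  for (g in c(gpdc_a, gpdc_b))
    stopifnot(identical(g$bins, bins), dim(g$values)[1] == k)
  stack <- function(gl, i, j) t(vapply(gl, function(g) g$values[i, j, ],
                                       numeric(length(bins))))
  out <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    A <- stack(gpdc_a, i, j); B <- stack(gpdc_b, i, j)
    kw <- kw_columns(A, B)
    dir_a <- colMeans(A) > colMeans(B)
    sig <- !is.na(kw$p) & kw$p < alpha
    # maximal runs of significant bins with a consistent direction
    runs <- rle(ifelse(sig, ifelse(dir_a, 1L, -1L), 0L))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r] == 0L || runs$lengths[r] < run_length) next
      idx <- starts[r]:ends[r]
      out[[length(out) + 1L]] <- data.frame(
        source = j, target = i,
        band_low_hz = min(bins[idx]), band_high_hz = max(bins[idx]),
        n_bins = length(idx), min_p = min(kw$p[idx]),
        direction = if (runs$values[r] == 1L) "A>B" else "B>A",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(source = integer(0), target = integer(0),
               band_low_hz = numeric(0), band_high_hz = numeric(0),
               n_bins = integer(0), min_p = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  class(res) <- c("path_band_result", "data.frame")
  attr(res, "run_length") <- run_length
  attr(res, "alpha") <- alpha
  res
}

#' Connectivity-window summary of GPDC magnitudes
#'
#' Classifies every (path, bin) GPDC value of a subject into
#' connection-strength windows — by default low [0.05, 0.20), mid
#' [0.20, 0.35) and high [0.35, 0.55) — and returns, per subject, the
#' percentage of values in each window and the mean GPDC within each
#' window. Values outside [first, last) boundaries are tracked as
#' out-of-range mass, so window percentages plus out-of-range mass sum
#' to 100.
#'
#' @param spectra list of per-subject \code{gpdc_spectrum} objects, or a
#'   list of numeric vectors of pooled off-diagonal GPDC values.
#' @param boundaries increasing window edges (default
#'   c(0.05, 0.20, 0.35, 0.55)).
#' @return data.frame, one row per subject: percentage and mean per
#'   window (columns pct_w1.., mean_w1..), \code{pct_out} and
#'   \code{mean_out} for the out-of-range mass. Empty-window means are
#'   \code{NA} (flagged missing).
#' @export
window_summary <- function(spectra, boundaries = c(0.05, 0.20, 0.35, 0.55)) {
  stopifnot(all(diff(boundaries) > 0), length(boundaries) >= 2L)
  nw <- length(boundaries) - 1L
  pull <- function(s) {
    if (inherits(s, "gpdc_spectrum")) {
      v <- s$values
      keep <- !diag(dim(v)[1])     # off-diagonal paths only
      as.numeric(apply(v, 3, function(m) m[keep]))
    } else as.numeric(s)
  }
  rows <- lapply(spectra, function(s) {
    v <- pull(s)
    w <- findInterval(v, boundaries)         # 0 = below, nw+1 = >= last edge
    inw <- w >= 1L & w <= nw
    pct <- vapply(seq_len(nw), function(i) 100 * mean(w == i), numeric(1))
    mns <- vapply(seq_len(nw), function(i)
      if (any(w == i)) mean(v[w == i]) else NA_real_, numeric(1))
    c(pct, 100 * mean(!inw), mns,
      if (any(!inw)) mean(v[!inw]) else NA_real_)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("pct_w", seq_len(nw)), "pct_out",
                  paste0("mean_w", seq_len(nw)), "mean_out")
  attr(out, "boundaries") <- boundaries
  out
}

#' Leave-one-out permutation reliability of a group test
#'
#' Re-runs a two-group test once per left-out subject (n folds for n
#' subjects) and reports the fraction of folds in which the test is
#' significant at \code{alpha}. The effect is judged reliable only when
#' that fraction strictly exceeds \code{threshold} (e.g. 0.9917, the
#' Bonferroni-corrected 95 percent threshold for six tests).
#'
#' @param test function(values_a, values_b) returning a list with a
#'   \code{p_value} element (e.g. [kruskal_wallis()]).
#' @param values per-subject values.
#' @param labels per-subject group labels (two levels; each group
#'   n >= 3).
#' @param alpha per-fold significance level.
#' @param threshold reliability threshold (proportion).
#' @return object of class \code{reliability_result}: list with
#'   \code{n_folds}, \code{fraction_significant}, \code{threshold},
#'   \code{is_reliable}.
#' @export
loo_reliability <- function(test, values, labels, alpha = 0.05,
                            threshold = 0.9917) {
  labels <- as.character(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2L, length(values) == length(labels),
            all(table(labels) >= 3L))
  n <- length(values)
  sig <- vapply(seq_len(n), function(i) {
    keep <- setdiff(seq_len(n), i)
    va <- values[keep][labels[keep] == lev[1]]
    vb <- values[keep][labels[keep] == lev[2]]
    test(va, vb)$p_value < alpha
  }, logical(1))
  frac <- mean(sig)
  structure(list(n_folds = n, fraction_significant = frac,
                 threshold = threshold,
                 is_reliable = frac > threshold),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("leave-one-out reliability: %.2f%% of %d folds significant; %s (threshold %.2f%%)\n",
              100 * x$fraction_significant, x$n_folds,
              if (x$is_reliable) "reliable" else "not reliable",
              100 * x$threshold))
  invisible(x)
}

#' Bonferroni-corrected alpha and reliability threshold
#'
#' Corrects a base level for m tests: alpha / m, and the matching
#' permutation-reliability percentage 100 (1 - alpha / m). With the
#' conventional .05 base: m = 6 gives 99.17 percent, m = 3 gives 98.33
#' percent, m = 4 gives alpha .0125, m = 2 gives .025.
#'
#' @param base_alpha uncorrected level (default .05).
#' @param m number of tests (>= 1).
#' @return list with \code{alpha} (corrected level) and
#'   \code{reliability_percent} (rounded to two decimals).
#' @export
bonferroni_threshold <- function(base_alpha = 0.05, m) {
  stopifnot(m >= 1)
  a <- base_alpha / m
  list(alpha = a, reliability_percent = round(100 * (1 - a), 2))
}
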