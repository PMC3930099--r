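#' Moderated regression of an outcome on connectivity
#'
#' Ordinary-least-squares fit of
#' \deqn{y = \beta_0 + \beta_1 x + \beta_2 m + \beta_3 x m + \epsilon}
#' where x is the per-subject connectivity summary (e.g. mean GPDC over
#' the discriminating paths), m the perinatal moderator (gestational age
#' or ultrasound classification), and \eqn{\beta_3} carries the
#' moderation effect. Predictors are not mean-centred by default;
#' centring changes the interpretation of \eqn{\beta_1} and
#' \eqn{\beta_2} (effects at m = 0 vs at the mean) but leaves
#' \eqn{\beta_3} untouched.
#'
#' @param y outcome per subject (executive-function score).
#' @param x independent variable per subject (GPDC summary).
#' @param m moderator per subject.
#' @param center mean-centre x and m before forming the interaction.
#' @return object of class \code{moderation_fit}: coefficient table
#'   (estimate, se, t, p for b0, b1_x, b2_m, b3_xm), the underlying
#'   \code{lm} fit, and the (possibly centred) design variables.
#' @export
fit_moderation <- function(y, x, m, center = FALSE) {
  y <- as.numeric(y); x <- as.numeric(x); m <- as.numeric(m)
  n <- length(y)
  stopifnot(n >= 10L, length(x) == n, length(m) == n)
  if (anyNA(c(y, x, m))) stop("missing values are not allowed", call. = FALSE)
  if (stats::var(x) == 0)
    stop("collinear design: predictor 'x' is constant", call. = FALSE)
  if (stats::var(m) == 0)
    stop("collinear design: moderator 'm' is constant ",
         "(interaction unidentifiable)", call. = FALSE)
  if (center) { x <- x - mean(x); m <- m - mean(m) }
  d <- data.frame(y = y, x = x, m = m)
  fit <- stats::lm(y ~ x + m + x:m, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: term(s) ", paste(bad, collapse = ", "),
         " not estimable", call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  rownames(ct) <- c("b0", "b1_x", "b2_m", "b3_xm")
  structure(list(coefficients = ct, lm = fit, data = d,
                 centered = center),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("moderated regression y ~ x + m + x:m",
      if (x$centered) "(centred predictors)", "\n")
  stats::printCoefmat(x$coefficients)
  if (!is.null(x$bootstrap)) {
    cat(sprintf("\npercentile bootstrap (%d resamples, alpha %.4g):\n",
                x$bootstrap$n_boot, x$bootstrap$alpha))
    print(x$bootstrap$ci)
  }
  invisible(x)
}

#' @export
coef.moderation_fit <- function(object, ...)
  stats::setNames(object$coefficients[, "Estimate"],
                  rownames(object$coefficients))

#' Percentile bootstrap confidence intervals for a moderation fit
#'
#' Resamples subjects with replacement \code{n_boot} times, refits the
#' moderated regression on each resample, and forms per-coefficient
#' percentile confidence intervals at level 1 - alpha (default
#' alpha = .025, the Bonferroni-corrected level for two perinatal
#' moderators). A coefficient is flagged significant when its interval
#' excludes zero. Collinear resamples are skipped and counted; more than
#' 10 percent skips triggers a warning.
#'
#' @param fit a \code{moderation_fit}.
#' @param n_boot bootstrap resamples (default 1000).
#' @param alpha corrected significance level (default .025).
#' @param seed integer seed.
#' @return the fit with a \code{bootstrap} element: \code{ci}
#'   (data.frame: estimate, boot_se, lower, upper, significant),
#'   \code{n_boot}, \code{alpha}, \code{n_skipped}.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, alpha = 0.025, seed = NULL) {
  stopifnot(inherits(fit, "moderation_fit"), alpha > 0, alpha < 1)
  d <- fit$data
  n <- nrow(d)
  X <- cbind(1, d$x, d$m, d$x * d$m)
  boots <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 4L)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      z <- .lm.fit(X[idx, , drop = FALSE], d$y[idx])
      if (z$rank < 4L || anyNA(z$coefficients)) {
        skipped <- skipped + 1L
        next
      }
      out[b, z$pivot] <- z$coefficients
    }
    list(out = out, skipped = skipped)
  })
  keep <- stats::complete.cases(boots$out)
  if (boots$skipped > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap resamples were collinear and skipped",
                    boots$skipped, n_boot))
  qs <- apply(boots$out[keep, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2))
  est <- coef(fit)
  ci <- data.frame(estimate = est,
                   boot_se = apply(boots$out[keep, , drop = FALSE], 2,
                                   stats::sd),
                   lower = qs[1L, ], upper = qs[2L, ],
                   row.names = names(est))
  ci$significant <- ci$lower > 0 | ci$upper < 0
  fit$bootstrap <- list(ci = ci, n_boot = n_boot, alpha = alpha,
                        n_skipped = boots$skipped)
  fit
}

#' Simple slopes of the outcome on connectivity at moderator levels
#'
#' The conditional slope of y on x at moderator value m0 is
#' \eqn{\beta_1 + \beta_3 m_0}, with a delta-method standard error from
#' the OLS covariance. Optionally also refits the unmoderated regression
#' within moderator strata defined by a median split, mirroring the
#' stratified reading of a moderation effect (e.g. low- vs
#' high-gestational-age subgroups).
#'
#' @param fit a \code{moderation_fit}.
#' @param m_levels moderator values at which to evaluate the slope
#'   (default: mean and mean +/- 1 sd of the fitted moderator).
#' @param stratify also return median-split stratified refits.
#' @return data.frame (m_level, slope, se); when \code{stratify} is
#'   TRUE, a list with that data.frame (\code{slopes}) and
#'   \code{strata} (stratum, n, slope, se from per-stratum simple
#'   regressions of y on x).
#' @export
simple_slopes <- function(fit, m_levels = NULL, stratify = FALSE) {
  stopifnot(inherits(fit, "moderation_fit"))
  m <- fit$data$m
  m_levels <- m_levels %||% (mean(m) + c(-1, 0, 1) * stats::sd(m))
  cf <- coef(fit)
  V <- stats::vcov(fit$lm)
  slopes <- data.frame(
    m_level = m_levels,
    slope = cf["b1_x"] + cf["b3_xm"] * m_levels,
    se = sqrt(V[2, 2] + m_levels^2 * V[4, 4] + 2 * m_levels * V[2, 4]),
    row.names = NULL)
  if (!stratify) return(slopes)
  lowhigh <- ifelse(m <= stats::median(m), "low", "high")
  strata <- do.call(rbind, lapply(c("low", "high"), function(s) {
    d <- fit$data[lowhigh == s, ]
    sfit <- stats::lm(y ~ x, data = d)
    data.frame(stratum = s, n = nrow(d),
               slope = stats::coef(sfit)[["x"]],
               se = summary(sfit)$coefficients["x", "Std. Error"])
  }))
  list(slopes = slopes, strata = strata)
}
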