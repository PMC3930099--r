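#' Binarised connection topology from a GPDC spectrum
#'
#' Collapses the frequency-bin dimension of a subject's GPDC spectrum to
#' one scalar per ordered path (band mean by default), then thresholds:
#' the directed connection j to i is present when the scalar strictly
#' exceeds \code{threshold}. The off-diagonal entries, flattened in
#' row-major path order (target row by target row), form the
#' k (k - 1)-length binary feature vector used for topology
#' classification (30 features for k = 6).
#'
#' @param subject_gpdc a \code{gpdc_spectrum}.
#' @param threshold GPDC threshold in [0, 1].
#' @param reduction \code{"band_mean"} (default) or \code{"per_bin_max"}.
#' @return object of class \code{topology_matrix}: list with
#'   \code{adjacency} (k-by-k 0/1 matrix, diagonal NA),
#'   \code{features} (binary vector, named "j->i"), \code{threshold},
#'   \code{reduction}.
#' @export
binarize_topology <- function(subject_gpdc, threshold,
                              reduction = c("band_mean", "per_bin_max")) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(subject_gpdc, "gpdc_spectrum"),
            threshold >= 0, threshold <= 1)
  v <- subject_gpdc$values
  k <- dim(v)[1]
  scal <- apply(v, c(1, 2), if (reduction == "band_mean") mean else max)
  adj <- (scal > threshold) + 0
  diag(adj) <- NA
  feats <- integer(0); nms <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    feats <- c(feats, adj[i, j])
    nms <- c(nms, sprintf("%d->%d", j, i))
  }
  names(feats) <- nms
  structure(list(adjacency = adj, features = feats, threshold = threshold,
                 reduction = reduction), class = "topology_matrix")
}

#' Fisher linear discriminant for two groups
#'
#' Computes the Fisher discriminant direction
#' \eqn{w \propto S_w^{-1} (\bar x_A - \bar x_B)} with the pooled
#' within-group covariance \eqn{S_w} regularised by a small ridge
#' (binary topology features make \eqn{S_w} near-singular whenever the
#' feature count approaches the subject count). The decision boundary is
#' placed midway between the projected group means, and the Mahalanobis
#' distance between group means under the pooled covariance is reported.
#'
#' @param features subjects-by-features numeric matrix.
#' @param labels two-level group labels, one per subject (n >= 2 per
#'   group).
#' @param ridge ridge added to \eqn{S_w} as \code{ridge * mean(diag(Sw))}
#'   (or \code{ridge} itself when the diagonal is all zero, which is
#'   flagged as degenerate).
#' @return object of class \code{fisher_lda}: weights, offset, group
#'   levels (first level projects positive), projected group means,
#'   \code{mahalanobis_distance}, \code{degenerate} flag.
#' @export
fit_lda <- function(features, labels, ridge = 1e-6) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2L, nrow(X) == length(labels),
            all(table(labels) >= 2L))
  Xa <- X[labels == lev[1], , drop = FALSE]
  Xb <- X[labels == lev[2], , drop = FALSE]
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  Sw <- ((nrow(Xa) - 1) * stats::cov(Xa) + (nrow(Xb) - 1) * stats::cov(Xb)) /
    (nrow(X) - 2)
  degenerate <- all(diag(Sw) == 0)
  lam <- if (degenerate) ridge else ridge * mean(diag(Sw))
  Swr <- Sw + diag(lam, ncol(X))
  w <- as.numeric(MASS::ginv(Swr) %*% (ma - mb))
  if (all(w == 0) && any(ma != mb))
    stop("degenerate discriminant: zero weight vector on separated means",
         call. = FALSE)
  proj_a <- sum(w * ma); proj_b <- sum(w * mb)
  d <- ma - mb
  maha <- sqrt(max(0, sum(d * as.numeric(MASS::ginv(Swr) %*% d))))
  structure(list(weights = w, offset = (proj_a + proj_b) / 2,
                 levels = lev,
                 projected_means = c(proj_a, proj_b),
                 mahalanobis_distance = maha,
                 degenerate = degenerate),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA: %d features, Mahalanobis distance %.3f%s\n",
              length(x$weights), x$mahalanobis_distance,
              if (x$degenerate) " (degenerate within-group covariance)" else ""))
  invisible(x)
}

#' @export
coef.fisher_lda <- function(object, ...) object$weights

#' Classify feature vectors with a fitted Fisher discriminant
#' @param object a \code{fisher_lda}.
#' @param newdata feature matrix (or vector) to classify.
#' @param ... unused.
#' @return character vector of predicted group labels.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  score <- as.numeric(X %*% object$weights) - object$offset
  # first level is the one whose projected mean lies above the boundary
  above <- object$projected_means[1] >= object$projected_means[2]
  ifelse(score >= 0,
         object$levels[if (above) 1 else 2],
         object$levels[if (above) 2 else 1])
}

#' Leave-one-out LDA accuracy across a GPDC threshold sweep
#'
#' For every threshold in the grid: binarise every subject's topology,
#' then leave each subject out in turn, fit the Fisher discriminant on
#' the rest and classify the held-out vector (the held-out subject never
#' enters the fit). Reports leave-one-out accuracy, the full-sample
#' Mahalanobis distance, and the discriminant accuracy — the product of
#' classification accuracy and Mahalanobis distance — per threshold.
#' The best threshold maximises LOO accuracy, with ties broken toward
#' the larger Mahalanobis distance and then the lower threshold.
#'
#' @param spectra list of per-subject \code{gpdc_spectrum} objects.
#' @param labels two-level group labels (n >= 2 per group; at least 2
#'   subjects overall to leave one out).
#' @param thresholds GPDC threshold grid (default 0.05 to 0.55 by 0.01).
#' @param reduction passed to [binarize_topology()].
#' @return object of class \code{sweep_result}: data.frame \code{sweep}
#'   (threshold, loo_accuracy, mahalanobis, discriminant_accuracy),
#'   \code{best_threshold}, \code{best_accuracy},
#'   \code{classification} (per-subject predicted labels at the best
#'   threshold), \code{weights} (full-sample discriminant weights at the
#'   best threshold, named by path), \code{failures} (count of
#'   degenerate folds, classified incorrect).
#' @export
loo_threshold_sweep <- function(spectra, labels,
                                thresholds = seq(0.05, 0.55, by = 0.01),
                                reduction = "band_mean") {
  labels <- as.character(labels)
  stopifnot(length(spectra) == length(labels), length(spectra) >= 3L,
            all(thresholds >= 0), all(thresholds <= 1),
            length(unique(labels)) == 2L, all(table(labels) >= 2L))
  n <- length(spectra)
  # the bin reduction is threshold-independent: compute per-path scalars once
  k <- dim(spectra[[1]]$values)[1]
  path_names <- names(binarize_topology(spectra[[1]], 0, reduction)$features)
  scal <- t(vapply(spectra, function(s) {
    m <- apply(s$values, c(1, 2),
               if (reduction == "band_mean") mean else max)
    f <- numeric(0)
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      f <- c(f, m[i, j])
    f
  }, numeric(k * (k - 1))))
  res <- data.frame(threshold = thresholds, loo_accuracy = NA_real_,
                    mahalanobis = NA_real_,
                    discriminant_accuracy = NA_real_)
  best <- list(acc = -Inf, maha = -Inf, thr = NA, pred = NULL, w = NULL)
  failures <- 0L
  for (ti in seq_along(thresholds)) {
    F <- (scal > thresholds[ti]) + 0
    full <- fit_lda(F, labels)
    pred <- character(n)
    for (i in seq_len(n)) {
      tr_lab <- labels[-i]
      if (min(table(tr_lab)) < 2L) { pred[i] <- NA; next }
      fold <- tryCatch(fit_lda(F[-i, , drop = FALSE], tr_lab),
                       error = function(e) NULL)
      pred[i] <- if (is.null(fold)) NA_character_ else
        predict(fold, F[i, ])
    }
    bad <- is.na(pred)
    failures <- failures + sum(bad)
    acc <- mean(!bad & pred == labels)   # failed folds count incorrect
    res$loo_accuracy[ti] <- acc
    res$mahalanobis[ti] <- full$mahalanobis_distance
    res$discriminant_accuracy[ti] <- acc * full$mahalanobis_distance
    better <- acc > best$acc ||
      (acc == best$acc && full$mahalanobis_distance > best$maha)
    if (better) {
      best <- list(acc = acc, maha = full$mahalanobis_distance,
                   thr = thresholds[ti], pred = pred,
                   w = stats::setNames(full$weights, path_names))
    }
  }
  structure(list(sweep = res, best_threshold = best$thr,
                 best_accuracy = best$acc,
                 classification = best$pred, weights = best$w,
                 failures = failures),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(paste0("GPDC threshold sweep (%d thresholds): best LOO accuracy ",
                     "%.3f at threshold %.2f\n"),
              nrow(x$sweep), x$best_accuracy, x$best_threshold))
  if (x$failures > 0)
    cat(sprintf("  %d degenerate folds counted incorrect\n", x$failures))
  invisible(x)
}

#' Plot LOO accuracy and discriminant accuracy against threshold
#' @param x a \code{sweep_result}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, ...) {
  graphics::plot(x$sweep$threshold, x$sweep$loo_accuracy, type = "l",
                 xlab = "GPDC threshold", ylab = "LOO accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}
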