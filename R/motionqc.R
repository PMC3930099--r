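#' Per-step displacement from realignment translations
#'
#' For each volume after the first, the displacement relative to the
#' preceding volume: the root mean square of the three axis translation
#' differences, \eqn{\sqrt{(\Delta x^2 + \Delta y^2 + \Delta z^2)/3}}.
#' The RMS convention (divide by 3 under the root) is the default;
#' \code{norm = "euclidean"} gives the Euclidean step length
#' \eqn{\sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}} instead.
#'
#' @param series T-by-6 realignment matrix (translations mm in columns
#'   1-3, rotations rad in columns 4-6) or T-by-3 translation matrix.
#' @param norm \code{"rms"} (default) or \code{"euclidean"}.
#' @return numeric vector of length T - 1 (mm); the first volume has no
#'   predecessor and contributes nothing.
#' @export
displacement_series <- function(series, norm = c("rms", "euclidean")) {
  norm <- match.arg(norm)
  tr <- as.matrix(series)
  stop_if_not_finite(tr, "realignment parameters")
  stopifnot(nrow(tr) >= 2L, ncol(tr) %in% c(3L, 6L))
  tr <- tr[, 1:3, drop = FALSE]
  d2 <- rowSums(diff(tr)^2)
  if (norm == "rms") sqrt(d2 / 3) else sqrt(d2)
}

#' Euler rotation angle from three axis rotations
#'
#' Single-angle summary of the 3-D rotation with axis rotations phi,
#' theta, psi (radians about x, y, z), computed as
#' \code{arccos((cos(phi)cos(theta) + cos(phi)cos(psi) + cos(theta)cos(psi)
#' + sin(phi)sin(psi)sin(theta) - 1) / 2)}. The arccos argument is
#' clipped to [-1, 1] against floating-point rounding, so an identity
#' rotation returns exactly 0 rather than NaN.
#'
#' @param phi,theta,psi rotations in radians (vectorised).
#' @return rotation angle(s) in [0, pi] radians.
#' @export
euler_angle <- function(phi, theta, psi) {
  stop_if_not_finite(c(phi, theta, psi), "rotation parameters")
  arg <- (cos(phi) * cos(theta) + cos(phi) * cos(psi) +
            cos(theta) * cos(psi) + sin(phi) * sin(psi) * sin(theta) - 1) / 2
  acos(pmin(1, pmax(-1, arg)))
}

#' Head-motion summary metrics for one subject
#'
#' The four per-subject quality-control metrics computed from the
#' realignment parameters:
#' \describe{
#'   \item{mean_motion}{mean of the per-step displacement (mm).}
#'   \item{max_motion}{largest per-step displacement (mm).}
#'   \item{n_movements}{number of steps with displacement strictly above
#'     \code{movement_threshold}; bounded by 0 and T - 1.}
#'   \item{rotation}{summary (mean by default) of the per-step Euler
#'     angles computed from the rotation-parameter differences between
#'     consecutive volumes (radians).}
#' }
#'
#' @param series T-by-6 realignment matrix.
#' @param movement_threshold displacement threshold in mm (default 0.1).
#' @param rotation_summary \code{"mean"} (default) or \code{"max"}.
#' @param norm displacement convention, see [displacement_series()].
#' @return object of class \code{motion_summary} (named list of the four
#'   metrics plus \code{n_volumes}).
#' @export
motion_summary <- function(series, movement_threshold = 0.1,
                           rotation_summary = c("mean", "max"),
                           norm = "rms") {
  rotation_summary <- match.arg(rotation_summary)
  rp <- as.matrix(series)
  stopifnot(ncol(rp) == 6L, nrow(rp) >= 2L)
  disp <- displacement_series(rp, norm = norm)
  drot <- diff(rp[, 4:6, drop = FALSE])
  ang <- euler_angle(drot[, 1], drot[, 2], drot[, 3])
  structure(list(
    mean_motion = mean(disp),
    max_motion = max(disp),
    n_movements = sum(disp > movement_threshold),
    rotation = if (rotation_summary == "mean") mean(ang) else max(ang),
    n_volumes = nrow(rp)), class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(paste0("motion summary (%d volumes): mean %.4f mm, ",
                     "max %.4f mm, %d movements, rotation %.2e rad\n"),
              x$n_volumes, x$mean_motion, x$max_motion, x$n_movements,
              x$rotation))
  invisible(x)
}

#' Bootstrap two-group comparison of a motion metric
#'
#' Two-sided p-value for a difference in group means from the percentile
#' position of zero in the bootstrap distribution of the mean difference
#' (subjects resampled with replacement within group). With four motion
#' metrics the Bonferroni-corrected level is .0125 (see
#' [bonferroni_threshold()]).
#'
#' @param values_a,values_b per-subject metric values (each n >= 2).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with \code{p_value}, \code{mean_difference} (A - B),
#'   \code{n_boot}, and \code{degenerate} (TRUE when the bootstrap
#'   distribution has zero variance, in which case the p-value is 1 for
#'   a zero difference and 0 otherwise — flagged rather than trusted).
#' @export
bootstrap_group_ttest <- function(values_a, values_b, n_boot = 1000L,
                                  seed = NULL) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  diffs <- with_seed(seed, {
    ia <- matrix(sample.int(length(a), n_boot * length(a), replace = TRUE),
                 n_boot)
    ib <- matrix(sample.int(length(b), n_boot * length(b), replace = TRUE),
                 n_boot)
    rowMeans(matrix(a[ia], n_boot)) - rowMeans(matrix(b[ib], n_boot))
  })
  degenerate <- stats::var(diffs) == 0
  p <- if (degenerate) as.numeric(mean(a) == mean(b)) else
    min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(p_value = p, mean_difference = mean(a) - mean(b),
       n_boot = n_boot, degenerate = degenerate)
}

#' Motion summaries for a whole cohort
#'
#' @param cohort a \code{cohort} or list of T-by-6 realignment matrices.
#' @param ... passed to [motion_summary()].
#' @return data.frame with one row per subject: the four metrics plus
#'   id/group when available.
#' @export
cohort_motion <- function(cohort, ...) {
  if (inherits(cohort, "cohort")) {
    rps <- lapply(cohort$subjects, `[[`, "realignment")
    ids <- vapply(cohort$subjects, `[[`, character(1), "id")
    grp <- cohort_labels(cohort)
  } else {
    rps <- cohort
    ids <- sprintf("sub-%03d", seq_along(rps))
    grp <- NA_character_
  }
  ms <- lapply(rps, motion_summary, ...)
  data.frame(
    id = ids, group = grp,
    mean_motion = vapply(ms, `[[`, numeric(1), "mean_motion"),
    max_motion = vapply(ms, `[[`, numeric(1), "max_motion"),
    n_movements = vapply(ms, `[[`, numeric(1), "n_movements"),
    rotation = vapply(ms, `[[`, numeric(1), "rotation"),
    stringsAsFactors = FALSE)
}
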