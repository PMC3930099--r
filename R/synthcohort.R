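#' Specify the directed coupling structure of a synthetic cohort
#'
#' A coupling spec is the ground truth behind a synthetic cohort: which
#' directed edges exist between network channels, at which lag and with
#' which coefficient, the per-channel innovation variances, and a
#' per-group multiplicative attenuation applied to the designated edges.
#' Attenuation below 1 in one group produces the group-level reduction in
#' directed coupling strength the downstream analyses are built to
#' detect.
#'
#' @param n_channels number of network channels k (default 6: three
#'   neurocognitive networks split into two subnetworks each).
#' @param order lag order p of the generating VAR.
#' @param edges data.frame with columns \code{source} (j), \code{target}
#'   (i), \code{lag} (l) and \code{coef} (\eqn{a_{ij}^{(l)}}); one row
#'   per directed edge. \code{NULL} means no cross-channel edges.
#' @param self_coupling lag-1 diagonal autoregressive coefficient applied
#'   to every channel (gives the series realistic low-frequency
#'   autocorrelation).
#' @param noise_variances per-channel innovation variances
#'   \eqn{\sigma_i^2} (recycled to length k; all > 0).
#' @param attenuation named list or vector mapping group label to the
#'   multiplicative factor (in [0, 1]) applied to every \code{edges}
#'   coefficient for that group.
#' @return an object of class \code{coupling_spec}.
#' @examples
#' spec <- coupling_spec(
#'   edges = data.frame(source = 2, target = 1, lag = 1, coef = 0.4),
#'   attenuation = c(A = 1, B = 0.3))
#' @export
coupling_spec <- function(n_channels = 6L, order = 1L, edges = NULL,
                          self_coupling = 0.3,
                          noise_variances = 1,
                          attenuation = c(A = 1, B = 1)) {
  k <- as.integer(n_channels); p <- as.integer(order)
  stopifnot(k >= 1L, p >= 1L)
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    stopifnot(all(c("source", "target", "lag", "coef") %in% names(edges)))
    stop_if_not_finite(edges$coef, "edge coefficients")
    stopifnot(all(edges$source %in% seq_len(k)),
              all(edges$target %in% seq_len(k)),
              all(edges$lag %in% seq_len(p)))
  }
  noise_variances <- rep_len(as.numeric(noise_variances), k)
  if (any(noise_variances <= 0))
    stop("noise variances must be strictly positive", call. = FALSE)
  attenuation <- unlist(attenuation)
  if (is.null(names(attenuation)) || any(!nzchar(names(attenuation))))
    stop("attenuation must be named by group label", call. = FALSE)
  if (any(attenuation < 0 | attenuation > 1))
    stop("attenuation factors must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_channels = k, order = p, edges = edges,
         self_coupling = self_coupling,
         noise_variances = noise_variances,
         attenuation = attenuation),
    class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("coupling spec: k = %d, order = %d, %d directed edge(s)\n",
              x$n_channels, x$order,
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  cat("  groups:", paste(sprintf("%s (attenuation %.2f)",
                                 names(x$attenuation), x$attenuation),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Build a stable generating VAR model for one group
#'
#' Realises the coupling spec as a \code{var_model} for the requested
#' group: self-coupling on the lag-1 diagonal, each designated edge
#' coefficient multiplied by the group's attenuation factor, diagonal
#' innovation covariance. If the resulting companion matrix is not
#' stable, all coefficients are uniformly rescaled so the spectral
#' radius equals \code{target_radius} (uniform rescaling preserves the
#' edge topology); a rescaling is recorded in the returned model's
#' \code{rescaled} attribute.
#'
#' @param spec a [coupling_spec()].
#' @param group group label; must be present in the spec's attenuation
#'   map.
#' @param target_radius spectral radius enforced when stabilisation is
#'   needed (default 0.95).
#' @return a stable \code{var_model} with attribute \code{rescaled}
#'   (\code{TRUE} if stabilisation was applied) and \code{group}.
#' @export
build_stable_var <- function(spec, group, target_radius = 0.95) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!group %in% names(spec$attenuation))
    stop("unknown group label '", group, "'", call. = FALSE)
  k <- spec$n_channels; p <- spec$order
  A <- replicate(p, matrix(0, k, k), simplify = FALSE)
  diag(A[[1L]]) <- spec$self_coupling
  att <- spec$attenuation[[group]]
  if (!is.null(spec$edges) && nrow(spec$edges) > 0L)
    for (r in seq_len(nrow(spec$edges))) {
      e <- spec$edges[r, ]
      A[[e$lag]][e$target, e$source] <- A[[e$lag]][e$target, e$source] +
        att * e$coef
    }
  model <- var_model(A, diag(spec$noise_variances, k))
  rescaled <- FALSE
  rho <- spectral_radius(model)
  if (rho >= 1) {
    # scaling all lag-l matrices by c^l scales the companion spectrum by c
    cc <- target_radius / rho
    A <- lapply(seq_len(p), function(l) A[[l]] * cc^l)
    model <- var_model(A, diag(spec$noise_variances, k))
    rescaled <- TRUE
  }
  attr(model, "rescaled") <- rescaled
  attr(model, "group") <- group
  model
}

#' Draw a random stable VAR model
#'
#' Random sparse coefficient matrices (each entry nonzero with
#' probability \code{edge_density}, Gaussian with sd \code{coef_sd},
#' plus a lag-1 diagonal), random per-channel noise variances, then
#' uniform rescaling of the coefficient set to companion spectral radius
#' \code{target_radius} whenever the raw draw is unstable. Used for
#' property checks over ensembles of generators (e.g. that GPDC stays in
#' [0, 1] and column-normalises for any stable model).
#'
#' @param n_channels channels k.
#' @param order lag order p.
#' @param edge_density probability an off-diagonal coefficient is
#'   nonzero.
#' @param coef_sd sd of nonzero coefficients.
#' @param noise_var_range range of the uniform draw for per-channel
#'   innovation variances.
#' @param target_radius stabilisation radius (default 0.95).
#' @param seed integer seed.
#' @return a stable \code{var_model}.
#' @export
random_stable_var <- function(n_channels, order, edge_density = 0.3,
                              coef_sd = 0.4, noise_var_range = c(0.5, 2),
                              target_radius = 0.95, seed = NULL) {
  k <- as.integer(n_channels); p <- as.integer(order)
  with_seed(seed, {
    A <- lapply(seq_len(p), function(l) {
      M <- matrix(stats::rnorm(k * k, 0, coef_sd) *
                    (stats::runif(k * k) < edge_density), k, k)
      if (l == 1L) diag(M) <- stats::runif(k, 0.1, 0.5)
      M
    })
    Sigma <- diag(stats::runif(k, noise_var_range[1], noise_var_range[2]),
                  k)
    model <- var_model(A, Sigma)
    rho <- spectral_radius(model)
    if (rho >= target_radius) {
      cc <- target_radius / rho
      A <- lapply(seq_len(p), function(l) A[[l]] * cc^l)
      model <- var_model(A, Sigma)
    }
    model
  })
}

# Truncated-normal draw by rejection (narrow use: gestational ages).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic two-group cohort
#'
#' Produces per-subject network time courses from the group-specific
#' stable VAR models, realignment-parameter series, and covariates with
#' the dependence structure the downstream analyses assume:
#' \itemize{
#'   \item group A ("term-like") uses the spec's full coupling, group B
#'     ("VPT-like") the attenuated coupling;
#'   \item gestational age (weeks) is drawn per group (term-like
#'     uniform 37-42, VPT-like uniform 25-32.9, i.e. below the very
#'     preterm cut-off of 33 weeks);
#'   \item neonatal ultrasound classification (0 = normal,
#'     1 = uncomplicated periventricular haemorrhage, 2 = haemorrhage
#'     with ventricular dilatation) is tied to gestational age through a
#'     Gaussian copula with configurable negative rank correlation;
#'   \item the executive-function score follows a linear model with a
#'     connectivity-by-gestational-age interaction,
#'     \eqn{EF = b_0 + b_1 x + b_2 GA_z + b_3 x GA_z + noise}, where x is
#'     the subject's realised coupling scale, so moderation recovery is
#'     testable against known coefficients.
#' }
#' Per-subject noise seeds are split deterministically from the master
#' seed (one draw per subject from the master-seeded stream), so the
#' cohort is reproducible subject-wise.
#'
#' @param spec a [coupling_spec()] with exactly two groups in its
#'   attenuation map.
#' @param n_per_group integer pair: subjects in group A and group B
#'   (default the study sizes 23 and 29).
#' @param n_time retained samples per subject (default 256 volumes).
#' @param seed master seed.
#' @param sampling_interval seconds per sample (default 2).
#' @param coupling_jitter_sd per-subject lognormal-ish jitter (sd on the
#'   multiplicative scale) of the edge coupling, giving within-group
#'   variability in true connectivity.
#' @param ga_us_rho magnitude of the negative gestational-age /
#'   ultrasound rank correlation (default 0.545).
#' @param ef_coefs coefficients (b0, b1, b2, b3) of the
#'   executive-function generating model.
#' @param ef_noise_sd residual sd of the executive-function score.
#' @param drift_scale realignment drift scale passed to
#'   [generate_realignment()].
#' @return an object of class \code{cohort}: list with \code{subjects}
#'   (each with id, group, timecourses (k-by-T), realignment, covariates,
#'   true coupling scale), \code{sampling_interval}, and the generating
#'   \code{spec}.
#' @export
generate_cohort <- function(spec, n_per_group = c(23L, 29L), n_time = 256L,
                            seed = NULL, sampling_interval = 2,
                            coupling_jitter_sd = 0.1,
                            ga_us_rho = 0.545,
                            ef_coefs = c(10, 4, 1, 2), ef_noise_sd = 1,
                            drift_scale = 0.02) {
  stopifnot(inherits(spec, "coupling_spec"), length(n_per_group) == 2L,
            all(n_per_group >= 2L), length(spec$attenuation) == 2L)
  groups <- names(spec$attenuation)
  n_tot <- sum(n_per_group)
  group_of <- rep(groups, n_per_group)
  seeds <- split_seeds(seed, 3L * n_tot + 1L)
  cov_seed <- seeds[length(seeds)]

  covs <- with_seed(cov_seed, {
    ga <- c(rtruncnorm1(n_per_group[1], 39.5, 1.2, 37, 42),
            rtruncnorm1(n_per_group[2], 29, 2.2, 25, 32.9))
    ga_z <- as.numeric(scale(ga))
    # Gaussian copula: latent score anti-correlated with GA, cut into
    # the three ultrasound classes (probabilities emulate 16/4/9 in the
    # preterm group; term-like subjects are coded 0).
    zu <- -ga_us_rho * ga_z + sqrt(1 - ga_us_rho^2) * stats::rnorm(n_tot)
    us <- integer(n_tot)
    b <- group_of == groups[2]
    cuts <- stats::quantile(zu[b], c(16, 20) / 29)
    us[b] <- findInterval(zu[b], cuts)
    jit <- exp(stats::rnorm(n_tot, 0, coupling_jitter_sd))
    list(ga = ga, ga_z = ga_z, us = us, jitter = jit)
  })

  subjects <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    g <- group_of[s]
    base <- build_stable_var(spec, g)
    # per-subject jitter of the cross-channel edges only
    model <- base
    if (!is.null(spec$edges) && nrow(spec$edges) > 0L) {
      for (r in seq_len(nrow(spec$edges))) {
        e <- spec$edges[r, ]
        model$A[[e$lag]][e$target, e$source] <-
          base$A[[e$lag]][e$target, e$source] * covs$jitter[s]
      }
      if (spectral_radius(model) >= 1) model <- base  # jitter never destabilises
    }
    x_true <- spec$attenuation[[g]] * covs$jitter[s]
    ef <- with_seed(seeds[2L * n_tot + s],
      ef_coefs[1] + ef_coefs[2] * x_true + ef_coefs[3] * covs$ga_z[s] +
        ef_coefs[4] * x_true * covs$ga_z[s] + stats::rnorm(1, 0, ef_noise_sd))
    subjects[[s]] <- list(
      id = sprintf("sub-%03d", s),
      group = g,
      timecourses = simulate_timecourses(model, n_time, seed = seeds[s]),
      realignment = generate_realignment(n_time, drift_scale = drift_scale,
                                         seed = seeds[n_tot + s]),
      covariates = list(gestational_age = covs$ga[s],
                        ultrasound = covs$us[s],
                        executive_function = ef),
      coupling_scale = x_true)
  }
  structure(
    list(subjects = subjects, sampling_interval = sampling_interval,
         groups = groups, spec = spec),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  tt <- ncol(x$subjects[[1]]$timecourses)
  cat(sprintf("synthetic cohort: %d subjects (%s), k = %d, T = %d, TR = %gs\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", names(table(g)), table(g)),
                    collapse = ", "),
              nrow(x$subjects[[1]]$timecourses), tt, x$sampling_interval))
  invisible(x)
}

#' Extract per-subject group labels from a cohort
#' @param cohort a \code{cohort}.
#' @return character vector of group labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "group")
}

#' Generate a synthetic realignment-parameter series
#'
#' Emulates the six rigid-body realignment parameters an fMRI
#' realignment step writes out: three translations (mm) then three
#' rotations (radians about x, y, z). The series is a smoothed Gaussian
#' random-walk drift plus optional injected movement spikes.
#'
#' @param n_time number of volumes T.
#' @param drift_scale per-step drift sd in mm (rotational drift uses
#'   \code{drift_scale / 50} radians). 0 gives a constant-zero series.
#' @param spikes list of spikes, each a list with \code{index} (step in
#'   1..T-1), \code{translation} (3-vector, mm) and optionally
#'   \code{rotation} (3-vector, radians) added from volume index + 1
#'   onwards, so the spike appears as a displacement at that step.
#' @param seed integer seed.
#' @return T-by-6 matrix, columns x, y, z translations then rotations.
#' @export
generate_realignment <- function(n_time, drift_scale = 0.02, spikes = list(),
                                 seed = NULL) {
  stopifnot(n_time >= 2L)
  rp <- with_seed(seed, {
    steps <- cbind(matrix(stats::rnorm(n_time * 3, 0, drift_scale), n_time, 3),
                   matrix(stats::rnorm(n_time * 3, 0, drift_scale / 50),
                          n_time, 3))
    steps[1L, ] <- 0
    rw <- apply(steps, 2, cumsum)
    # light smoothing keeps the drift slow relative to the 0.1 mm threshold
    apply(rw, 2, function(x) stats::filter(c(x[1], x[1], x, x[n_time],
                                             x[n_time]),
                                           rep(1 / 5, 5))[3:(n_time + 2)])
  })
  rp <- matrix(as.numeric(rp), n_time, 6)
  for (sp in spikes) {
    i <- sp$index
    stopifnot(i >= 1L, i <= n_time - 1L)
    rp[(i + 1):n_time, 1:3] <- sweep(rp[(i + 1):n_time, 1:3, drop = FALSE], 2,
                                     sp$translation, `+`)
    if (!is.null(sp$rotation))
      rp[(i + 1):n_time, 4:6] <- sweep(rp[(i + 1):n_time, 4:6, drop = FALSE], 2,
                                       sp$rotation, `+`)
  }
  colnames(rp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rp
}

#' Generate noisy component maps from template masks
#'
#' Builds one spatial map per template (the binary indicator scaled by
#' \code{snr}, plus unit-variance Gaussian noise) and
#' \code{n_distractors} pure-noise maps, emulating the map stack a group
#' ICA hands to template matching. With \code{snr = Inf} the maps are the
#' noiseless indicators.
#'
#' @param templates list of binary arrays on a shared grid (templates
#'   must agree in dimension).
#' @param snr scale of the template signal relative to unit noise.
#' @param n_distractors number of pure-noise maps appended.
#' @param seed integer seed.
#' @return list of maps (arrays), signal maps first (one per template,
#'   same order) then distractors; names indicate provenance.
#' @export
generate_component_maps <- function(templates, snr = 4, n_distractors = 2L,
                                    seed = NULL) {
  stopifnot(is.list(templates), length(templates) >= 1L)
  dims <- lapply(templates, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("templates do not share a voxel grid", call. = FALSE)
  nv <- length(templates[[1L]])
  with_seed(seed, {
    maps <- lapply(templates, function(tpl) {
      noise <- if (is.infinite(snr)) 0 else stats::rnorm(nv)
      m <- (if (is.infinite(snr)) 1 else snr) * as.numeric(tpl > 0) + noise
      array(m, dim(tpl))
    })
    dis <- replicate(n_distractors,
                     array(stats::rnorm(nv), dim(templates[[1L]])),
                     simplify = FALSE)
    out <- c(maps, dis)
    names(out) <- c(paste0("signal_", seq_along(maps)),
                    if (n_distractors > 0) paste0("noise_", seq_len(n_distractors)))
    out
  })
}
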