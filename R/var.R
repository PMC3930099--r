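#' Construct a vector autoregressive model object
#'
#' A \code{var_model} bundles the quantities that define a stationary
#' VAR(p) process \eqn{Y_t = v + \sum_{l=1}^p A_l Y_{t-l} + \epsilon_t}:
#' the intercept \eqn{v}, the lag coefficient matrices \eqn{A_l} whose
#' entry \eqn{a_{ij}^{(l)}} is the causality coefficient from channel
#' \eqn{j} to channel \eqn{i} at lag \eqn{l}, and the residual covariance
#' \eqn{\Sigma} whose diagonal \eqn{\sigma_i^2} drives the variance
#' weighting in generalised partial directed coherence.
#'
#' @param A list of p square k-by-k coefficient matrices (lag 1 first).
#' @param Sigma residual covariance matrix (k-by-k, symmetric positive
#'   semi-definite with strictly positive diagonal).
#' @param intercept numeric k-vector \eqn{v}; defaults to zeros.
#' @param n_samples_fit number of samples the model was fitted on, or
#'   \code{NA} for a constructed (generating) model.
#' @return an object of class \code{var_model}.
#' @seealso [fit_var()], [build_stable_var()], [simulate.var_model()],
#'   [gpdc_spectrum()]
#' @export
var_model <- function(A, Sigma, intercept = NULL, n_samples_fit = NA_integer_) {
  if (is.matrix(A)) A <- list(A)
  stopifnot(is.list(A), length(A) >= 1L)
  k <- nrow(A[[1L]])
  for (Al in A) {
    stopifnot(is.matrix(Al), nrow(Al) == k, ncol(Al) == k)
    stop_if_not_finite(Al, "coefficient matrix")
  }
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == k, ncol(Sigma) == k)
  stop_if_not_finite(Sigma, "residual covariance")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("residual covariance must be symmetric", call. = FALSE)
  if (any(diag(Sigma) <= 0))
    stop("residual variances must be strictly positive", call. = FALSE)
  intercept <- intercept %||% numeric(k)
  stopifnot(length(intercept) == k)
  structure(
    list(k = k, p = length(A), A = A, Sigma = Sigma,
         intercept = as.numeric(intercept),
         n_samples_fit = n_samples_fit),
    class = "var_model")
}

#' Companion matrix of a VAR(p) model
#'
#' Stacks the lag matrices into the (k p)-by-(k p) companion form whose
#' eigenvalues determine stability: the process is stationary iff the
#' spectral radius is below 1.
#'
#' @param model a \code{var_model}.
#' @return the companion matrix.
#' @export
companion_matrix <- function(model) {
  k <- model$k; p <- model$p
  C <- matrix(0, k * p, k * p)
  C[seq_len(k), ] <- do.call(cbind, model$A)
  if (p > 1L)
    C[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  C
}

#' Spectral radius of the companion matrix
#' @param model a \code{var_model}.
#' @return largest eigenvalue modulus of [companion_matrix()].
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model, %d channels%s\n", x$p, x$k,
              if (is.na(x$n_samples_fit)) ""
              else sprintf(", fitted on %d samples", x$n_samples_fit)))
  cat(sprintf("  spectral radius: %.4f\n", spectral_radius(x)))
  cat(sprintf("  residual variances: %s\n",
              paste(signif(diag(x$Sigma), 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.var_model <- function(object, ...) {
  out <- do.call(cbind, object$A)
  colnames(out) <- paste0("ch", rep(seq_len(object$k), object$p),
                          ".l", rep(seq_len(object$p), each = object$k))
  rownames(out) <- paste0("ch", seq_len(object$k))
  out
}

#' One-step-ahead prediction from a VAR model
#'
#' Computes the noiseless predictor
#' \eqn{\hat Y_t = v + \sum_{l=1}^p A_l Y_{t-l}} for every time point of
#' \code{newdata} with a full lag history.
#'
#' @param object a \code{var_model}.
#' @param newdata channels-by-time matrix (k rows).
#' @param ... unused.
#' @return k-by-(T - p) matrix of one-step predictions for times
#'   p+1, ..., T.
#' @export
predict.var_model <- function(object, newdata, ...) {
  Y <- as.matrix(newdata)
  stopifnot(nrow(Y) == object$k, ncol(Y) > object$p)
  TT <- ncol(Y); p <- object$p
  pred <- matrix(object$intercept, object$k, TT - p)
  for (l in seq_len(p))
    pred <- pred + object$A[[l]] %*% Y[, (p + 1 - l):(TT - l), drop = FALSE]
  pred
}

#' @export
residuals.var_model <- function(object, newdata, ...) {
  Y <- as.matrix(newdata)
  Y[, -seq_len(object$p), drop = FALSE] - predict(object, Y)
}

#' Simulate time courses from a VAR model
#'
#' Runs the recursion \eqn{Y_t = v + \sum_l A_l Y_{t-l} + \epsilon_t}
#' with Gaussian innovations of covariance \eqn{\Sigma}, starting from
#' zeros and discarding a burn-in so the retained samples are drawn from
#' (approximately) the stationary distribution.
#'
#' @param model a stable \code{var_model} (spectral radius < 1).
#' @param n_time number of retained samples T.
#' @param burnin samples discarded before retention (>= 100).
#' @param seed integer seed; the simulation is a pure function of
#'   (model, n_time, burnin, seed).
#' @return k-by-T matrix of simulated time courses.
#' @export
simulate_timecourses <- function(model, n_time, burnin = 500L, seed = NULL) {
  stopifnot(inherits(model, "var_model"), n_time >= 1, burnin >= 100)
  if (spectral_radius(model) >= 1)
    stop("refusing to simulate from an unstable model (spectral radius >= 1)",
         call. = FALSE)
  k <- model$k; p <- model$p
  total <- n_time + burnin
  L <- t(chol(model$Sigma + diag(1e-12, k)))
  with_seed(seed, {
    eps <- L %*% matrix(stats::rnorm(k * total), k, total)
    Y <- matrix(0, k, total + p)   # p leading zero columns seed the recursion
    for (t in seq_len(total)) {
      yt <- model$intercept + eps[, t]
      for (l in seq_len(p)) yt <- yt + model$A[[l]] %*% Y[, t + p - l]
      Y[, t + p] <- yt
    }
    Y[, (p + burnin + 1):(p + total), drop = FALSE]
  })
}

#' @rdname simulate_timecourses
#' @param object a \code{var_model} (S3 \code{simulate} method).
#' @param nsim number of retained samples.
#' @param ... passed to [simulate_timecourses()] (e.g. \code{burnin}).
#' @export
simulate.var_model <- function(object, nsim = 256L, seed = NULL, ...) {
  simulate_timecourses(object, n_time = nsim, seed = seed, ...)
}

#' Fit a VAR(p) model by least squares
#'
#' Multivariate ordinary least squares on the lagged design
#' \eqn{[1, Y_{t-1}, ..., Y_{t-p}]}: each channel is regressed on the p
#' lags of all channels plus an intercept. The residual covariance is
#' formed from residual cross-products with effective sample size
#' \eqn{T - p}.
#'
#' @param timecourses channels-by-time matrix (k rows, T columns).
#' @param order lag order p (>= 1).
#' @return a fitted \code{var_model} with \code{n_samples_fit = T}.
#' @export
fit_var <- function(timecourses, order = 1L) {
  Y <- as.matrix(timecourses)
  stop_if_not_finite(Y, "time courses")
  k <- nrow(Y); TT <- ncol(Y); p <- as.integer(order)
  stopifnot(p >= 1L)
  if (TT <= k * p + p + 10)
    stop("too few samples to identify a VAR(", p, ") on ", k, " channels",
         call. = FALSE)
  Teff <- TT - p
  # design: rows are times p+1..T, columns 1 + k*p regressors
  X <- matrix(1, Teff, 1 + k * p)
  for (l in seq_len(p))
    X[, (2 + (l - 1) * k):(1 + l * k)] <- t(Y[, (p + 1 - l):(TT - l), drop = FALSE])
  Yresp <- t(Y[, (p + 1):TT, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient regressor matrix (collinear or constant channels)",
         call. = FALSE)
  B <- qr.coef(qrX, Yresp)                  # (1 + k p) x k
  resid <- Yresp - X %*% B
  Sigma <- crossprod(resid) / Teff
  A <- lapply(seq_len(p), function(l)
    t(B[(2 + (l - 1) * k):(1 + l * k), , drop = FALSE]))
  var_model(A, Sigma, intercept = B[1L, ], n_samples_fit = TT)
}

# Per-subject BIC at a given order: log det Sigma_hat + penalty per
# effective sample, with parameter count p k^2 + k (coefficients plus
# intercept).
var_bic <- function(timecourses, order) {
  fit <- fit_var(timecourses, order)
  Teff <- fit$n_samples_fit - fit$p
  ld <- determinant(fit$Sigma, logarithm = TRUE)
  as.numeric(ld$modulus) + log(Teff) / Teff * (fit$p * fit$k^2 + fit$k)
}

#' Group-level VAR order selection by BIC
#'
#' Evaluates, for every candidate order p in 1..p_max, the sum over
#' subjects of the per-subject Bayesian Information Criterion
#' \eqn{\log\det\hat\Sigma(p) + \frac{\log T_{eff}}{T_{eff}} (p k^2 + k)}
#' and returns the order minimising the group total. BIC is preferred to
#' AIC here because AIC tends to over-estimate VAR order.
#'
#' @param subject_timecourses list of channels-by-time matrices, one per
#'   subject (shared k).
#' @param p_max largest candidate order (must satisfy
#'   \code{p_max < min(T) / (2 k)}).
#' @return list with \code{order} (selected p), and \code{bic_table}
#'   (candidate-by-subject matrix of BIC values, plus group totals as the
#'   \code{"group"} attribute is avoided; totals in column sums).
#' @export
select_order_group <- function(subject_timecourses, p_max = 10L) {
  stopifnot(is.list(subject_timecourses), length(subject_timecourses) >= 1L)
  k <- nrow(subject_timecourses[[1L]])
  Tmin <- min(vapply(subject_timecourses, ncol, integer(1)))
  if (p_max >= Tmin / (2 * k))
    stop("p_max too large for the shortest series (need p_max < T/(2k))",
         call. = FALSE)
  tab <- vapply(subject_timecourses, function(tc)
    vapply(seq_len(p_max), function(p) var_bic(tc, p), numeric(1)),
    numeric(p_max))
  tab <- matrix(tab, nrow = p_max)
  rownames(tab) <- paste0("p", seq_len(p_max))
  total <- rowSums(tab)
  list(order = unname(which.min(total)), bic_table = tab, bic_total = total)
}
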