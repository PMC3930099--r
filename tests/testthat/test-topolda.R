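test_that("topology binarisation flattens 30 ordered paths for k = 6", {
  m <- random_stable_var(6, 1, seed = 121)
  g <- gpdc_spectrum(m)
  tp <- binarize_topology(g, 0.1)
  expect_length(tp$features, 30L)
  expect_true(all(tp$features %in% c(0, 1)))
  expect_true(all(is.na(diag(tp$adjacency))))
  # threshold 0: any strictly positive GPDC becomes a connection
  pos <- binarize_topology(g, 0)
  off <- g$values[rep(!diag(6), length(g$bins))]
  expect_equal(sum(pos$features), sum(apply(g$values, c(1, 2), mean)[!diag(6)] > 0))
  # threshold 1: nothing survives
  expect_true(all(binarize_topology(g, 1)$features == 0))
  # adjacency and feature vector agree entry-wise
  expect_equal(unname(tp$features[1]), tp$adjacency[2, 1])
})

test_that("Fisher LDA reproduces definition arithmetic in one dimension", {
  # group means 0 and 2, pooled variance 1 -> Mahalanobis distance 2
  f <- fit_lda(matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1),
               rep(c("a", "b"), each = 3))
  expect_equal(f$mahalanobis_distance, 2, tolerance = 1e-3)
  # boundary midway between projected means classifies by proximity
  expect_equal(predict(f, matrix(c(-0.5, 2.5), ncol = 1)), c("a", "b"))
  # identical distributions: Mahalanobis ~ 0
  set.seed(122)
  X <- matrix(rnorm(60), ncol = 2)
  f0 <- fit_lda(X, rep(c("a", "b"), 15))
  expect_lt(f0$mahalanobis_distance, 1)
  # disjoint deterministic topologies: perfect separation
  Xd <- rbind(matrix(rep(c(1, 0), each = 5), 5), matrix(rep(c(0, 1), each = 5), 5))
  fd <- fit_lda(Xd, rep(c("a", "b"), each = 5))
  expect_true(fd$degenerate)           # zero within-group variance flagged
  expect_equal(unname(predict(fd, Xd)), rep(c("a", "b"), each = 5))
})

test_that("Fisher weights align with the MASS::lda cross-check", {
  set.seed(123)
  X <- rbind(MASS::mvrnorm(30, c(0, 0), diag(2)),
             MASS::mvrnorm(30, c(2, 1), diag(2)))
  labs <- rep(c("a", "b"), each = 30)
  f <- fit_lda(X, labs)
  ref <- MASS::lda(X, grouping = labs)
  # same discriminant direction up to sign/scale
  cosine <- abs(sum(f$weights * ref$scaling) /
                  sqrt(sum(f$weights^2) * sum(ref$scaling^2)))
  expect_gt(cosine, 0.999)
  # same classifications on training data (equal priors, equal n)
  expect_equal(unname(predict(f, X)),
               as.character(predict(ref, X)$class))
})

test_that("threshold sweep separates groups and is honest under permutation", {
  coh <- generate_cohort(edge_spec(), c(12, 12), 256, seed = 124)
  g <- raw_gpdc(coh)
  sw <- loo_threshold_sweep(g$spectra, g$labels,
                            thresholds = seq(0.02, 0.3, by = 0.02))
  expect_gt(sw$best_accuracy, 0.9)
  expect_true(all(sw$sweep$loo_accuracy >= 0 & sw$sweep$loo_accuracy <= 1))
  expect_equal(sw$sweep$discriminant_accuracy,
               sw$sweep$loo_accuracy * sw$sweep$mahalanobis)
  expect_length(sw$classification, 24L)
  expect_length(sw$weights, 30L)
  # permuted labels destroy the separation
  set.seed(125)
  perm <- loo_threshold_sweep(g$spectra, sample(g$labels),
                              thresholds = seq(0.02, 0.3, by = 0.04))
  expect_lt(perm$best_accuracy, sw$best_accuracy)
  # LOO accuracy is invariant to a consistent relabelling of channels
  relabel <- function(s) {
    pm <- c(3, 1, 2, 6, 4, 5)
    structure(list(values = s$values[pm, pm, , drop = FALSE], bins = s$bins,
                   squared = s$squared,
                   sampling_interval = s$sampling_interval),
              class = "gpdc_spectrum")
  }
  sw2 <- loo_threshold_sweep(lapply(g$spectra, relabel), g$labels,
                             thresholds = seq(0.02, 0.3, by = 0.02))
  expect_equal(sw2$sweep$loo_accuracy, sw$sweep$loo_accuracy)
  expect_error(loo_threshold_sweep(g$spectra[1:2], g$labels[1:2]))
})

test_that("discriminant accuracy vanishes with the Mahalanobis distance", {
  vals <- array(0.2, c(3, 3, 50))
  mk <- structure(list(values = vals, bins = gpdc_bins(), squared = TRUE,
                       sampling_interval = 2), class = "gpdc_spectrum")
  same <- replicate(10, mk, simplify = FALSE)
  sw <- loo_threshold_sweep(same, rep(c("a", "b"), 5),
                            thresholds = c(0.1, 0.3))
  expect_true(all(sw$sweep$mahalanobis < 1e-6))
  expect_true(all(sw$sweep$discriminant_accuracy < 1e-6))
})
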