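test_that("normality gate applies the skewness/kurtosis rule strictly", {
  set.seed(111)
  expect_equal(normality_gate(rnorm(1000))$route, "parametric")
  # heavy tails: Pearson kurtosis above 7
  heavy <- c(rnorm(200), 25, -25, 30)
  gk <- normality_gate(heavy)
  expect_gt(gk$kurtosis, 7)
  expect_equal(gk$route, "nonparametric")
  # strict inequality at the boundary: cut-off equal to the sample value
  x <- rexp(500)
  g <- normality_gate(x)
  expect_equal(normality_gate(x, skew_cutoff = abs(g$skewness),
                              kurt_cutoff = g$kurtosis)$route,
               "parametric")
  expect_error(normality_gate(rep(2, 10)), "zero-variance")
})

test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  expect_equal(kruskal_wallis(c(1, 2, 3), c(4, 5, 6))$H, 3.857,
               tolerance = 1e-3)
  expect_equal(kruskal_wallis(c(1, 2), c(3, 4))$H, 2.4)
  expect_equal(kruskal_wallis(c(5, 1, 9), c(5, 1, 9))$H, 0)
  # tie correction agrees with the oracle
  a <- c(1, 2, 2, 7); b <- c(2, 5, 5, 8)
  expect_equal(kruskal_wallis(a, b)$H, kw_oracle(a, b))
  expect_error(kruskal_wallis(rep(1, 3), rep(1, 4)), "tied")
})

test_that("binwise cluster rule reports exactly the qualifying runs", {
  # constructed spectra: two groups differing only on path 2->1 in bins
  # 10..20, separated enough that each bin's KW p-value is < .05
  mk <- function(subject_shift) {
    vals <- array(0.2, c(3, 3, 50))
    vals[1, 2, 10:20] <- 0.2 + subject_shift
    structure(list(values = vals, bins = gpdc_bins(), squared = TRUE,
                   sampling_interval = 2), class = "gpdc_spectrum")
  }
  set.seed(112)
  ga <- lapply(rnorm(10, 0.10, 0.01), mk)
  gb <- lapply(rnorm(10, 0.00, 0.01), mk)
  res <- binwise_cluster_test(ga, gb)
  expect_equal(nrow(res), 1L)
  expect_equal(res$source, 2L)
  expect_equal(res$target, 1L)
  expect_equal(res$direction, "A>B")
  expect_equal(res$band_low_hz, gpdc_bins()[10])
  expect_equal(res$band_high_hz, gpdc_bins()[20])
  # a 4-bin effect does not qualify
  mk4 <- function(s) {
    v <- array(0.2, c(3, 3, 50)); v[1, 2, 10:13] <- 0.2 + s
    structure(list(values = v, bins = gpdc_bins(), squared = TRUE,
                   sampling_interval = 2), class = "gpdc_spectrum")
  }
  ga4 <- lapply(rnorm(10, 0.10, 0.01), mk4)
  gb4 <- lapply(rnorm(10, 0.00, 0.01), mk4)
  expect_equal(nrow(binwise_cluster_test(ga4, gb4)), 0L)
})

test_that("the run rule keeps the per-path null flag rate near nominal", {
  # exchangeable groups: flags can only be false positives; the 5-bin
  # consistent-direction rule keeps the per-path rate close to the
  # per-bin level (bins from one fitted VAR are strongly correlated,
  # so it does not shrink much further; see the methods vignette)
  nflag <- 0; nrep <- 15
  for (r in 1:nrep) {
    coh <- generate_cohort(edge_spec(att_b = 1), c(12, 12), 256,
                           seed = 7000 + r)
    g <- raw_gpdc(coh)
    res <- binwise_cluster_test(g$spectra[g$labels == "A"],
                                g$spectra[g$labels == "B"])
    nflag <- nflag + nrow(unique(res[, c("source", "target")]))
  }
  rate <- nflag / (nrep * 30)
  expect_lt(rate, 0.10)
})

test_that("window summary partitions GPDC mass into strength windows", {
  ws <- window_summary(list(c(0.1, 0.25, 0.4, 0.5)))
  expect_equal(unlist(ws[1, c("pct_w1", "pct_w2", "pct_w3")]),
               c(pct_w1 = 25, pct_w2 = 25, pct_w3 = 50))
  expect_equal(ws$mean_w3, 0.45)
  expect_equal(ws$pct_out, 0)
  # all below the lowest boundary: everything is out-of-range mass
  ws0 <- window_summary(list(c(0.01, 0.02, 0.04)))
  expect_equal(unlist(ws0[1, c("pct_w1", "pct_w2", "pct_w3")]),
               c(pct_w1 = 0, pct_w2 = 0, pct_w3 = 0))
  expect_equal(ws0$pct_out, 100)
  expect_true(is.na(ws0$mean_w1))
  # percentages plus out-of-range mass always total 100
  set.seed(113)
  vals <- list(runif(200, 0, 0.7), runif(200, 0, 0.7))
  wsr <- window_summary(vals)
  expect_equal(rowSums(wsr[, c("pct_w1", "pct_w2", "pct_w3", "pct_out")]),
               c(100, 100))
})

test_that("globally attenuated coupling lowers high-strength connectivity", {
  dense <- coupling_spec(
    n_channels = 6, order = 1,
    edges = data.frame(source = c(2, 3, 5, 6), target = c(1, 2, 4, 5),
                       lag = 1, coef = c(0.8, 0.6, 0.7, 0.5)),
    attenuation = c(A = 1, B = 0.7))
  lower <- 0
  for (r in 1:10) {
    coh <- generate_cohort(dense, c(8, 8), 256, seed = 300 + r)
    g <- raw_gpdc(coh)
    ws <- window_summary(g$spectra)
    lower <- lower +
      (mean(ws$pct_w3[g$labels == "B"]) < mean(ws$pct_w3[g$labels == "A"]))
  }
  expect_gte(lower, 9)
})

test_that("leave-one-out reliability counts folds and applies strict thresholds", {
  set.seed(114)
  vals <- c(rnorm(10), rnorm(12, 8))
  labs <- rep(c("A", "B"), c(10, 12))
  r <- loo_reliability(kruskal_wallis, vals, labs, alpha = 0.05,
                       threshold = 0.9917)
  expect_equal(r$n_folds, 22L)
  expect_equal(r$fraction_significant, 1)
  expect_true(r$is_reliable)
  # null data: nothing reliable
  r0 <- loo_reliability(kruskal_wallis, rnorm(22), labs, alpha = 0.05,
                        threshold = 0.9917)
  expect_false(r0$is_reliable)
  # constant outcome gives an exact 0/1 fraction
  expect_true(loo_reliability(function(a, b) list(p_value = 1),
                              vals, labs, 0.05, 0.5)$fraction_significant == 0)
  # fraction exactly at the threshold is NOT reliable (strict "more than")
  counter <- function(a, b)
    list(p_value = if (8 %in% c(a, b)) 0 else 1)   # fails only without subject 8
  vals2 <- c(1:10, 101:112)
  rth <- loo_reliability(counter, vals2, labs, alpha = 0.05,
                         threshold = 21 / 22)
  expect_equal(rth$fraction_significant, 21 / 22)
  expect_false(rth$is_reliable)
})

test_that("Bonferroni thresholds reproduce the printed analytic values", {
  expect_equal(bonferroni_threshold(m = 6)$reliability_percent, 99.17)
  expect_equal(bonferroni_threshold(m = 4)$alpha, 0.0125)
  expect_equal(bonferroni_threshold(m = 2)$alpha, 0.025)
  b1 <- bonferroni_threshold(m = 1)
  expect_equal(b1$alpha, 0.05)
  expect_equal(b1$reliability_percent, 95)
  expect_error(bonferroni_threshold(m = 0))
})
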