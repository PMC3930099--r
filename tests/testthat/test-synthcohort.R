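test_that("build_stable_var realises the requested coupling and stays stable", {
  # requested edge lands in the right coefficient slot
  m <- build_stable_var(edge_spec(coef = 0.4), "A")
  expect_equal(m$A[[1]][1, 2], 0.4)
  expect_equal(m$A[[1]][2, 1], 0)
  # attenuation applied multiplicatively for group B
  mb <- build_stable_var(edge_spec(coef = 0.4, att_b = 0.3), "B")
  expect_equal(mb$A[[1]][1, 2], 0.12)
  # all-zero edges: trivially stable, zero cross-coefficients
  m0 <- build_stable_var(coupling_spec(n_channels = 3, self_coupling = 0),
                         "A")
  expect_true(all(m0$A[[1]] == 0))
  expect_lt(spectral_radius(m0), 1)
  expect_error(build_stable_var(edge_spec(), "C"), "unknown group")
})

test_that("unstable coefficient sets are uniformly rescaled below radius 1", {
  # strong cyclic coupling is unstable before stabilisation
  spec <- coupling_spec(
    n_channels = 3, order = 2, self_coupling = 0.9,
    edges = data.frame(source = c(1, 2, 3), target = c(2, 3, 1),
                       lag = c(1, 1, 2), coef = c(0.9, 0.9, 0.9)),
    attenuation = c(A = 1, B = 1))
  m <- build_stable_var(spec, "A")
  expect_true(attr(m, "rescaled"))
  # independent eigenvalue oracle: companion matrix built by hand
  k <- m$k; p <- m$p
  C <- rbind(do.call(cbind, m$A),
             cbind(diag(k * (p - 1)), matrix(0, k * (p - 1), k)))
  expect_lt(max(Mod(eigen(C, only.values = TRUE)$values)), 1)
  expect_equal(max(Mod(eigen(C, only.values = TRUE)$values)), 0.95,
               tolerance = 1e-8)
  # topology preserved: zero entries stay zero, nonzero stay nonzero
  expect_true(m$A[[1]][2, 1] > 0)
  expect_equal(m$A[[1]][3, 1], 0)
})

test_that("random stable VAR ensemble is always stable", {
  for (i in 1:25) {
    m <- random_stable_var(sample(2:6, 1), sample(1:5, 1), seed = i)
    expect_lt(spectral_radius(m), 1)
    expect_true(all(diag(m$Sigma) > 0))
  }
})

test_that("simulated time courses match their generating model", {
  # zero model: unit white noise
  m0 <- var_model(list(matrix(0, 3, 3)), diag(3))
  Y <- simulate_timecourses(m0, 5000, seed = 4)
  expect_equal(dim(Y), c(3L, 5000L))
  expect_true(all(abs(rowMeans(Y)) < 0.1))
  expect_true(all(abs(apply(Y, 1, var) - 1) < 0.1))
  # lag-0 covariance vs the discrete Lyapunov solution
  A <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2)
  m <- var_model(list(A), diag(2))
  Y <- simulate_timecourses(m, 20000, seed = 5)
  S <- tcrossprod(Y - rowMeans(Y)) / (ncol(Y) - 1)
  P <- matrix(solve(diag(4) - kronecker(A, A), as.numeric(diag(2))), 2, 2)
  expect_true(all(abs(S - P) / max(abs(P)) < 0.1))
  # determinism
  expect_identical(simulate_timecourses(m, 100, seed = 7),
                   simulate_timecourses(m, 100, seed = 7))
  # unstable model refused
  bad <- var_model(list(diag(1.05, 2)), diag(2))
  expect_error(simulate_timecourses(bad, 100, seed = 1), "unstable")
})

test_that("generate_cohort reproduces the study design", {
  coh <- generate_cohort(edge_spec(), seed = 3, n_time = 64)
  expect_s3_class(coh, "cohort")
  labs <- cohort_labels(coh)
  expect_equal(as.integer(table(labs)[c("A", "B")]), c(23L, 29L))
  expect_equal(dim(coh$subjects[[1]]$timecourses), c(6L, 64L))
  expect_equal(coh$sampling_interval, 2)
  # reproducibility: same master seed, same cohort
  coh2 <- generate_cohort(edge_spec(), seed = 3, n_time = 64)
  expect_identical(coh$subjects[[10]]$timecourses,
                   coh2$subjects[[10]]$timecourses)
  expect_identical(coh$subjects[[10]]$covariates,
                   coh2$subjects[[10]]$covariates)
})

test_that("cohort covariates carry the perinatal dependence structure", {
  coh <- generate_cohort(edge_spec(), n_per_group = c(40, 60), n_time = 64,
                         seed = 11)
  labs <- cohort_labels(coh)
  ga <- vapply(coh$subjects, function(s) s$covariates$gestational_age,
               numeric(1))
  us <- vapply(coh$subjects, function(s) s$covariates$ultrasound, numeric(1))
  # gestational-age ranges respect the group definitions
  expect_true(all(ga[labs == "A"] >= 37 & ga[labs == "A"] <= 42))
  expect_true(all(ga[labs == "B"] < 33))
  # ultrasound codes 0/1/2, abnormal only in the VPT-like group
  expect_true(all(us %in% 0:2))
  expect_true(all(us[labs == "A"] == 0))
  # negative GA-ultrasound rank correlation within the VPT-like group
  expect_lt(cor(ga[labs == "B"], us[labs == "B"], method = "spearman"), 0)
})

test_that("attenuation transfers to population GPDC on the designated edge", {
  # large-T single-subject check of the structure-transfer property
  ma <- build_stable_var(edge_spec(coef = 0.4, att_b = 0.3), "A")
  mb <- build_stable_var(edge_spec(coef = 0.4, att_b = 0.3), "B")
  ga <- gpdc_spectrum(fit_var(simulate_timecourses(ma, 8000, seed = 1), 1))
  gb <- gpdc_spectrum(fit_var(simulate_timecourses(mb, 8000, seed = 2), 1))
  expect_gt(mean(ga$values[1, 2, ]), mean(gb$values[1, 2, ]))
  # and in small replicate cohorts the group means order the same way
  lower <- 0
  for (r in 1:10) {
    coh <- generate_cohort(edge_spec(), c(8, 8), 256, seed = r)
    g <- raw_gpdc(coh)
    mA <- mean(vapply(g$spectra[g$labels == "A"],
                      function(s) mean(s$values[1, 2, ]), numeric(1)))
    mB <- mean(vapply(g$spectra[g$labels == "B"],
                      function(s) mean(s$values[1, 2, ]), numeric(1)))
    lower <- lower + (mB < mA)
  }
  expect_gte(lower, 9)
})

test_that("realignment generator honours drift, spikes and seeds", {
  expect_equal(generate_realignment(50, drift_scale = 0, seed = 1),
               generate_realignment(50, drift_scale = 0, seed = 2),
               ignore_attr = TRUE)
  expect_true(all(generate_realignment(50, drift_scale = 0, seed = 1) == 0))
  rp <- generate_realignment(
    100, drift_scale = 0,
    spikes = list(list(index = 40, translation = c(0.3, 0, 0))), seed = 1)
  expect_gte(motion_summary(rp)$n_movements, 1)
  expect_identical(generate_realignment(64, seed = 9),
                   generate_realignment(64, seed = 9))
})

test_that("component-map generator feeds GOF matching as designed", {
  tpl1 <- array(0, c(5, 5, 2)); tpl1[1:2, 1, 1] <- 1
  tpl2 <- array(0, c(5, 5, 2)); tpl2[4:5, 5, 2] <- 1
  maps <- generate_component_maps(list(tpl1, tpl2), snr = Inf, seed = 1)
  expect_length(maps, 4)   # two signal + two distractors
  # noiseless maps: each template's own map wins its ranking
  r1 <- rank_and_select(maps, tpl1)
  expect_equal(r1$selected, 1L)
  expect_equal(rank_and_select(maps, tpl2)$selected, 2L)
  # disjoint templates at high snr: own-mask GOF beats cross-mask GOF
  maps_hi <- generate_component_maps(list(tpl1, tpl2), snr = 8, seed = 2)
  expect_lt(gof_score(maps_hi[[1]], tpl2), gof_score(maps_hi[[1]], tpl1))
  expect_error(generate_component_maps(list(tpl1, array(0, c(4, 4, 2)))),
               "grid")
})
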