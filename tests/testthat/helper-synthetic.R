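# Shared synthetic fixtures, built in code.

# One attenuated directed edge 2 -> 1; group B couples at 30% strength.
edge_spec <- function(coef = 0.35, att_b = 0.3, k = 6) {
  coupling_spec(
    n_channels = k, order = 1,
    edges = data.frame(source = 2, target = 1, lag = 1, coef = coef),
    attenuation = c(A = 1, B = att_b))
}

# Small cohort for fast structural tests.
quick_cohort <- function(seed = 1, n = c(5, 6), n_time = 128) {
  generate_cohort(edge_spec(), n_per_group = n, n_time = n_time, seed = seed)
}

# GPDC spectra for an exact-VAR synthetic cohort: fit on the raw series
# (no band-pass; the generator is already a finite-order VAR).
raw_gpdc <- function(cohort, order = 1) {
  cohort_gpdc(cohort, order = order, filter = FALSE)
}

# Independent hand computation of the two-group Kruskal-Wallis H with
# tie correction (the rank-formula oracle; the implementation goes
# through stats::kruskal.test).
kw_oracle <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  N <- length(x)
  Ra <- sum(r[seq_along(a)]); Rb <- sum(r) - Ra
  H <- 12 / (N * (N + 1)) * (Ra^2 / length(a) + Rb^2 / length(b)) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
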