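---
title: "Frequency-domain Granger causality between resting-state networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain Granger causality between resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgranger)
```

## The model

The pipeline treats k network time courses (one per resting-state
network or subnetwork, sampled every `sampling_interval` seconds;
defaults k = 6 and 2 s, i.e. the default mode, central executive and
salience networks split into two subnetworks each at a typical fMRI
repetition time) as a stationary vector autoregression

$$Y_t = v + \sum_{l=1}^{p} A_l\, Y_{t-l} + \varepsilon_t,
\qquad \mathrm{Cov}(\varepsilon_t) = \Sigma .$$

The entry $a_{ij}^{(l)}$ of $A_l$ is the causal coefficient from
channel $j$ to channel $i$ at lag $l$; $j$ Granger-causes $i$ when some
$a_{ij}^{(l)} \neq 0$. `fit_var()` estimates $v$ and the $A_l$ by
per-channel ordinary least squares on the lagged design and forms
$\hat\Sigma$ from residual cross-products with effective sample size
$T - p$. The transfer polynomial

$$\bar a_{ij}(\lambda) = \delta_{ij} -
  \sum_{l=1}^{p} a_{ij}^{(l)}\, e^{-\mathrm i 2\pi\lambda l}$$

yields the squared-modulus generalised partial directed coherence

$$|\pi_{ij}(\lambda)|^2 =
  \frac{|\bar a_{ij}(\lambda)|^2 / \sigma_i^2}
       {\sum_{m=1}^k |\bar a_{mj}(\lambda)|^2 / \sigma_m^2},$$

computed by `gpdc_spectrum()` at each bin centre of a 0.002 Hz grid
spanning 0.05–0.15 Hz (50 bins). The $1/\sigma_i$ weighting
("generalised" PDC) makes the measure invariant to channel scale; the
column normalisation bounds every value in [0, 1] and makes each source
column sum to 1 over targets, so the squared modulus reads as the
proportion of the source spectrum sent to each target after partialling
out the remaining channels. Both properties are asserted across random
stable ensembles in the test suite, to 1e-10.

Assumptions worth keeping in mind: linearity and covariance
stationarity of the network dynamics; an adequate finite VAR order; and
innovations whose diagonal variances $\sigma_i^2$ meaningfully scale
the channels. GPDC is a model property — every spectral conclusion is
conditional on the fitted VAR.

## Tunable parameters

| Parameter | Where | Default | Units | Why |
|---|---|---|---|---|
| `sampling_interval` | throughout | 2 | s | common fMRI repetition time; Nyquist 0.25 Hz |
| `band` | spectra, gpdc | 0.05–0.15 | Hz | endogenous BOLD fluctuation band, clear of drift and respiratory/cardiac aliasing |
| `bin_width` | gpdc | 0.002 | Hz | 50 bins across the band; spectral specificity at T = 256 |
| `order` / `p_max` | gpdc | BIC, p ≤ 5–10 | lags | group-level BIC; BIC preferred to AIC against order inflation |
| `movement_threshold` | motionqc | 0.1 | mm | displacement above which a step counts as a movement |
| `run_length`, `alpha` | groupcompare | 5, .05 | bins, level | five neighbouring significant bins required before a band is reported |
| window boundaries | groupcompare | .05/.20/.35/.55 | GPDC | low/mid/high connection-strength windows |
| `thresholds` | topolda | .05–.55 by .01 | GPDC | sweep range covering the observed GPDC mass |
| `ridge` | topolda | 1e-6 | relative | stabilises the pooled covariance of ~30 binary features on ~50 subjects |
| `n_boot`, `alpha` | moderation | 1000, .025 | — | percentile bootstrap; .025 = .05 Bonferroni-corrected for two moderators |

## The synthetic-data generator

`generate_cohort()` emulates the *statistical* structure the analysis
assumes, at the network level:

* per-group stable VAR generators realised from a `coupling_spec` —
  k = 6 channels, lag-1 self-coupling 0.3, designated directed edges
  (default scenario: one edge at coefficient 0.35), and a multiplicative
  per-group attenuation (default 0.3 for the "VPT-like" group),
  reproducing a reduction of high-strength directed connections in the
  clinical group; coefficients are uniformly rescaled to companion
  spectral radius 0.95 whenever a draw is unstable, which preserves the
  edge topology;
* T = 256 samples per subject at 2 s, matching a nine-minute
  resting-state acquisition; burn-in 500 samples (transients decay
  below 1e-3 at radius 0.95);
* group sizes defaulting to 23 term-like and 29 VPT-like subjects;
* realignment-parameter series (smoothed random-walk drift, optional
  spikes) as fixtures for the motion metrics;
* covariates: gestational age uniform-ish within 37–42 weeks
  (term-like) and 25–33 weeks (VPT-like); ultrasound classification
  (0 normal / 1 uncomplicated haemorrhage / 2 haemorrhage with
  dilatation) tied to gestational age by a Gaussian copula with rank
  correlation −0.545 within the VPT-like group; and an
  executive-function score generated as
  $b_0 + b_1 x + b_2\,GA_z + b_3\,x\,GA_z + \text{noise}$ with $x$ the
  subject's realised coupling scale, so moderation recovery is testable
  against known coefficients.

Per-subject seeds are drawn once from the master-seeded stream (one
draw per subject), so cohorts are pure functions of (spec, seed) and
reproducible subject-wise.

What the generator does **not** emulate: haemodynamic convolution and
its regional variability, measurement noise with spatial structure,
physiological confounds, non-stationarity, or 4-D volumes (no ICA step
is simulated; component maps for template matching are generated
separately as noisy mask indicators by `generate_component_maps()`).
Passing tests therefore demonstrate that the *statistical machinery*
behaves as designed on data satisfying its assumptions — not that those
assumptions hold for any particular fMRI dataset.

## Numerical choices and design decisions

**Transfer polynomial.** The exponent in $\bar a_{ij}(\lambda)$ is
$e^{-\mathrm i 2\pi\lambda l}$ with $\lambda = f \cdot \Delta t$ cycles
per sample; bin values are evaluated at bin centres (at 0.002 Hz pitch
a within-bin average differs negligibly and costs determinism nothing).

**Squared modulus vs amplitude.** The reported scalar is the squared
modulus (a proportion of sent power); the amplitude form
$|\pi_{ij}(\lambda)|$ is available via `squared = FALSE`.

**Band-pass filtering and VAR estimation.** `bandpass_filter()` is
zero-phase frequency-domain masking with a 0.01 Hz cosine roll-off:
exact band edges and no phase distortion of the lag relationships on
which Granger-causal estimates depend. For *recorded broadband* signals
filtering into the band of interest precedes fitting (the default,
`filter = TRUE`). For series that are already finite-order VAR
realisations — the synthetic cohorts — filtering is actively harmful: a
strictly band-limited process has no finite autoregressive
representation, so group BIC inflates the order towards its cap and
low-order fits acquire spurious reverse-direction coupling (the
well-documented filtering pathology of Granger-causal estimation; see
Barnett & Seth, *J Neurosci Methods* 2011). Synthetic-cohort validation
therefore fits on the raw simulated series (`filter = FALSE`).

**Order selection.** Per-subject BIC is
$\log\det\hat\Sigma(p) + \frac{\log T_{\mathrm{eff}}}{T_{\mathrm{eff}}}(p k^2 + k)$
with $T_{\mathrm{eff}} = T - p$, summed over subjects; the group
argmin is used for every subject so that spectra are comparable.

**Five-bin cluster rule.** Per path and bin, a two-group
Kruskal–Wallis test (tie-corrected, chi-square p on 1 df) at the 95%
threshold; a band is reported only when at least five neighbouring bins
are significant *with a consistent effect direction* (a band has one
direction). Callers should know the rule's actual type-I behaviour:
for VAR-based spectra the 50 bins are strongly correlated across
subjects (for an order-1 fit the off-diagonal numerator
$|\bar a_{ij}|^2$ is frequency-constant), so the rule behaves like
slightly more than one test per path at the per-bin level rather than
like a stringent run requirement. Measured over 200 null cohorts
(n = 25/25, T = 256), the per-path flag rate is ~5.5%, against 4.7%
for a single tie-corrected Kruskal–Wallis at that sample size. The rule
earns its keep against isolated-bin noise in higher-order fits, but it
is *not* conservative relative to α = .05 when bin values are smooth
functionals of one fitted model — treat flagged single-path results
near threshold accordingly.

**Connectivity windows.** Half-open windows [0.05, 0.20), [0.20, 0.35),
[0.35, 0.55); values outside [0.05, 0.55) are tracked as out-of-range
mass so each subject's percentages total 100.

**Leave-one-out reliability.** One fold per left-out participant (n
folds); an effect is reliable only when the significant fraction
*strictly exceeds* the threshold (e.g. 0.9917 — the 95% threshold
Bonferroni-corrected for six tests).

**Motion metrics.** Displacement is the root mean square of the three
axis translation deltas between consecutive volumes (divide by 3 under
the root; the Euclidean norm is available via `norm = "euclidean"`).
The first volume has no predecessor and contributes nothing. The
per-subject rotation summary is the mean per-step Euler angle
(`rotation_summary = "max"` optional); rotations are assumed to be in
radians, the common realignment-parameter convention. The arccos
argument of the Euler formula is clipped to [−1, 1] so an identity
rotation returns 0 rather than NaN. The bootstrap group test returns
the percentile position of zero in the resampled mean-difference
distribution; at n ≈ 20 per group this percentile-of-zero construction
is mildly anticonservative (measured ~3.5% rejections at the .0125
level under the null), which is inherent to the estimator rather than
to the implementation — interpret borderline motion differences with a
t-test as well.

**Template matching.** Z-scoring uses population variance over
analysis-mask voxels (`variance = "sample"` optional); voxels outside
the analysis mask are excluded from both means so empty space cannot
inflate scores. The exclusion rule covers the common failure mode in which the
best-fitting component is actually an artifact (typically
cerebrospinal fluid in ventricle-adjacent networks): the top-ranked
component is skipped whenever *any* artifact template fits it better
than the target does; ties in GOF break toward the lower component
index, and every skip is logged.

**Fisher LDA.** Binary topology features on ~50 subjects guarantee a
near-singular pooled covariance, so the discriminant uses a
pseudo-inverse with ridge 1e-6 (relative to the mean diagonal); the
boundary sits midway between projected group means; held-out subjects
are binarised with the same threshold but never enter the fold's fit.
Degenerate folds count as misclassifications. Ties in the threshold
sweep break toward the larger Mahalanobis distance, then the lower
threshold. The per-path scalar reduced over bins before thresholding is
the band mean (`per_bin_max` optional).

**Moderation.** Predictors are not mean-centred by default (centring is
an option and changes only the interpretation of the main effects);
moderators are analysed one at a time because gestational age and
ultrasound classification are collinear; gestational-age
stratification, where requested, is a median split. Bootstrap
resamples with a collinear design are skipped and counted, with a
warning above 10% skips.

## Problem sizes

The test suite validates at the scales the method targets: cohorts of
23 + 29 (or 25 + 25) subjects, k = 6 channels, T = 256 samples;
100-replicate simulations for detection/recovery rates;
500 replicates for bootstrap coverage; ensembles of 100 random stable
VARs (k ≤ 6, p ≤ 5) for the normalisation, boundedness and stability
properties.

## Known limitations

* GPDC inherits every limitation of VAR modelling at fMRI timescales:
  slow sampling relative to neuronal dynamics, haemodynamic blurring,
  and sensitivity to order misspecification.
* The five-bin cluster rule is not conservative for smooth model-based
  spectra (see above).
* The percentile bootstrap group test is anticonservative at small n
  (see above).
* `fit_lda` with 30 binary features and ~50 subjects relies on the
  ridge; the reported weights are interpretable only jointly, not
  path-by-path.
* The synthetic generator's effect sizes are calibrated to reproduce
  qualitative group differences (direction and detectability), not any
  specific empirical effect magnitude.
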