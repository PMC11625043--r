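---
title: "Measuring hemispheric lateralization of resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemispheric lateralization of resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemilat)
```

## The measurement model

Cortical vertices come in homotopic pairs — mirror-symmetric locations, one
per hemisphere, linked by an explicit bijection in the atlas. For each
vertex, two connectivity strengths are computed from the Fisher-z
(`atanh`-transformed Pearson) functional-connectivity matrix of its BOLD
time series:

* **intra** — the sum of z-connectivity to every other vertex in the *same*
  hemisphere (self excluded), and
* **he** — the sum of z-connectivity to every vertex in the *opposite*
  hemisphere except the homotopic partner (interhemispheric *heterotopic*
  connectivity).

For each homotopic pair, the laterality index is

$$\mathrm{LI} = \frac{L - R}{|L + R|},$$

computed separately for the intra and he strengths. Positive values mean
stronger left-hemispheric interactions, negative values stronger
right-hemispheric ones. Network-based LIs average the pair-wise LIs over the
homotopic pairs whose two members carry the same network label (seven
task-relevant networks: SMN, AUD, LAN, DAN, CON, FPN, DMN; unlabeled
`NONE` vertices contribute to the strength sums but never to network
averages). *Alignment-to-young* is the cosine similarity between a
subject's pair-wise LI vector and the mean LI vector of the young
non-musician (YNM) group over the same network's pairs: a scalar per
subject, network and LI kind that measures how youth-like the subject's
lateralization pattern is.

The inferential battery mirrors the study design this package models
(three groups: young non-musicians, older musicians OM, older non-musicians
ONM): one-sample t tests on network LIs; one-way ANOVA across groups with a
mean-centered Levene gate at $\alpha = 0.05$ choosing between the classic F
(with pooled-t/FDR post hocs) and the Welch F (with Games-Howell post
hocs); Jonckheere-Terpstra tests for the ordered trend YNM > OM > ONM in
alignment; and partial correlations between LI (or alignment) and
speech-reception thresholds in the older groups, residualizing age, gender
(0/1), education, hearing level, MoCA, digit span, Stroop, mean framewise
displacement and mean global FC. Benjamini-Hochberg adjustment is applied
within each family of seven network tests.

## Numerical choices

* **Fisher clipping.** Correlations are clipped to $\pm(1-10^{-7})$ before
  `atanh`; a perfectly correlated degenerate pair then contributes a large
  finite z (≈ 8.41) instead of infinity.
* **Self-correlation** is excluded from the intra sum: `atanh(1)` is
  infinite and would dominate every sum.
* **LI validity.** The index is undefined when $|L+R|$ vanishes. Pairs with
  $|L + R| < \varepsilon$ (default $10^{-8}$) are masked rather than
  clipped: clipping would bias network means, masking only reduces the pair
  count. $|\mathrm{LI}| > 1$ is possible when $L$ and $R$ have opposite
  signs and is kept as computed — the definition imposes no bound.
* **Motion QC.** Frames with FD strictly above 0.5 mm are censored before
  correlation (a `scrub` flag disables this for controlled experiments);
  subjects with strictly more than 20% flagged frames are excluded. The
  mFD covariate is the mean over *all* frames, before censoring.
* **Template validity** is handled listwise within each network: a pair
  invalid in any young subject is dropped from the template, so every
  alignment uses a single fixed index set per network. By default a young
  subject's own map is included in the template it is compared against
  (`template_mode = "leave_one_out"` switches to the jackknife variant);
  the group-average definition makes no exclusion, so inclusion is the
  default.
* **Welch effect size.** Partial eta squared is defined from the classic
  between/within sums of squares; it is reported unchanged next to the
  Welch F, which is the only reading consistent with printing
  $\eta_p^2$ alongside a Welch statistic.
* **Jonckheere-Terpstra** uses the normal approximation with tie-corrected
  variance (group sizes in the intended uses exceed 20), one-sided in the
  hypothesized direction; a decreasing trend gives a negative z. A null
  variance of zero (all observations tied) defines z = 0.
* **Psychometric fit.** A two-parameter logistic
  $P(\mathrm{SNR}) = 1/(1+e^{-(\mathrm{SNR}-\alpha)/\beta})$ is fitted to
  proportions correct by Levenberg-Marquardt least squares (guess and lapse
  rates fixed at 0). Initialization: $\alpha_0$ = the SNR level with
  proportion nearest 0.5, $\beta_0 = 1$ dB; $\beta$ is bounded below by
  $10^{-6}$. The speech-reception threshold per masker type is the mean of
  the two spatial-condition $\alpha$s; fitting a single logistic to the
  pooled counts is a defensible alternative reading and can be obtained by
  summing the per-condition counts before fitting.

## The synthetic cohort

Real imaging data are deliberately out of scope; every stage is instead
verified on cohorts with *planted* structure. Per-subject time series are
zero-mean multivariate normal draws from a latent-factor covariance: each
network contributes one intra factor per hemisphere (loading
$\sqrt{\mathrm{intra}_H}$ on that hemisphere's network vertices), one
heterotopic factor (loadings $\sqrt{\mathrm{hetero}_L}$,
$\sqrt{\mathrm{hetero}_R}$), and one homotopic factor per pair, plus
independent noise. Because the covariance is a Gram matrix plus a positive
diagonal, it is positive semidefinite for *any* nonnegative weights — the
reason a factor construction was chosen over direct block filling — and
population correlations are available in closed form
(`expected_correlations()`), which the tests check against long-run sample
correlations.

Defaults emulate the modeled study: group sizes 24/23/23 (YNM/OM/ONM), 750
timepoints per subject, an atlas of 120 homotopic pairs per network plus 48
unlabeled pairs (1,776 vertices), fixed gender splits 12/12, 9/14, 14/9,
and covariates drawn from the published per-group means and SDs
(independent truncated normals — the summaries constrain nothing more).
Group plans encode the qualitative findings being emulated: the young plan
carries planted asymmetries (right-lateralized CON intra and LAN he, a
left-lateralized DMN, milder asymmetries elsewhere), the ONM plan is fully
symmetric, and the OM plan retains 80% of the young asymmetry. The
magnitudes themselves are calibration choices — per-network coupling
weights around 0.15–0.42 against unit noise, giving within-network
correlations near 0.2–0.3 — since no empirical per-network FC distributions
are available to match. Behavior is linked to lateralization through a
linear-Gaussian rule (`behavior_link()`): threshold = group mean + slope ×
realized network LI + covariate effects + noise, so the planted partial
correlation has the closed form
$b\,\sigma_{LI}/\sqrt{b^2\sigma_{LI}^2+\sigma_e^2}$ and recovery can be
tested exactly; the default slope is 0.

What the generator does *not* emulate: hemodynamic autocorrelation,
spatially structured noise, motion artifacts correlated with signal,
surface geometry, and inter-subject variability in network topography.
Passing tests therefore demonstrate the correctness of the *computational
machinery* under the stated generative model, not the empirical claims of
any real-data analysis.

## Verification strategy and problem sizes

The test suite checks three layers, at sizes chosen to keep a full run in
minutes:

1. **Exact oracles** — hand-computed examples and brute-force
   re-implementations (double-loop strength sums, inverse-correlation
   partial r, enumerated Mann-Whitney counts, step-up BH) on ≥ 50 random
   small instances, agreeing to $10^{-8}$ or better.
2. **Invariances** — hemisphere relabeling negates every valid LI exactly
   (bitwise, since $(L-R)$ and $(R-L)$ are exact negations in floating
   point); global time-series rescaling leaves LI maps unchanged;
   symmetric-plan covariances are exactly invariant under the
   pair-swap permutation.
3. **Calibration and recovery** — on symmetric-plan cohorts (one network of
   40 pairs, 300 timepoints, 8 subjects per group) the mean network LI
   stays within 3 standard errors of zero over 200 replicate cohorts, and
   the gated ANOVA and the one-sided trend test hold their nominal 5% level
   within ±1 percentage point over 2,000 replicates; three increasing
   planted asymmetries yield strictly increasing mean LIs; young-plan
   subjects score reliably higher alignment-to-young than symmetric-plan
   subjects (one-sided p < 0.01 over 100 replicates); and the published
   summary-statistic battery is reproduced from the bundled group summaries
   to within the rounding of two-decimal inputs.

A worked end-to-end example:

```{r example, eval = FALSE}
cfg <- run_config(seed = 42, simulate = list(
  group_sizes = c(YNM = 8, OM = 12, ONM = 12),
  pairs_per_network = c(SMN = 5, AUD = 4, LAN = 5, DAN = 4, CON = 5,
                        FPN = 4, DMN = 4, NONE = 2),
  n_timepoints = 80))
res <- run_full(cfg)
head(res$stats)
run_table1(res$cohort)
```

## Known limitations

* The Levene gate at $\alpha = 0.05$ is one of several defensible
  heterogeneity gates; the gate actually used alongside published Welch
  statistics is rarely stated, so `force = "classic"/"welch"` overrides it.
* Covariates are generated independently; real demographic covariates
  correlate (age with hearing, education with cognition), so partial
  correlation behavior under collinear covariates is exercised only by the
  dedicated rank-deficiency error path.
* The normal approximation of the Jonckheere-Terpstra test is inaccurate
  below ~5 observations per group; no exact enumeration is provided.
* Group-level map correlations compare pair-wise LI vectors; vertex-level
  maps in surface space (and any spatial-autocorrelation-aware inference)
  are out of scope.
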