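---
title: "Phylogenetic comparative methods for cerebello-cerebral allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative methods for cerebello-cerebral allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsallometry)
```

## The scientific question

Across primates, cerebellar and cerebral volumes covary tightly. Because
species share evolutionary history, their trait values are not independent
observations: closely related species resemble each other simply because
they diverged recently. Every analysis in this package therefore treats the
phylogeny as the backbone of the error structure. The central questions are
allometric: does the cerebellum scale isometrically with the cerebrum (a
log-log slope of 1), and does the ansiform area (cerebellar crura I–II, the
lobules most connected with transmodal cerebral cortex) scale faster than
the rest of the cerebello-cerebral system? A slope above 1 (hyper-allometry)
means the structure expands disproportionately in larger brains, which by
itself produces large volume *ratios* in large-brained species — ratios are
a consequence of allometry, not independent evidence of specialization.

## The model stack

**Phylogenetic covariance.** For a rooted, time-calibrated tree, the
Brownian-motion (BM) expectation is `cov(y_i, y_j) = sigma2 * C[i, j]`,
where `C[i, j]` is the shared root-to-MRCA path length of species `i` and
`j` (`phylo_vcv()`, computed by accumulating each edge over its descendant
tips). Model transforms act on `C` rather than on branch lengths so they
compose cleanly: Pagel's lambda multiplies off-diagonals (`lambda = 0` is
the star phylogeny of independent species), the Ornstein–Uhlenbeck
transform uses the fixed-root, non-stationary form (appropriate for a tree
calibrated from a dated root; the stationary form would be a config
alternative), and Early Burst rescales shared time as
`(exp(r t) - 1) / r`, continuously approaching BM as `r -> 0`.

**Model fitting.** `fit_model()` maximizes the multivariate normal
likelihood with among-species covariance `C(theta)` and among-trait
covariance `R` (Kronecker structure). The variance convention is ML
(n-divisor) throughout, because AIC comparison across models requires joint
ML; the PGLS standard errors below use the usual `n - p` divisor instead.
Missing trait values are removed by row-deletion on the stacked
(species x trait) covariance, which is exact for these Gaussian models;
with complete data the root states and `R` have closed forms, with missing
data they are profiled numerically from complete-case starts. Shape
parameters are profiled on a coarse grid (lambda at 0, 0.25, ..., 1;
log-spaced alpha and r scaled by tree depth) followed by local refinement
to 1e-8 on the log-likelihood. Parameter counts are itemized per fit
(`k_detail`) so `AIC = 2k - 2 lnL` is auditable. Per-trait-alpha OU is fit
as independent per-trait OU models (diagonal trait covariance): a per-trait
alpha breaks the Kronecker structure, and the full multivariate-alpha OU is
deliberately out of scope. The chi-squared comparison of lambda = 1 versus
lambda = 0 uses `df = 1` by convention — the two fixed-lambda models have
equal parameter counts and are not nested in the usual sense, so the
reference distribution is a flagged choice, not a theorem.

**Ancestral states.** `ace_bm()` is the GLS/joint-ML reconstruction: with
`c_a` the covariance between an internal node and the tips, the estimate is
`z_a = z0 + c_a' C^{-1} (y - z0)` and the variance adds the uncertainty of
the GLS root `z0`. CIs are formed on the log10 scale and exponentiated on
back-transform, so they are asymmetric in mm3 — uncertainty grows toward
the past, which is visible in the root CIs printed by
`analysis/03_ancestral_states.R`.

**PGLS and isometry.** `pgls_fit()` implements
`beta = (X' C^{-1} X)^{-1} X' C^{-1} y` via Cholesky whitening, with
t-based CIs on `n - 2` degrees of freedom — at `n = 13` the t quantiles
matter. The predictor is always the larger reference structure (cerebrum,
or rest-of-cerebellum = cerebellum - ansiform, computed rather than
supplied). Isometry calls compare the *slope CI* against 1 at the 95% and
99% levels separately. An alternative display convention — whether a
same-intercept isometric line leaves the confidence *band* of the
regression — is strictly weaker and is provided only as a plot
(`plot_allometry()`); see "known limitations".

**Grade shifts.** `pancova()` augments the design with a group dummy
(intercept shift), a group x slope interaction, or both, and compares
restricted and full models by an F test in the whitened space. The
likelihood R-squared, `R2_lik = 1 - exp(-(2/n)(lnL - lnL0))`, feeds
Fisher's R-to-Z comparison of pooled versus per-group fits.

## Tunable parameters and defaults

* `min_n_for_variability = 4` specimens: below that a MAD says nothing
  about intraspecific variability and MAD% is suppressed. The MAD is raw
  (no 1.4826 consistency factor), which is what the bundled table's
  printed variability values use.
* Outlier screen: Shapiro–Wilk plus Tukey fences (quartiles +/- 1.5 IQR),
  flag-only; exclusion is an explicit downstream decision.
* Ratio display rounding: 2 decimals, half away from zero
  (`round_half_away()`), the convention the bundled table's recomputable
  cells follow.
* Ultrametricity tolerance: relative depth spread <= 1e-6, because dated
  consensus trees carry rounding.
* Generator defaults (`simulate_allometric_traits()`): predictor root
  `x_root = 4` (log10 mm3, ~10 cm3), `sigma2_x = 0.005`,
  `sigma2_e = 0.0007` per My. These are the empirical estimates from the
  bundled data on the bundled chronogram (BM rate of log10 cerebral volume,
  and the PGLS residual rate), so simulations run at realistic study
  conditions. Residuals evolve by BM on the same tree by default — that is
  exactly the assumption that makes PGLS the right estimator — with an
  `iid` mode to illustrate PGLS/OLS divergence.
* `simulate_tree()` uses a pure-birth rate of 0.042/My, giving an expected
  depth near 74 My at 34 tips, the scale of the primate crown group.
* Shrinkage factors are drawn log-uniform per species (symmetric in log
  space; a single global factor would cancel exactly on a log-log
  regression), with a plain-uniform option for sensitivity checks; which
  member of the pair carries the within-brain factor is immaterial to the
  slope and is logged in the report config. The study setting is 10,000
  replicates; the test suite uses a few hundred with correspondingly wider
  tolerances.
* Jerison's encephalization quotient is implemented in its standard form
  `EQ = brain / (0.12 P^{2/3})`: the compact printed form of that formula
  omits the brain term, and the standard quotient is what the reference
  allometry defines.

## What the synthetic data emulate — and what they do not

`simulate_tree()` + `simulate_allometric_traits()` +
`simulate_specimens()` reproduce the statistical structure the analysis
assumes: a time-calibrated tree, log-volumes coupled by a log-log allometry
with phylogenetically structured residuals, lognormal intraspecific
replicates calibrated so the expected raw MAD% hits a target, and optional
clade grade shifts. They do not emulate segmentation error, differential
tissue shrinkage by white-matter content, sex/age structure, or
non-Brownian adaptive regimes. Passing tests therefore demonstrate that
the estimators are correct and calibrated *under the stated model*, not
that real primate volumes satisfy that model.

The bundled chronogram
(`inst/extdata/synthetic_consensus_chronogram.nwk`) is a synthetic
stand-in assembled once from standard published divergence-time estimates
(root 74 My). Regression slopes on it agree with published values to about
two decimals, but node-level details differ from any specific consensus
tree; analyses intended for publication should use a dated consensus tree
from a primate phylogeny resource (e.g. 10kTrees), passed through
`parse_newick()`. Tree provenance should be recorded with results rather
than assumed — the package never guesses which tree version produced a
published number.

## Numerical choices and degenerate inputs

* Covariances are kept symmetric explicitly; transforms are checked to
  have minimum eigenvalue above -1e-10 in the property suite.
* `gls_core()` warns when the covariance condition number exceeds 1e10 and
  errors on singular designs (constant predictor).
* Pairwise-complete starting covariances for missing-data fits can be
  non-PSD; their spectrum is floored before Cholesky.
* Exactly collinear data yield zero standardized residuals (not 0/0) in
  `brain_body_residuals()`; `compute_ratios()` needs no zero-denominator
  guard because volumes are validated positive on load.
* Ties between the 95% and 99% verdicts are reported as two separate
  calls, never collapsed.
* All stochastic functions require an explicit seed and are bit-for-bit
  reproducible given one.

## Problem sizes used in the checks

The test suite and the acceptance script simulate at the study's own scale
(34 tips) with 200–1,000 replicates per property: 1,000 for CI coverage
and pANCOVA null calibration, 200 for power, 600 for the BM-versus-OU
ranking rate, a few hundred elsewhere. These counts give Monte-Carlo
standard errors of 1–3 percentage points on the rates being checked, which
is the resolution at which the assertions are written.

## Known limitations

* **Clade intercept shifts are weakly identified.** A monophyletic clade's
  shared Brownian drift is statistically close to a grade shift, so the
  pANCOVA's power against intercept shifts of realistic size (~0.3 log10
  units) is only about 0.5 at n = 34 under study-calibrated noise, while
  slope shifts of 0.2 are detected essentially always. This is a property
  of the design, not of the implementation; it argues for caution when
  interpreting non-significant grade-shift tests as evidence of absence.
* **Ansiform significance depends on the covariance structure.** With 13
  species, five of them apes sharing ~57 My of history, the BM slope CI
  for the ansiform regressions is wide: the hyper-allometric point
  estimates (~1.3) are robust, but their formal significance under the
  slope-CI convention requires either a more star-like covariance than a
  dated consensus subtree provides (the lambda MLE on this trait pair is
  ~0.5, under which the 99% CI excludes 1) or the weaker line-versus-band
  display criterion. The package reports both the calls and the CIs so the
  reader can see which convention carries a claim.
* Real specimen-level AIC tables, chi-squared statistics, shrinkage-
  corrected replication collections and EQ values require specimen-level
  or non-open data and are outside what the bundled medians can reproduce;
  the corresponding logic is exercised on published AIC differences and by
  simulation instead.
* The missing-data likelihood uses row-deletion with direct numerical
  profiling, which reproduces EM-based multivariate fits approximately,
  not bit-exactly.
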