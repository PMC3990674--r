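---
title: "Models and methods in isoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in isoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

isoniche implements a two-scale analysis of raptor nestling diet from
feather stable isotopes: Bayesian diet apportionment and diet indices at
the territory scale, niche metrics and productivity correlations at the
population scale, and a forward simulator that generates complete
studies with known ground truth. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions
taken where the methodology left genuine choices open.

## The mixing model

Each territory-year is fitted independently (no hierarchical pooling
across territories: diet estimation deliberately stays at the unit the
downstream fitness models use). For consumer $i$ and isotope
$j \in \{\delta^{13}C, \delta^{15}N\}$,

$$X_{ij} \sim N\Big(\textstyle\sum_k p_k(\mu_{jk} + \lambda_j),\;
\sum_k p_k^2(\omega_{jk}^2 + \tau_j^2) + \sigma_j^2\Big),$$

where $p$ is the diet proportion vector (simplex, $K = 8$ prey
categories), $\mu_{jk}, \omega_{jk}$ are source tissue means and SDs,
$\lambda_j, \tau_j$ the trophic discrimination factor (TDF) mean and SD,
and $\sigma_j$ a residual SD. Assumptions worth keeping in mind:

* **TDF uncertainty enters the variance term**, not resampled per MCMC
  draw. This matches the classical mean/variance composition of
  SIAR-class models and keeps the model exactly integrable on a grid for
  reduced problems, which we exploit as an independent oracle in the
  test suite.
* Source distributions are **shared across the study area** (prey
  isotope values pooled over populations).
* No concentration dependence, isotope routing, or more than two
  isotopes.

Priors: $p \sim \text{Dirichlet}(\alpha)$ with $\alpha = 1$ (flat on the
simplex) and $\sigma_j \sim U(0, 20\,\text{‰})$ — the upper bound far
exceeds any observed isotopic spread, so it is effectively
uninformative; both are configurable in `mixing_spec()`.

### Sampler and numerical choices

Random-walk Metropolis on centered-log-ratio transformed proportions
($z = \log p - \overline{\log p}$, proposals re-centered after each
step), which is simple, gradient-free and dimension-robust at $K = 8$.
Under the softmax map the Dirichlet prior plus log-Jacobian contribute
$\sum_k \alpha_k \log p_k$ to the target. Residual SDs take a reflected
random walk inside $(0, 20)$, preserving proposal symmetry. Details:

* **Initialisation**: $z$ at the prior mean plus jitter that grows with
  the chain index, so chains start overdispersed; $\sigma$ from a
  log-normal draw capped below the prior bound.
* **Adaptation**: proposal scales multiply by
  $\exp(\hat{a} - 0.3)$ every 50 burn-in iterations ($\hat{a}$ the
  recent acceptance rate), frozen after burn-in so the retained chain is
  a valid Markov chain.
* **Defaults**: 2 chains × (10,000 burn-in + 40,000 draws, thin 10).
  The reduced problems in the test suite use shorter chains
  (1,000–2,000 burn-in, 4,000–10,000 draws) — sizes chosen so the whole
  suite exercises dozens of fits while each fit still passes the
  convergence gate comfortably.
* **Convergence gate**: split-$\widehat{R} \le 1.05$ on every $p_k$ and
  $\sigma_j$; on failure chain lengths double, at most twice, then a
  diagnostic error carries the $\widehat{R}$ table. Degenerate
  likelihoods (zero total variance off the mixture mean) return
  $-\infty$ rather than erroring, so the sampler simply rejects.

The TDF sensitivity protocol (`tdf_sensitivity()`) moves one isotope's
TDF at a time to the endpoints 1.6/2.6 ‰ ($\delta^{13}C$) and
2.2/3.2 ‰ ($\delta^{15}N$), holding the TDF SDs at 0.08/0.5 ‰ and
re-using the baseline seed so reported changes are not Monte Carlo
noise. It reports per-source absolute changes in posterior mean
contribution and their grand mean in percentage points.

## Niche metrics

Inputs are territory-year observations: in two-chick territories the
siblings' isotope values are averaged first (`aggregate_siblings()`),
so each territory-year is one point. Conventions we had to fix:

* **SDNND uses the population SD** (denominator $n$). Either convention
  is defensible; this one is applied everywhere, including the
  brute-force oracles.
* **Bootstrap**: $B$ resamples of size $m$ *with replacement*
  ($m$ defaults to the smallest population-year, e.g. 12 territories in
  the full design), one shared resample per replicate for all four
  metrics, mean over replicates. A `replace = FALSE` flag provides the
  subsampling convention since the reference procedure is ambiguous.
* **Standard ellipse**: $SEA = \pi\sqrt{\det \hat\Sigma}$ with the
  $n-1$ covariance; $SEA_c = SEA\,(n-1)/(n-2)$, requiring $n \ge 3$ and
  a non-singular covariance (collinear clouds raise a
  degenerate-geometry error). The ellipse boundary is at squared
  Mahalanobis distance 1 (semi-axes = principal SDs), which contains
  $1 - e^{-1/2} \approx 39.4\%$ of bivariate normal data — the "core"
  roughly-40% niche. The radius is a parameter of
  `ellipse_containment()` for other conventions.

## Diet indices and rank correlations

$H' = -\sum_k p_k \ln p_k$ uses the natural log, making the ceiling
$\ln 8 \approx 2.079$ for eight categories — consistent with observed
territory-level diversity ceilings in this system.
$PS_i = 1 - \frac{1}{2}\sum_k |p_{ik} - q_k|$ uses the full-population
mean diet $q$ by default; a leave-one-out option excludes the focal
territory (not used in the headline pipeline, since a single territory
barely moves a 70-territory mean). Both indices are computed on
**posterior mean** diet vectors; a per-draw variant would propagate
mixing uncertainty but is out of scope for the headline analysis.

`spearman_test()` computes $\rho$ as the Pearson correlation of
mid-ranks and a two-sided $p$ by full $n!$ enumeration for $n \le 9$
(ties included naturally), else by the $t$ approximation with $n - 2$
df. Zero rank variance yields a missing $\rho$ with a warning rather
than an error, because constant diet shares are a legitimate screen
outcome.

## Fitness models

Productivity of successful pairs — the probability of fledging two
chicks instead of one — is a binomial-logit GLMM with territory and
year-within-population (population × year) random intercepts, fitted by
Laplace approximation (lme4; the two factors are crossed, ruling out
adaptive quadrature). The candidate set is fixed at 15 models; pair age
and mate replacement appear in all of them, quadratic terms only with
their linear term, the interaction only with both mains.

* Continuous predictors are standardised before fitting and quadratics
  built from the standardised values, stabilising the quadratic and
  interaction fits.
* $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ = fixed coefficients
  + 2 variance components and $n$ = territory-year observations. Both
  accounting choices had to be fixed by us; they are stated here so the
  ranking is reproducible.
* $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{terr} +
  \sigma^2_{year:pop} + \pi^2/3)$ with $\sigma^2_f$ the variance of the
  fixed-effect linear predictor; $R^2_c$ adds the random variances to
  the numerator (latent-scale, logit distribution-specific variance
  $\pi^2/3$).

Population-scale inference is deliberately non-parametric: Spearman
correlations of mean productivity against $SEA_c$ and $SDNND_b$ across
population-years, using the exact small-$n$ permutation $p$-values
(seven population-years in the full design).

## The synthetic study generator

`scenario_config()` defaults define the emulated study: seven
population-years with 20, 12, 20, 17, 25, 24 and 12 territories, eight
prey categories, TDFs 2.1 ± 0.08 / 2.7 ± 0.5 ‰, and a binary
productivity model driven by pair age, mate replacement, $PS_i$
(quadratic) and $H'$.

* **Source geometry is invented** (stated per-category prey values are
  not available in machine-readable form), and lives entirely in the
  config. The eight TDF-shifted means are placed so that the mixing
  polygon is non-degenerate, encloses the observed consumer envelope
  ($\delta^{13}C \in [-24.85, -19.26]$,
  $\delta^{15}N \in [2.34, 11.03]$ ‰) and puts the corn-fed dovecote
  pigeon category at the carbon-rich extreme, reproducing the
  crop/dovecote bimodality that motivates the pigeon split.
* **Diet regimes**: territory diets are Dirichlet draws. The
  Andalusia-like population-year uses a large concentration (60) around
  a rabbit/partridge-rich mean ("tight"); the others use concentration
  12 ("spread"), with 15% of territories drawn around a specialist mean
  concentrated on preferred prey. These values were chosen once so that
  simulated $H'$ and $PS_i$ overlap the observed territory-level ranges
  ([1.23, 2.08] and [0.62, 0.97]) and Dirichlet dispersion mimics the
  reported among-territory variation.
* **Feathers** are drawn from exactly the mixing model's likelihood
  (residual SDs 0.3/0.4 ‰), with siblings conditionally independent
  given the territory's true diet — their similarity emerges from the
  shared diet, which suffices to reproduce the "similar sibling values"
  pattern without an extra shared noise term.
* **Breeding outcomes** come from the logistic model with configured
  coefficients (centering constants $PS_0 = 0.85$, $H'_0 = 1.8$ keep
  the defaults interpretable) and random intercept SDs 0.3.

What the generator does **not** emulate: spatial prey-availability
structure, temporal autocorrelation or individual turnover beyond a
Bernoulli replacement flag, unsuccessful breeding attempts (the
breeding table contains successful pairs only, so whole-population
productivity is not simulated), measurement drift, or non-normal source
distributions. Passing recovery tests therefore demonstrates internal
consistency of the estimators under the model's own assumptions — not
robustness to the many ways real field data violate them.

## Data handling decisions

* Domestic pigeons arrive as one category and are split on
  $\delta^{13}C$ by a deterministic 1-D 2-means clustering (centers
  initialised at the range extremes), the low-carbon cluster becoming
  the crop-foraging group; a fixed threshold can override the
  clustering. No constant is invented where the data are bimodal.
* Missing or unparseable isotope values are rejected with row-level
  errors, never imputed: the analysis is defined on complete pairs.
* CSVs are comma-separated UTF-8 with `.` decimals and lower-snake
  headers; report tables round to 1 decimal (percentages) or 2–3
  decimals (metrics), with raw-precision companions always written.

## Problem sizes and limitations

The test suite validates estimators at reduced sizes chosen as the
smallest that still separate correct from incorrect behaviour: mixing
fits on 1–2 consumers with 5,000–12,000 retained draws, recovery over
50 replicate territories, GLMM recovery over 50 replicates of 200
territories, bootstrap self-consistency at $B$ = 4,000. The acceptance
script fits 50 mixing models (10 territories × 5 TDF settings).

Known limitations: per-territory fits with two consumers are strongly
prior-influenced (wide credible intervals are the honest output);
Akaike-weight rankings on ~70 observations rarely separate neighbouring
models decisively; Wald intervals from Laplace-approximate binomial
GLMMs undercover slightly when random-effect variances are near zero;
and the pigeon 2-means split assumes genuine bimodality — unimodal
pigeon samples will still be split somewhere in the middle.
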