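# isoniche

Stable-isotope trophic ecology of territorial raptors: from nestling
feather δ¹³C/δ¹⁵N values to Bayesian diet apportionment, isotopic niche
metrics, diet diversity/specificity indices, and diet–fitness models —
with a synthetic study generator so every stage can be validated against
known ground truth.

## Who this is for

Ecologists analysing predator diets from stable isotopes at two spatial
scales:

* **territory scale** — what did the nestlings in each breeding
  territory eat, how diverse was that diet, and did it predict whether
  the pair fledged one chick or two?
* **population scale** — how wide and how evenly structured is the
  population's isotopic niche, and does niche structure correlate with
  mean productivity across population-years?

## The models

**Mixing model (SIAR-class).** A consumer's isotope pair is a
proportion-weighted mixture of K = 8 prey source distributions, after
adding trophic discrimination factors (TDFs) λ to the source means:

    X_ij ~ Normal( Σ_k p_k (μ_jk + λ_j),
                   Σ_k p_k² (ω_jk² + τ_j²) + σ_j² )

with diet proportions **p** on the simplex under a Dirichlet prior and
uniform priors on the residual SDs σ_j. Sampling is by random-walk
Metropolis on log-ratio-transformed proportions, with split-R̂
convergence gating. TDF defaults are 2.1 ± 0.08 ‰ (δ¹³C) and
2.7 ± 0.5 ‰ (δ¹⁵N), and `tdf_sensitivity()` refits at shifted TDF
endpoints (1.6–2.6 ‰ and 2.2–3.2 ‰) to quantify how much the posterior
mean diet depends on them.

**Niche metrics.** Per population-year: isotopic ranges CR and NR, mean
distance to centroid CD, SD of nearest-neighbour distances SDNND (all
bootstrapped at a fixed resample size so unequal samples are
comparable), and the small-sample corrected standard ellipse area
SEAc = π √det(Σ̂) · (n−1)/(n−2).

**Diet indices.** Shannon diversity H′ = −Σ p ln p and proportional
similarity PSᵢ = 1 − ½ Σ |p_ik − q_k| against the population mean diet
q, plus a Spearman screen relating each prey category's consumption to
H′ (preferred prey correlate negatively).

**Fitness models.** P(two fledglings | successful pair) is modelled by
15 binomial-logit GLMMs (lme4, Laplace) with territory and
year-within-population random intercepts, ranked by AICc with Akaike
weights and Nakagawa–Schielzeth marginal/conditional R².

## Worked example

```r
library(isoniche)

cfg <- scenario_config()            # 7 population-years, 8 sources
sim <- simulate_study(cfg, seed = 1)

obs <- aggregate_siblings(sim$consumers)
niche_metrics(obs, B = 1000, seed = 1)
#>   population year mean_d13c mean_d15n cr_b nr_b  cd_b sdnnd_b   sea sea_c  n
#> 1  Andalusia 2011     -22.8      5.25 1.15 2.18 0.674   0.266 0.919  1.01 12
#> 2  Catalonia 2008     -22.4      6.25 2.50 5.09 1.473   0.516 3.275  3.46 20
#> 3  Catalonia 2009     -22.6      5.45 3.39 4.61 1.633   0.576 5.451  5.81 17
#> ...
```

The tight-diet (Andalusia-like) population-year shows by far the
smallest ellipse (SEAc ≈ 1.0 ‰² vs ≈ 3.5–6.8 ‰² elsewhere) and the
lowest CD/SDNND: homogeneous territory diets compress the isotopic
niche.

```r
one <- dplyr::filter(sim$consumers, population == "Andalusia",
                     territory == "T01")
fit <- fit_mixing_model(
  mixing_spec(one, sim$sources, burn_in = 2000, n_samples = 8000,
              thin = 10),
  seed = 1)
tidy(fit)
#> # A tibble: 8 × 7
#>   category  mean     sd    q025  q975  rhat n_eff
#> 1 OC       0.141 0.115  0.00386 0.419 1.00   333.
#> 2 AR       0.163 0.119  0.00502 0.427 1.00   463.
#> ...
glance(fit)
#>   n_sources n_consumers chains draws max_rhat min_n_eff extensions_used
#> 1         8           2      2  1600     1.02      295.               0
```

With two chicks per territory the posterior is wide — the per-source
means (each with its 95% credible interval) still sum to 1 exactly, and
`max_rhat ≤ 1.05` certifies convergence. `run_pipeline(out_dir)` chains
all stages and writes the three report tables plus the TDF sensitivity
summary; `autoplot()` methods give quick-look graphics.

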