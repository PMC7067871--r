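# dioecia

Spatial population genetics for mapped dioecious tree stands.

Tropical dioecious trees are obligate outcrossers whose genes move twice —
as pollen between sexed adults and as seeds away from mothers. How far
those movements reach, and whether recruitment near parents is suppressed
(the Janzen–Connell effect), together set the fine-scale spatial genetic
structure (FSGS) of the stand. `dioecia` packages the full analysis chain
for a single mapped, sexed and genotyped population inside a rectangular
plot, for ecologists and population geneticists working with codominant
(microsatellite-style) markers:

- **Demography** — per-cohort sex-ratio G-tests (`G = 2 Σ O ln(O/E)`), the
  replicated-G heterogeneity decomposition `Σ G_i = G_pooled + G_het`, and
  Kolmogorov–Smirnov comparison of male vs female size distributions.
- **Diversity** — `Na`, rarefied allelic richness `Ar(g)`, `Ho`, unbiased
  `He = n/(n−1)(1 − Σ p_a²)`, fixation index `F = 1 − Ho/He` with a
  bootstrap-over-loci confidence interval.
- **FSGS** — pairwise Loiselle kinship
  `F_ij = Σ_l [Σ_a (x_ia−p_a)(x_ja−p_a) + Σ_a p_a(1−p_a)/(n_l−1)] / Σ_l Σ_a p_a(1−p_a)`,
  distance-class autocorrelograms with genotype-permutation envelopes, the
  regression of `F_ij` on `ln d_ij` (jackknife-over-loci SE, permutation
  p), the intensity statistic `Sp = −b_log / (1 − F_(1))`, and a
  between-cohort correlogram for parent–offspring proximity.
- **Spatial interaction** — bivariate Ripley `K12(t)` with the isotropic
  rectangle edge correction, `L12(t) = √(K12/π) − t`, and random-labeling
  envelopes (association where `L12` exceeds the upper envelope).
- **Parentage** — exclusion probabilities by exhaustive enumeration,
  likelihood paternity and parent-pair assignment under an explicit
  genotyping-error model (`P(g_o|parents) = (1−ε) P_Mendel + ε P_HWE`),
  with simulation-calibrated 95%/80% confidence tiers and the
  mother–offspring mismatch estimator of ε.
- **Dispersal** — effective vs realized pollen and seed kernels, band
  proportions, kernel comparison (KS + directional verdict) as a
  Janzen–Connell probe, and progeny-count fitness regressions.
- **Simulator** — a spatially explicit forward generator of a dioecious
  stand (exponential pollen/seed kernels, logistic distance-dependent
  survival around each parent, genotyping error and missingness) with the
  full pedigree and dispersal truth recorded, used as the recovery oracle
  throughout the test suite.

## Worked example

```r
library(dioecia)
p <- sim_params(n_adults = 210, n_seeds = 500, rng_seed = 7)
adults <- simulate_adults(p)
run <- simulate_progeny(adults, p)   # seeds + pedigree/dispersal truth

demography_summary(adults)$tests
#>   cohort proportion_male     G df        p
#> 1     II           0.629  7.85  1 5.09e-03
#> 2    III           0.702 15.81  1 7.00e-05
#> 3 pooled           0.662 22.42  1 2.19e-06

sp_summary(adults, n_perm = 999, rng_seed = 7)
#> FSGS: b_log = 0.00000 (SE 0.00064, perm p = 0.956), F(1) = -0.0013, Sp = -0.0000
#>   lower upper mean_kinship n_pairs env_lower env_upper     p
#> 1     0    20   -0.0012674      93 -0.014923  0.020142 0.700
#> 2    20    40    0.0113771     277 -0.006932  0.013054 0.094
#> ...
```

The sex ratio is male-biased in every cohort (G-tests, p < 0.01), while the
kinship correlogram of this panmictic simulated stand stays inside its 95%
permutation envelope everywhere and Sp ≈ 0 — no FSGS, as constructed.

The Janzen–Connell probe compares a kernel before and after
distance-dependent thinning. For the seed kernel of the same run:

```r
tr <- run$truth
cmp <- compare_kernels(tr$seed_dist, tr$seed_dist[tr$survived])
cmp$bands
#>     band prop_a prop_b   delta
#> 1 <=150m  0.764  0.217 -0.5466
#> 2 <=600m  0.234  0.772  0.5377
#> 3  >600m  0.002  0.011  0.0089
cmp$verdict
#> [1] "b larger"
```

Only 92 of 500 seeds survive thinning, and the surviving (realized) kernel
has lost most of its ≤150 m mass to the 150–600 m band — the
recruitment-curve signature that distance-dependent mortality leaves on
gene flow. Parentage assignment recovers such kernels from genotypes
alone: with the default 0.0923 genotyping-error model, 70 of 92 simulated
seedlings are assigned a parent pair (44 at the 95% tier) and the assigned
seed-dispersal kernel has median 209 m against a true survivor median
within the same band.

See `vignettes/dioecia-methods.Rmd` for the estimators, permutation
conventions, simulator assumptions and their rationale.

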