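---
title: "Methods: spatial population genetics of a dioecious tree stand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial population genetics of a dioecious tree stand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioecia)
```

`dioecia` analyses a mapped, sexed and genotyped population of a dioecious
tree inside a rectangular plot. Its pipeline runs from demographic tests
(sex ratios by size class), through genetic diversity and fine-scale
spatial genetic structure (FSGS), to bivariate spatial interaction,
likelihood parentage and dispersal-kernel comparison — the last being a
genetic probe for distance-dependent (Janzen–Connell) recruitment. A
forward simulator with a known pedigree provides the ground truth against
which every stage is validated.

## Data model

A `population()` is a table of individuals (`id`, planar coordinates in
meters, `dbh` in cm, `sex` in male/female/undetermined, `cohort`) plus a
three-dimensional genotype array (individuals x loci x 2 alleles) and the
plot rectangle. Genotypes are unordered pairs of integer allele labels;
comparisons are label equality only, so labels may be fragment sizes or
arbitrary bin codes. A locus call with either allele missing is treated as
wholly missing at that locus and is excluded pairwise from every estimator
— never imputed.

Diametric cohorts default to I = [0, 10) cm, II = [10, 20] cm,
III = (20, `Inf`) cm. Field protocols rarely state how exact-boundary stems
were classified, so the convention is explicit and configurable
(`assign_size_class(dbh, breaks = )`).

## Sex ratios and size structure

Deviations from a 1:1 sex ratio use the goodness-of-fit G-test,
`G = 2 * sum(O * ln(O/E))` with equal expected counts and the convention
`0 * ln 0 = 0`. Heterogeneity among cohorts uses the replicated-G
decomposition `sum(G_i) = G_pooled + G_het` with `k - 1` degrees of
freedom; the additivity holds exactly on every input and is tested as an
invariant. Undetermined-sex individuals never enter ratio tests. Size
distributions between sexes are compared by the two-sample
Kolmogorov–Smirnov test with the asymptotic p-value; cm-resolution dbh
produces ties, so that p is approximate (an exact small-sample version is
out of scope).

## Diversity estimators

Per locus: `Na` (observed allele count), `Ho` (heterozygote fraction among
complete genotypes), unbiased expected heterozygosity
`He = n/(n-1) * (1 - sum(p_a^2))` with `n` the gene count, and the fixation
index `F = 1 - Ho/He` (undefined at monomorphic loci, which are excluded
from multilocus means). The multilocus `F` is the ratio of means,
`1 - mean(Ho)/mean(He)`, which weights loci by their heterozygosity rather
than averaging unstable per-locus ratios. Allelic richness uses rarefaction
to a common gene-sample size `g`,
`Ar(g) = sum_a [1 - C(N - N_a, g)/C(N, g)]`, with `g` defaulting to the
smallest per-locus gene count, the standard choice when cohorts differ in
size. Confidence intervals for `F` come from a percentile bootstrap over
loci; with the typical nine microsatellites such intervals are expectedly a
little anticonservative (coverage of zero about 93% in our Hardy–Weinberg
simulations).

## Kinship and FSGS

Pairwise kinship uses the allele-frequency–centred estimator of Loiselle
and colleagues. For locus `l` with allele dosages `x_ia` in {0, 0.5, 1} and
reference frequencies `p_a` estimated from `n_l` individuals,

    F_ij,l = [ sum_a (x_ia - p_a)(x_ja - p_a) + sum_a p_a(1-p_a)/(n_l - 1) ]
             / sum_a p_a (1 - p_a)

and the multilocus value averages loci with weights
`w_l = sum_a p_a(1-p_a)`, dropping a locus for any pair missing it.
Monomorphic loci carry zero weight. This estimator is robust to the modest
allele-frequency skew of microsatellite panels and is the customary
companion of the Sp framework.

One numerical property worth knowing: the bias-correction term
`p(1-p)/(n-1)` (with `n` counted in individuals) slightly overcorrects the
`-p(1-p)/(2n)` sampling covariance of dosages against the estimated
frequencies, so the all-pair mean under panmixia sits near `+1/(2n)` rather
than exactly at zero (about +0.005 at n = 100 in our simulations). All
inference in the package is rank-based against genotype permutations, so
this offset cancels and affects nothing downstream.

The autocorrelogram averages `F_ij` in half-open distance classes
`(lower, upper]`; the defaults (20 m classes to 100 m, then 25 m classes to
200 m) reflect common survey design in plots of roughly 1000 x 300 m and
keep >100 pairs per class at survey scale. The null distribution permutes
the genotype-to-location assignment. Envelopes are order statistics: with
`k = floor(0.025 (n_perm + 1))`, the band between the k-th smallest and
k-th largest null class mean is outside-crossed by a null-consistent
observation with probability exactly `2k/(n_perm + 1)` (5.0% at
`n_perm = 199` or 999). Permutation p-values are two-sided ranks with the
observed value included. The regression of `F_ij` on `ln d_ij` runs over
all pairs, not class means; co-located pairs are excluded with a warning
(ln 0), and a distance cap is available. Slope uncertainty comes from a
delete-one-locus jackknife; significance from the same permutation null.
The FSGS intensity statistic is `Sp = -b_log / (1 - F1)` where `F1` is the
first-class mean kinship — the package computes it only through this
identity, so the definitional test holds to machine precision.

The between-cohort analysis restricts pairs to one member from each cohort
(seedlings against large adults probes parent–offspring proximity:
a parent–offspring pair has kinship near 0.25 under this estimator's
scaling). Reference frequencies come from the union of the two cohorts and
the permutation null shuffles locations within the union, cohort labels
travelling with genotypes. Whether per-cohort FSGS should reference the
cohort's own frequencies or the whole stand is genuinely open; the default
is the analyzed cohort (`reference =` overrides).

## Bivariate spatial interaction

Ripley's bivariate `K12` with the isotropic edge correction for a
rectangular window:

    K12(t) = |A| / (n1 n2) * sum_{i in 1} sum_{j in 2} 1(d_ij <= t) / c_ij

where `c_ij` is the fraction of the circle centred on point `i` with
radius `d_ij` lying inside the rectangle (each crossed edge removes an arc
`2 acos(d_e/r)`; adjacent-edge overlaps `acos(d_1/r) + acos(d_2/r) - pi/2`
are added back). The transformation `L12(t) = sqrt(K12/pi) - t` is centred
at zero under independence, so association reads as `L12 > 0` and repulsion
as `L12 < 0`. Distances are valid up to half the shorter window side; the
default grid is 5–150 m in 5 m steps. The estimator centres circles on
class-1 points; a symmetrized average of both directions is available by
flag (`symmetrized = TRUE`), and the class-exchange test in the suite uses
it. The null model is random labeling — pooled locations held fixed, class
labels reassigned — with the same order-statistic envelope convention as
the correlograms. Monte Carlo validation: the mean of `K12` under complete
spatial randomness (200 replicates, two classes of 200 points in a
1000 x 300 m window) is within 0.5% of `pi t^2` at t = 25 and 50 m.

## Parentage

The observation model is a single-parameter genotyping-error process: with
probability `eps`, independently per individual and locus, the recorded
genotype is an unrelated Hardy–Weinberg draw at the reference frequencies.
The simulator injects exactly this process, so the likelihood and the
generative model match. `eps` is estimated in the field manner from
mother–offspring duos as the fraction of co-typed locus comparisons where
the offspring shares no maternal allele.

Single-locus transition probability:
`P(g_o | g_m, g_f) = (1 - eps) P_Mendel(g_o | g_m, g_f) + eps P_HWE(g_o)`;
missing genotypes contribute likelihood 1. Paternity with a known mother
scores each candidate by the multilocus LOD against a random-father
baseline; parent-pair assignment scores every (female, male) pair against
`P_HWE(g_o)`. Dioecy resolves the parent roles. The best candidate (or
pair) is assigned when its LOD reaches a confidence tier; tiers are
calibrated by simulation — offspring generated with the true father (pair)
inside the candidate pool with probability 0.5 and outside otherwise, at
the same `eps` — as the smallest LOD cutoffs delivering at least 95% and
80% correct assignments above the cutoff. These tiers are a transparent
stand-in for the opaque posterior confidence of full-likelihood sibship
software: pairwise-likelihood categorical assignment is deliberately chosen
over sibship reconstruction, trading a little power for an exactly matched
generative model and testability. Near-ties (best LODs within 1e-9) are
left unassigned rather than resolved arbitrarily; with `eps = 0` a unique
Mendelian-compatible candidate is assigned outright, which makes the
likelihood and exclusion verdicts coincide exactly.

Exclusion probabilities (single parent, second-parent-given-mother, parent
pair) are computed by exhaustive enumeration over per-locus genotype
configurations under Hardy–Weinberg — no closed-form approximations — and
combine across loci as `1 - prod(1 - Q_l)`; the suite checks them to 1e-12
against an independent allele-tuple enumeration.

## Dispersal kernels and the Janzen–Connell probe

Three samples with fixed distance definitions: effective pollen
(mother–father distance from paternity on embryos), realized pollen
(mother–father distance from parent-pair assignment on established
seedlings) and realized seed (offspring–mother distance). Band proportions
default to breaks at 150 and 600 m. Kernel comparison adds a two-sample KS
statistic — an extension beyond the descriptive band proportions — plus a
directional verdict from the band-wise ECDF ordering. Unassigned offspring
are always counted alongside a kernel, since they usually mean a parent
outside the plot. Progeny counts per adult feed ordinary least-squares
fitness screens against dbh or distance.

## The simulator

`sim_params()` defaults describe the study system the package targets: a
30-ha (1000 x 300 m) plot with 210 reproductive adults (the two larger
diametric cohorts of a ~354-tree stand), male-biased sex expression
(P(male) = 0.6), nine microsatellite loci with seven alleles each
(flat-Dirichlet founder frequencies give expected heterozygosity centred
near 0.75 with wide spread), Hardy–Weinberg founder genotypes, exponential
pollen and seed kernels with 200 m means (realized means inside the
truncating window land near the ~300 m scale typical of vertebrate- and
insect-mediated dispersal in such stands), logistic distance-dependent
survival with half-distance 150 m and slope scale 30 m, genotyping error
0.0923 and 2% missing calls. Mothers are uniform among females; fathers
are drawn with weight `exp(-d/pollen_kernel_mean)`; seed displacement has
exponential length and uniform direction, redrawn until inside the window
so the realized kernel is window-truncated exactly as a field plot
truncates observation.

Survival is `s(d_mother) * s(d_father)` with
`s(d) = 1/(1 + exp(-(d - jc_d50)/jc_slope))`, distances taken from the
deposition point to each parent: each parent is an independent source of
distance-dependent mortality. We considered the alternative of thinning on
the distance to the *nearest* parent, but it cannot express the phenomenon
the probe exists to detect: as the pollen distance shrinks the father
co-locates with the mother and adds no extra mortality, making the
survival weight non-monotone in pollen distance (equal at zero and at
infinity). The multiplicative escape model is monotone in both parental
distances, so thinning contracts the short-distance band of both the
pollen and the seed kernel — the recruitment-curve signature the
effective/realized comparison is designed to reveal.

The generator does not model overlapping generations, growth, mutation,
selfing (the species is dioecious), polyploidy, null alleles, aggregated
adult placement or temporal variation in flowering. Passing tests
therefore validate the estimators and their inference machinery, not the
realism of any particular field system; in real data, clumped recruitment,
undetected null alleles or out-of-plot gene flow can move every statistic.

## Numerical conventions and test scale

Tie-breaks and tolerances: LOD near-ties at 1e-9; allele-frequency sums
validated to 1e-12; envelopes and p-values use the order-statistic and
+1-rank conventions above, which make permutation tests exact at any
`n_perm`. Degenerate inputs fail loudly (empty distance classes, zero
co-typed comparisons, monomorphic-only panels, out-of-window coordinates),
never silently.

The validation suite runs on one CPU in well under a minute of simulation
per property: 400 replicate stands of 120 adults for the envelope type-I
rate (5% +- 2%), 200 CSR point patterns for K12 unbiasedness (within 5% of
`pi t^2`), 500 simulated offspring against 100 candidate fathers for
paternity recovery (>= 95% correct at the 95% tier), 20 replicate runs of
5000 seeds for the Janzen–Connell band contraction (>= 18 of 20), and 50
random mini-populations for exact agreement with the brute-force kinship
oracle. These sizes were chosen so each Monte Carlo bound has comfortable
margin while the whole suite stays quick to run routinely.

```{r example, eval = FALSE}
# a complete miniature analysis
p <- sim_params(n_adults = 150, n_seeds = 400, rng_seed = 7)
adults <- simulate_adults(p)
run <- simulate_progeny(adults, p)
seedlings <- realized_offspring(run$offspring, run$truth)

demography_summary(adults)$tests
diversity_by_cohort(adults, B = 1000, rng_seed = 7)
sp_summary(adults, n_perm = 999, rng_seed = 7)

obs <- apply_genotyping_error(seedlings, 0.0923, 0.02, rng_seed = 8)
asn <- assign_parent_pair(obs, adults, error_rate = 0.0923, rng_seed = 9)
compare_kernels(run$truth$pollen_dist,
                dispersal_distances(asn, "realized_pollen"))
```

## Known limitations

Single population, single generation, planar rectangular windows only.
The KS p-values are asymptotic. The confidence tiers are calibrated against
a two-point prior (parent fully inside or fully outside the pool) and carry
that prior's assumptions. Exact reproduction of any particular field
study's tables is not attempted: the acceptance layer instead checks
published desk arithmetic exactly and everything else as properties with
known ground truth.
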