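#' Reference allele frequencies per locus
#'
#' Counts both alleles of every complete genotype. A genotype with either
#' allele missing is wholly excluded at that locus (never imputed), so the
#' gene count `n_genes` is always even.
#'
#' @param pop a genotyped [population()].
#' @return object of class `"allele_freqs"`: per locus a list with `freq`
#'   (named relative frequencies) and `n_genes`.
#' @export
allele_frequencies <- function(pop) {
  if (is.null(pop$geno)) stopf("population is not genotyped")
  loci <- lapply(seq_along(pop$loci), function(l) {
    a1 <- pop$geno[, l, 1]; a2 <- pop$geno[, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) stopf("locus %s has zero complete genotypes", pop$loci[l])
    cnt <- table(c(a1[ok], a2[ok]))
    list(freq = cnt / sum(cnt), n_genes = 2L * sum(ok))
  })
  names(loci) <- pop$loci
  structure(list(loci = loci), class = "allele_freqs")
}

#' Per-locus and mean genetic diversity (Na, Ho, He, F)
#'
#' `Na` is the observed allele count; `Ho` the fraction of heterozygotes
#' among complete genotypes; `He` the unbiased expected heterozygosity
#' `n/(n-1) * (1 - sum(p^2))` with `n` the gene count; `F = 1 - Ho/He`
#' per locus (undefined at monomorphic loci, which are excluded from the
#' means). The multilocus fixation index is the ratio of means,
#' `1 - mean(Ho)/mean(He)` over polymorphic loci.
#'
#' @param pop a genotyped [population()] with >= 2 individuals.
#' @return list: `per_locus` data.frame and `mean` (named vector with
#'   `Na`, `Ho`, `He`, `F`, `n` = individuals).
#' @export
diversity_summary <- function(pop) {
  if (n_individuals(pop) < 2) stopf("need at least two individuals")
  fr <- allele_frequencies(pop)
  rows <- lapply(seq_along(pop$loci), function(l) {
    a1 <- pop$geno[, l, 1]; a2 <- pop$geno[, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    f <- fr$loci[[l]]
    n_genes <- f$n_genes
    Na <- length(f$freq)
    Ho <- mean(a1[ok] != a2[ok])
    He <- if (Na > 1) n_genes / (n_genes - 1) * (1 - sum(f$freq^2)) else 0
    Fl <- if (He > 0) 1 - Ho / He else NA_real_
    data.frame(locus = pop$loci[l], n = sum(ok), Na = Na, Ho = Ho, He = He,
               F = Fl, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  poly <- per$He > 0
  mF <- if (any(poly)) 1 - mean(per$Ho[poly]) / mean(per$He[poly]) else NA_real_
  list(per_locus = per,
       mean = c(Na = mean(per$Na), Ho = mean(per$Ho), He = mean(per$He),
                F = mF, n = n_individuals(pop)))
}

# rarefied allele count at gene-sample size g for one vector of allele counts
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  stopifnot(g >= 1, g <= N)
  # P(allele absent from a g-subsample) = C(N - N_a, g) / C(N, g)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `Ar(g) = sum_a [1 - C(N - N_a, g)/C(N, g)]`. Standardizing `g`
#' to the smallest per-locus gene count makes cohorts of unequal size
#' comparable.
#'
#' @param pop a genotyped [population()].
#' @param g rarefaction gene count; default = the minimum `n_genes` over
#'   loci.
#' @return list: `per_locus` named vector, `mean`, `g`.
#' @export
allelic_richness <- function(pop, g = NULL) {
  fr <- allele_frequencies(pop)
  n_genes <- vapply(fr$loci, `[[`, integer(1), "n_genes")
  g <- g %||% min(n_genes)
  if (g > min(n_genes)) stopf("g exceeds the gene count of locus %s",
                              names(which.min(n_genes)))
  ar <- vapply(fr$loci, function(f) {
    rarefied_richness(round(f$freq * f$n_genes), g)
  }, numeric(1))
  list(per_locus = ar, mean = mean(ar), g = g)
}

#' Bootstrap confidence interval for the multilocus fixation index
#'
#' Resamples loci with replacement `B` times, recomputes the multilocus
#' `F` (ratio of mean Ho to mean He over the resampled polymorphic loci)
#' and returns the 2.5/97.5 percentile interval.
#'
#' @param pop a genotyped [population()] with >= 2 polymorphic loci.
#' @param B bootstrap replicates (>= 100).
#' @param rng_seed integer seed.
#' @return list: `F_hat`, `lower`, `upper`, `B`.
#' @export
bootstrap_F_ci <- function(pop, B = 1000, rng_seed = NULL) {
  stopifnot(B >= 100)
  ds <- diversity_summary(pop)
  per <- ds$per_locus[ds$per_locus$He > 0, ]
  if (nrow(per) < 2) stopf("need at least two polymorphic loci")
  with_seed(rng_seed, {
    boot <- vapply(seq_len(B), function(b) {
      i <- sample.int(nrow(per), replace = TRUE)
      1 - mean(per$Ho[i]) / mean(per$He[i])
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    list(F_hat = unname(ds$mean["F"]), lower = ci[1], upper = ci[2], B = B)
  })
}

#' Table-style per-cohort diversity summary
#'
#' @param pop a genotyped [population()] with cohorts assigned.
#' @param B bootstrap replicates for the F interval (0 to skip).
#' @param rng_seed integer seed.
#' @return data.frame: one row per cohort with N, Na, Ar, Ho, He, F and the
#'   bootstrap CI bounds.
#' @export
diversity_by_cohort <- function(pop, B = 1000, rng_seed = NULL) {
  cohorts <- intersect(c("I", "II", "III"), unique(pop$ind$cohort))
  rows <- lapply(cohorts, function(co) {
    sub <- subset_population(pop, !is.na(pop$ind$cohort) & pop$ind$cohort == co)
    ds <- diversity_summary(sub)
    ar <- allelic_richness(sub)
    ci <- if (B >= 100) bootstrap_F_ci(sub, B, rng_seed) else
      list(lower = NA_real_, upper = NA_real_)
    data.frame(cohort = co, N = n_individuals(sub), Na = ds$mean["Na"],
               Ar = ar$mean, Ho = ds$mean["Ho"], He = ds$mean["He"],
               F = ds$mean["F"], F_lower = ci$lower, F_upper = ci$upper,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
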