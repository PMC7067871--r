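#' Sex counts per diametric cohort
#'
#' Tabulates males, females and undetermined individuals by cohort.
#' Undetermined individuals are excluded from every ratio test (only sexed
#' trees enter the G-tests) but reported here.
#'
#' @param pop a [population()].
#' @return data.frame with one row per cohort plus a pooled row.
#' @export
sex_counts <- function(pop) {
  coh <- factor(pop$ind$cohort, c("I", "II", "III"))
  sex <- factor(pop$ind$sex, c("male", "female", "undetermined"))
  tab <- table(coh, sex)
  out <- as.data.frame.matrix(tab)
  out <- rbind(out, colSums(out))
  out$cohort <- c(rownames(tab), "pooled")
  rownames(out) <- NULL
  out[c("cohort", "male", "female", "undetermined")]
}

#' Goodness-of-fit G-test for a 1:1 sex ratio
#'
#' `G = 2 * sum(O * ln(O / E))` against equal expected counts, with the
#' convention `0 * ln(0) = 0`; df = 1; p from the upper chi-square tail.
#' For very small counts an exact binomial p is available.
#'
#' @param males,females nonnegative counts; their sum must be positive.
#' @param exact also compute a two-sided exact binomial p-value.
#' @return list: `proportion_male`, `G`, `df`, `p` (and `p_exact` if asked).
#' @export
sex_ratio_gtest <- function(males, females, exact = FALSE) {
  stopifnot(males >= 0, females >= 0)
  n <- males + females
  if (n < 1) stopf("no sexed individuals")
  o <- c(males, females)
  e <- rep(n / 2, 2)
  terms <- ifelse(o == 0, 0, o * log(o / e))
  G <- 2 * sum(terms)
  out <- list(proportion_male = males / n, G = G, df = 1L,
              p = stats::pchisq(G, df = 1, lower.tail = FALSE))
  if (exact) out$p_exact <- stats::binom.test(males, n, 0.5)$p.value
  out
}

#' Heterogeneity G-test of sex ratios across cohorts
#'
#' Replicated-G decomposition: the per-cohort G statistics sum to the
#' pooled-counts G plus a heterogeneity component,
#' `G_het = sum(G_i) - G_pooled`, with `k - 1` degrees of freedom. A large
#' `G_het` means the male proportion differs among cohorts regardless of
#' whether the pooled ratio deviates from 1:1.
#'
#' @param counts matrix or data.frame with columns `male`, `female` and one
#'   row per cohort (k >= 2; every row total positive).
#' @return list: `G_het`, `df`, `p`, plus the per-cohort and pooled tests.
#' @export
g_heterogeneity <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("male", "female") %in% names(counts)))
  k <- nrow(counts)
  if (k < 2) stopf("need at least two cohorts")
  tot <- counts$male + counts$female
  if (any(tot <= 0)) stopf("cohort with zero sexed individuals")
  per <- lapply(seq_len(k), function(i)
    sex_ratio_gtest(counts$male[i], counts$female[i]))
  G_each <- vapply(per, `[[`, numeric(1), "G")
  pooled <- sex_ratio_gtest(sum(counts$male), sum(counts$female))
  G_het <- sum(G_each) - pooled$G
  list(G_het = G_het, df = k - 1L,
       p = stats::pchisq(G_het, df = k - 1, lower.tail = FALSE),
       G_cohorts = G_each, pooled = pooled)
}

#' Two-sample Kolmogorov-Smirnov test on size distributions
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic KS distribution (ties, common with cm-resolution
#' dbh, make it approximate).
#'
#' @param a,b numeric samples (e.g. dbh of males vs females); `NA` dropped.
#' @return list: `D`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Per-cohort sex-ratio summary table for a population
#'
#' Runs the 1:1 G-test within each cohort and pooled, plus the
#' heterogeneity test and a KS comparison of male vs female dbh.
#'
#' @param pop a [population()].
#' @return list: `counts`, `tests` (per-cohort data.frame),
#'   `heterogeneity`, `ks_dbh`.
#' @export
demography_summary <- function(pop) {
  cnt <- sex_counts(pop)
  rows <- cnt[cnt$male + cnt$female > 0 & cnt$cohort != "pooled", ]
  tests <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    g <- sex_ratio_gtest(rows$male[i], rows$female[i])
    data.frame(cohort = rows$cohort[i], proportion_male = g$proportion_male,
               G = g$G, df = g$df, p = g$p, stringsAsFactors = FALSE)
  }))
  pooled <- sex_ratio_gtest(sum(rows$male), sum(rows$female))
  tests <- rbind(tests, data.frame(cohort = "pooled",
                                   proportion_male = pooled$proportion_male,
                                   G = pooled$G, df = pooled$df, p = pooled$p))
  het <- if (nrow(rows) >= 2) g_heterogeneity(rows) else NULL
  m <- pop$ind$sex == "male"; f <- pop$ind$sex == "female"
  ks <- if (any(m & !is.na(pop$ind$dbh)) && any(f & !is.na(pop$ind$dbh))) {
    ks_two_sample(pop$ind$dbh[m], pop$ind$dbh[f])
  }
  list(counts = cnt, tests = tests, heterogeneity = het, ks_dbh = ks)
}
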