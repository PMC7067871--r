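test_that("kinship matches hand values, is symmetric, drops missing loci", {
  # two individuals AA and BB, p = 0.5, n = 2: terms cancel exactly
  pop <- make_pop(list(list(c(1L, 1L)), list(c(2L, 2L))))
  k <- kinship_matrix(pop)
  expect_equal(k$F[1, 2], 0)
  # symmetry and NA diagonal on random data with missingness
  rp <- make_random_pop(n = 15, L = 4, k = 5, miss = 0.2, seed = 4)
  kr <- kinship_matrix(rp)
  expect_identical(kr$F, t(kr$F))
  expect_true(all(is.na(diag(kr$F))))
  # brute-force per-allele oracle agreement
  expect_equal(kr$F, loiselle_oracle(rp), tolerance = 1e-12,
               ignore_attr = TRUE)
  mono <- make_pop(list(list(c(1L, 1L)), list(c(1L, 1L))))
  expect_error(kinship_matrix(mono), "monomorphic")
})

test_that("kinship under HWE randomness has near-zero mean", {
  m <- vapply(1:25, function(s) {
    p <- sim_params(n_adults = 100, rng_seed = 20000 + s, genotyping_error = 0)
    mean(kinship_matrix(simulate_adults(p))$F, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(m)), 1 / 100)
})

test_that("one all-pairs distance class is permutation invariant (p = 1)", {
  rp <- make_random_pop(n = 20, L = 3, k = 4, miss = 0, seed = 6,
                        window = c(50, 50))
  kin <- kinship_matrix(rp)
  d <- pairwise_distances(rp)
  ac <- autocorrelogram(kin, d, classes = max(d) + 1, n_perm = 99,
                        rng_seed = 1)
  expect_equal(ac$p, 1)
  expect_equal(ac$n_pairs, choose(20, 2))
  expect_equal(ac$mean_kinship, mean(kin$F[upper.tri(kin$F)]))
})

test_that("strong isolation by distance lifts the first class above the envelope", {
  hits <- vapply(1:5, function(s) {
    p <- sim_params(n_adults = 60, n_seeds = 250, seed_kernel_mean = 20,
                    pollen_kernel_mean = 20, jc_d50 = -1e6, rng_seed = 700 + s)
    ad <- simulate_adults(p)
    off <- simulate_progeny(ad, p)$offspring
    kin <- kinship_matrix(off)
    d <- pairwise_distances(off)
    ac <- autocorrelogram(kin, d, classes = c(20, 40), n_perm = 199,
                          rng_seed = s)
    ac$mean_kinship[1] > ac$env_upper[1]
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("regression slope matches exact OLS; jackknife needs >= 2 loci", {
  expect_equal(dioecia:::ols_slope(c(0, 1, 2), c(0.1, 0.05, 0)), -0.05)
  expect_equal(dioecia:::ols_slope(1:10, rep(0.3, 10)), 0)  # flat response
  rp <- make_random_pop(n = 25, L = 5, k = 5, miss = 0.1, seed = 13)
  kin <- kinship_matrix(rp)
  d <- pairwise_distances(rp)
  reg <- kinship_log_regression(kin, d, n_perm = 99, rng_seed = 3)
  iu <- upper.tri(d)
  expect_equal(reg$b_log, dioecia:::ols_slope(log(d[iu]), kin$F[iu]))
  expect_gte(reg$se_jackknife, 0)
  expect_true(reg$p_perm > 0 && reg$p_perm <= 1)
  one <- make_random_pop(n = 25, L = 1, k = 5, miss = 0, seed = 14)
  expect_error(kinship_log_regression(kinship_matrix(one),
                                      pairwise_distances(one), n_perm = 99),
               "two polymorphic loci")
})

test_that("co-located pairs are excluded from the regression with a warning", {
  rp <- make_random_pop(n = 10, L = 3, k = 4, miss = 0, seed = 15)
  rp$ind$x[2] <- rp$ind$x[1]; rp$ind$y[2] <- rp$ind$y[1]
  expect_warning(
    kinship_log_regression(kinship_matrix(rp), pairwise_distances(rp),
                           n_perm = 99, rng_seed = 1),
    "co-located")
})

test_that("Sp reproduces published arithmetic and its identity", {
  expect_equal(round(sp_statistic(-0.0121, 0.0531), 4), 0.0128)
  expect_equal(round(sp_statistic(-0.01, 0.0771), 4), 0.0108)
  expect_equal(round(sp_statistic(-0.01, 0.0502), 4), 0.0105)
  expect_equal(sp_statistic(0, 0.5), 0)
  expect_error(sp_statistic(-0.01, 1), "F1")
  # full-pipeline identity: Sp = -b/(1 - F1) to machine precision
  p <- sim_params(n_adults = 70, rng_seed = 303, genotyping_error = 0)
  ad <- simulate_adults(p)
  sp <- sp_summary(ad, classes = c(100, 250, 500), n_perm = 99, rng_seed = 2)
  expect_identical(sp$Sp, -sp$b_log / (1 - sp$F1))
})

test_that("between-cohort correlogram is symmetric in the cohorts and sees parent-offspring structure", {
  p <- sim_params(n_adults = 50, n_seeds = 120, seed_kernel_mean = 1e-9,
                  jc_d50 = -1e6, rng_seed = 801, genotyping_error = 0)
  ad <- simulate_adults(p)
  off <- simulate_progeny(ad, p)$offspring
  cls <- c(20, 100, 400)
  ab <- between_class_autocorrelogram(ad, off, classes = cls, n_perm = 99,
                                      rng_seed = 5)
  ba <- between_class_autocorrelogram(off, ad, classes = cls, n_perm = 99,
                                      rng_seed = 5)
  expect_equal(ab$mean_kinship, ba$mean_kinship, tolerance = 1e-12)
  # seeds drop at the mother: the first class is dominated by
  # parent-offspring pairs, approaching the 0.25 kinship of the estimator
  expect_gt(ab$mean_kinship[1], 0.1)
  all_mean <- mean(kinship_matrix(ad)$F, na.rm = TRUE)
  expect_gt(ab$mean_kinship[1], 5 * abs(all_mean))
  expect_gt(ab$mean_kinship[1], ab$env_upper[1])
  # disjointness is enforced
  expect_error(between_class_autocorrelogram(ad, ad), "disjoint")
})

test_that("default classes keep >100 pairs per class at survey scale", {
  p <- sim_params(n_adults = 354, rng_seed = 99, genotyping_error = 0)
  ad <- simulate_adults(p)
  kin <- kinship_matrix(ad)
  d <- pairwise_distances(ad)
  ac <- autocorrelogram(kin, d, n_perm = 99, rng_seed = 1)
  expect_true(all(ac$n_pairs > 100))
})
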