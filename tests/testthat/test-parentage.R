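test_that("transition probability follows the error-mixture model", {
  p <- c("1" = 0.5, "2" = 0.5)
  # impossible transmission without error; forced heterozygote; mixture
  expect_equal(transition_probability(c(1, 2), c(1, 1), c(1, 1), p, 0), 0)
  expect_equal(transition_probability(c(1, 2), c(1, 1), c(2, 2), p, 0), 1)
  expect_equal(transition_probability(c(1, 2), c(1, 1), c(1, 1), p, 0.0923),
               0.0923 * 0.5)
  # missing genotypes contribute likelihood 1
  expect_equal(transition_probability(c(NA, NA), c(1, 1), c(1, 1), p, 0.1), 1)
  expect_equal(transition_probability(c(1, 1), NULL, c(1, 1), p, 0.1), 1)
  expect_error(transition_probability(c(1, 3), c(1, 1), c(1, 1), p, 0.1),
               "not covered")
})

test_that("exclusion probabilities match exhaustive enumeration", {
  # biallelic p = q = 0.5: known-parent exclusion is exactly 3/16
  f <- freqs_from_list(list(L1 = c("1" = 0.5, "2" = 0.5)))
  ex <- exclusion_probabilities(f)
  expect_equal(ex$per_locus$Q2, 0.1875, tolerance = 1e-12)
  # two such loci combine multiplicatively
  f2 <- freqs_from_list(list(L1 = c("1" = 0.5, "2" = 0.5),
                             L2 = c("1" = 0.5, "2" = 0.5)))
  ex2 <- exclusion_probabilities(f2)
  expect_equal(unname(ex2$combined["Q2"]), 1 - (1 - 0.1875)^2,
               tolerance = 1e-12)
  # monomorphic locus excludes nothing
  exm <- exclusion_probabilities(freqs_from_list(list(L1 = c("7" = 1))))
  expect_equal(unname(unlist(exm$per_locus[c("Q1", "Q2", "Qpair")])),
               c(0, 0, 0))
  # random 2-4 allele loci against the allele-tuple enumeration oracle
  set.seed(17)
  for (k in 2:4) {
    p <- as.numeric(rgamma(k, 1)); p <- p / sum(p)
    names(p) <- seq_len(k)
    got <- exclusion_probabilities(freqs_from_list(list(LX = p)))$per_locus
    want <- exclusion_oracle(p)
    expect_equal(c(got$Q1, got$Q2, got$Qpair), unname(want),
                 tolerance = 1e-12)
  }
  # combined exclusion never decreases as loci are added
  set.seed(18)
  ps <- lapply(1:5, function(i) {
    p <- as.numeric(rgamma(3, 1)); p <- p / sum(p); names(p) <- 1:3; p
  })
  combs <- vapply(1:5, function(m)
    unname(exclusion_probabilities(freqs_from_list(ps[1:m]))$combined["Qpair"]),
    numeric(1))
  expect_true(all(diff(combs) >= 0))
})

test_that("error-free paternity agrees with exclusion logic", {
  set.seed(23)
  adults <- make_hwe_pop(30, L = 6, k = 5, sex = "male")
  mothers <- make_hwe_pop(5, L = 6, k = 5, sex = "female", prefix = "f")
  all_ad <- population(rbind(adults$ind, mothers$ind),
                       dioecia:::abind3(adults$geno, mothers$geno),
                       adults$loci, adults$window)
  fr <- allele_frequencies(all_ad)
  p <- sim_params(n_adults = 35, n_loci = 6, rng_seed = 5, n_seeds = 40,
                  jc_d50 = -1e6, genotyping_error = 0)
  pr <- simulate_progeny(all_ad, p)
  pat <- assign_paternity(pr$offspring, pr$truth$mother, all_ad, fr,
                          error_rate = 0, n_sim = 300, rng_seed = 6)
  # every offspring with a unique compatible male gets exactly that male;
  # no assigned father is Mendelian-incompatible
  assigned <- !is.na(pat$father)
  expect_true(all(pat$mismatch[assigned] == 0))
  expect_gt(mean(pat$father[assigned] == pr$truth$father[assigned]), 0.9)
  # offspring with all loci missing is unassigned
  off1 <- subset_population(pr$offspring, 1)
  off1$geno[] <- NA_integer_
  pat1 <- assign_paternity(off1, pr$truth$mother[1], all_ad, fr,
                           error_rate = 0,
                           thresholds = c("95%" = 0, "80%" = 0))
  expect_true(is.na(pat1$father))
  expect_equal(pat1$tier, "unassigned")
})

test_that("parent-pair assignment recovers simulated pedigrees", {
  p <- sim_params(n_adults = 120, n_seeds = 120, rng_seed = 55,
                  genotyping_error = 0)
  ad <- simulate_adults(p)
  pr <- simulate_progeny(ad, p)
  obs <- apply_genotyping_error(pr$offspring, 0.01, 0, rng_seed = 8)
  fr <- allele_frequencies(ad)
  pp <- assign_parent_pair(obs, ad, fr, error_rate = 0.01, n_sim = 400,
                           rng_seed = 9)
  hi <- pp$tier == "95%"
  expect_gt(sum(hi), 50)
  expect_gte(mean(pp$mother[hi] == pr$truth$mother[hi] &
                  pp$father[hi] == pr$truth$father[hi]), 0.9)
  # assigned parents have the right sexes by construction
  expect_true(all(ad$ind$sex[match(pp$mother[hi], ad$ind$id)] == "female"))
  expect_true(all(ad$ind$sex[match(pp$father[hi], ad$ind$id)] == "male"))
  # derived distances match coordinates
  i <- which(hi)[1]
  mo <- match(pp$mother[i], ad$ind$id); fa <- match(pp$father[i], ad$ind$id)
  expect_equal(pp$pollen_dist[i],
               sqrt((ad$ind$x[mo] - ad$ind$x[fa])^2 +
                    (ad$ind$y[mo] - ad$ind$y[fa])^2))
})

test_that("assignment accuracy degrades with error rate and pool size", {
  accuracy <- function(eps, n_males, seed) {
    set.seed(seed)
    males <- make_hwe_pop(n_males, L = 9, k = 7, sex = "male")
    fem <- make_hwe_pop(10, L = 9, k = 7, sex = "female", prefix = "f")
    ad <- population(rbind(males$ind, fem$ind),
                     dioecia:::abind3(males$geno, fem$geno),
                     males$loci, males$window)
    p <- sim_params(n_adults = n_males + 10, n_loci = 9, n_seeds = 150,
                    jc_d50 = -1e6, rng_seed = seed,
                    genotyping_error = eps)
    pr <- simulate_progeny(ad, p)
    fr <- allele_frequencies(ad)
    obs <- apply_genotyping_error(pr$offspring, eps, 0, rng_seed = seed + 1,
                                  freqs = fr)
    pat <- assign_paternity(obs, pr$truth$mother, ad, fr, error_rate = eps,
                            n_sim = 400, rng_seed = seed + 2)
    mean(!is.na(pat$father) & pat$father == pr$truth$father)
  }
  a0 <- accuracy(0, 50, 100)
  a2 <- accuracy(0.15, 50, 100)
  expect_gte(a0, a2 - 0.02)
  small_pool <- accuracy(0.01, 25, 200)
  big_pool <- accuracy(0.01, 200, 200)
  expect_gte(small_pool, big_pool - 0.02)
})

test_that("mother-offspring mismatch rate estimates epsilon", {
  # 12 mismatching of 130 comparisons reproduces the printed 0.0923 shape:
  # 13 duos x 10 co-typed loci
  m10 <- make_pop(lapply(1:13, function(i) rep(list(c(1L, 2L)), 10)),
                  x = seq(1, 13), y = rep(1, 13))
  o_geno <- lapply(1:13, function(i) rep(list(c(1L, 3L)), 10))
  # 12 mismatching calls: offspring 1 mismatches at 10 loci, offspring 2 at 2
  o_geno[[1]] <- rep(list(c(4L, 5L)), 10)
  o_geno[[2]][1:2] <- list(c(4L, 5L))
  o10 <- make_pop(o_geno, x = seq(1, 13), y = rep(2, 13))
  est <- estimate_genotyping_error(o10, mother_ids = m10$ind$id, m10)
  expect_equal(est$comparisons, 130L)
  expect_equal(est$mismatches, 12L)
  expect_equal(round(est$epsilon, 4), 0.0923)
  # no mismatches -> 0
  same <- estimate_genotyping_error(m10, m10$ind$id, m10)
  expect_equal(same$epsilon, 0)
  # nothing co-typed -> error
  o_missing <- o10
  o_missing$geno[] <- NA_integer_
  expect_error(estimate_genotyping_error(o_missing, m10$ind$id, m10),
               "no co-typed")
})
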