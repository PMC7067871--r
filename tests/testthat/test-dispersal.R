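fake_assignment <- function(father, pollen, seed = NULL, mother = "f1") {
  out <- data.frame(offspring = sprintf("o%d", seq_along(father)),
                    mother = mother, father = father,
                    lod = 1, tier = ifelse(is.na(father), "unassigned", "95%"),
                    mismatch = 0L, pollen_dist = pollen,
                    stringsAsFactors = FALSE)
  if (!is.null(seed)) out$seed_dist <- seed
  class(out) <- c("parentage", "data.frame")
  out
}

test_that("dispersal samples use the mode-specific distance definition", {
  asn <- fake_assignment(father = c("m1", NA, "m2"),
                         pollen = c(50, NA, 120), seed = c(0, NA, 30))
  eff <- dispersal_distances(asn, "effective_pollen")
  expect_equal(eff$distances, c(50, 120))
  expect_equal(eff$n_unassigned, 1)
  seedk <- dispersal_distances(asn, "realized_seed")
  expect_equal(seedk$distances, c(0, 30))
  # 3-4-5: the pollen distance is the mother-father separation
  expect_equal(dispersal_distances(fake_assignment("m1", 50),
                                   "realized_pollen")$distances, 50)
  no_seed <- fake_assignment("m1", 50)
  expect_error(dispersal_distances(no_seed, "realized_seed"), "seed")
})

test_that("band proportions partition the sample", {
  expect_equal(unname(band_proportions(c(100, 200, 700), c(150, 600))),
               c(1, 1, 1) / 3)
  expect_equal(unname(band_proportions(c(10, 20), c(150, 600))), c(1, 0, 0))
  # boundaries: bands are (b_{k-1}, b_k] and distance 0 is in the first band
  expect_equal(unname(band_proportions(c(0, 150, 150.01), c(150, 600))),
               c(2 / 3, 1 / 3, 0))
  set.seed(5)
  d <- rexp(200, 1 / 300)
  expect_equal(sum(band_proportions(d, c(50, 150, 600))), 1)
  expect_error(band_proportions(numeric(0)), "empty")
})

test_that("kernel summary gives the documented statistics", {
  s <- kernel_summary(c(10, 20, 30))
  expect_equal(unname(s["mean"]), 20)
  expect_equal(unname(s["median"]), 20)
  expect_equal(unname(s["se"]), 10 / sqrt(3))
  one <- kernel_summary(42)
  expect_equal(unname(one["mean"]), 42)
  expect_true(is.na(one["se"]))
  rng <- kernel_summary(c(7.2, 833.2))
  expect_equal(unname(rng["min"]), 7.2)
  expect_equal(unname(rng["max"]), 833.2)
  expect_equal(unname(rng["median"]), (7.2 + 833.2) / 2)
})

test_that("kernel comparison detects shifts and reports band deltas", {
  set.seed(6)
  a <- rexp(300, 1 / 200)
  same <- compare_kernels(a, a)
  expect_equal(same$D, 0)
  expect_equal(same$bands$delta, c(0, 0, 0))
  expect_equal(same$verdict, "equal")
  shifted <- compare_kernels(a, a + 100)
  expect_gt(shifted$D, 0)
  expect_equal(shifted$verdict, "b larger")
})

test_that("fitness regression matches exact OLS", {
  lin <- suppressWarnings(fitness_regression(c(2, 4, 6, 8), c(1, 2, 3, 4)))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$slope, 2)
  dec <- suppressWarnings(fitness_regression(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  expect_equal(dec$slope, -1)
  expect_equal(dec$r_squared, 1)
  flat <- fitness_regression(c(3, 3, 3, 3), c(1, 2, 3, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fitness_regression(1:4, rep(2, 4)), "constant")
})

test_that("progeny counts cover all adults including zeros", {
  asn <- fake_assignment(father = c("m1", "m1", "m2", NA),
                         pollen = c(1, 2, 3, NA))
  ind <- data.frame(id = c("m1", "m2", "m3", "f1"), x = 1:4, y = 1:4,
                    sex = c("male", "male", "male", "female"))
  adults <- population(ind, window = c(10, 10))
  cnt <- progeny_counts(asn, adults, "father")
  expect_equal(unname(cnt), c(2L, 1L, 0L, 0L))
})

test_that("assigned kernels track the simulated truth end to end", {
  p <- sim_params(n_adults = 150, n_seeds = 260, rng_seed = 71,
                  jc_d50 = -1e6, genotyping_error = 0)
  ad <- simulate_adults(p)
  pr <- simulate_progeny(ad, p)
  obs <- apply_genotyping_error(pr$offspring, 0.01, 0, rng_seed = 72)
  fr <- allele_frequencies(ad)
  pp <- assign_parent_pair(obs, ad, fr, error_rate = 0.01, n_sim = 400,
                           rng_seed = 73)
  hi <- pp$tier == "95%"
  expect_gt(sum(hi), 200)
  seed_hat <- pp$seed_dist[hi]
  seed_true <- pr$truth$seed_dist
  ks <- suppressWarnings(stats::ks.test(seed_hat, seed_true))
  expect_lte(unname(ks$statistic), 0.1)
  expect_lt(abs(stats::median(seed_hat) / stats::median(seed_true) - 1), 0.15)
})
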