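#' Parameters for the spatially explicit forward simulator
#'
#' Defaults describe a 30-ha (1000 x 300 m) mapped plot of a dioecious,
#' insect-pollinated, vertebrate-dispersed tree: ~210 reproductive adults
#' (the two larger diametric cohorts), a male-biased sex ratio, nine
#' microsatellite loci with about seven alleles each, exponential pollen
#' and seed dispersal kernels with 200 m means, logistic distance-dependent
#' (Janzen-Connell) seedling survival with half-distance 150 m, and a 9.23%
#' genotyping-error rate of the kind estimated from mother-offspring
#' mismatches.
#'
#' @param window plot width and height (m).
#' @param n_adults number of adults (>= 2, both sexes required after
#'   assignment).
#' @param sex_ratio probability that an adult is male (must leave a positive
#'   chance of both sexes).
#' @param n_loci,alleles_per_locus genotype dimensions; founder allele
#'   frequencies are drawn from a flat Dirichlet over `alleles_per_locus`
#'   labels, genotypes under Hardy-Weinberg.
#' @param pollen_kernel_mean mean of the exponential pollen kernel (m):
#'   fathers are drawn with weight `exp(-d / pollen_kernel_mean)`.
#' @param seed_kernel_mean mean of the exponential seed displacement (m).
#' @param jc_d50 distance (m) at which Janzen-Connell survival is 50%;
#'   very negative values disable thinning.
#' @param jc_slope logistic slope scale (m) of the survival curve.
#' @param n_seeds number of seeds produced per simulated cohort.
#' @param genotyping_error per-locus probability that an observed genotype
#'   is replaced by a random Hardy-Weinberg genotype (in `[0, 1)`).
#' @param missing_rate per-locus probability of a missing call (in `[0, 1)`).
#' @param undetermined_rate fraction of adults relabelled sex-undetermined
#'   (emulates non-flowering individuals; they keep their true sex in the
#'   `true_sex` column).
#' @param rng_seed integer seed making every simulator output reproducible.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(window = c(1000, 300), n_adults = 210,
                       sex_ratio = 0.6, n_loci = 9, alleles_per_locus = 7,
                       pollen_kernel_mean = 200, seed_kernel_mean = 200,
                       jc_d50 = 150, jc_slope = 30, n_seeds = 500,
                       genotyping_error = 0.0923, missing_rate = 0.02,
                       undetermined_rate = 0, rng_seed = NULL) {
  p <- list(window = as.numeric(window), n_adults = as.integer(n_adults),
            sex_ratio = sex_ratio, n_loci = as.integer(n_loci),
            alleles_per_locus = as.integer(alleles_per_locus),
            pollen_kernel_mean = pollen_kernel_mean,
            seed_kernel_mean = seed_kernel_mean,
            jc_d50 = jc_d50, jc_slope = jc_slope,
            n_seeds = as.integer(n_seeds),
            genotyping_error = genotyping_error,
            missing_rate = missing_rate,
            undetermined_rate = undetermined_rate,
            rng_seed = rng_seed)
  stopifnot(length(p$window) == 2, all(p$window > 0),
            p$n_adults >= 2, p$n_loci >= 1, p$alleles_per_locus >= 1,
            p$pollen_kernel_mean > 0, p$seed_kernel_mean > 0,
            p$jc_slope > 0, p$n_seeds >= 0)
  if (p$sex_ratio <= 0 || p$sex_ratio >= 1) {
    stopf("sex_ratio must lie strictly in (0, 1): both sexes are required")
  }
  for (f in c("genotyping_error", "missing_rate", "undetermined_rate")) {
    if (p[[f]] < 0 || p[[f]] >= 1) stopf("%s must lie in [0, 1)", f)
  }
  class(p) <- "sim_params"
  p
}

# Flat Dirichlet draw over k categories.
rdirichlet_flat <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# HWE genotypes for n individuals at one locus: two independent allele draws.
r_hwe_genotypes <- function(n, p_alleles) {
  labels <- as.integer(names(p_alleles) %||% seq_along(p_alleles))
  cbind(sample(labels, n, TRUE, prob = p_alleles),
        sample(labels, n, TRUE, prob = p_alleles))
}

#' Simulate the mapped adult population
#'
#' Positions are uniform in the window, sex is male with probability
#' `sex_ratio`, founder allele frequencies are flat-Dirichlet and genotypes
#' Hardy-Weinberg. Adult dbh is drawn from a gamma shifted past the 10-cm
#' boundary so adults fall into the two larger cohorts, as a mapped
#' reproductive population does. A draw with no male or no female is an
#' error (re-seed).
#'
#' @param params a [sim_params()].
#' @return a [population()] of adults; founder allele frequencies are kept
#'   in `attr(, "founder_freqs")` and the pre-relabelling sex in the
#'   `true_sex` column.
#' @export
simulate_adults <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed, {
    n <- params$n_adults
    x <- stats::runif(n, 0, params$window[1])
    y <- stats::runif(n, 0, params$window[2])
    sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
    if (!any(sex == "male") || !any(sex == "female")) {
      stopf("simulated adults are all one sex; use another rng_seed")
    }
    dbh <- 10 + stats::rgamma(n, shape = 2, scale = 5)
    freqs <- lapply(seq_len(params$n_loci), function(l) {
      p <- rdirichlet_flat(params$alleles_per_locus)
      names(p) <- seq_along(p)
      p
    })
    geno <- array(NA_integer_, c(n, params$n_loci, 2))
    for (l in seq_len(params$n_loci)) geno[, l, ] <- r_hwe_genotypes(n, freqs[[l]])
    obs_sex <- sex
    if (params$undetermined_rate > 0) {
      hide <- stats::runif(n) < params$undetermined_rate
      # never hide the last individual of a sex
      for (s in c("male", "female")) {
        if (all(hide[sex == s])) hide[which(sex == s)[1]] <- FALSE
      }
      obs_sex[hide] <- "undetermined"
    }
    ind <- data.frame(id = sprintf("A%03d", seq_len(n)), x = x, y = y,
                      dbh = dbh, sex = obs_sex,
                      cohort = assign_size_class(dbh),
                      stringsAsFactors = FALSE)
    ind$true_sex <- sex
    loci <- sprintf("L%02d", seq_len(params$n_loci))
    names(freqs) <- loci
    pop <- population(ind, geno, loci, params$window)
    attr(pop, "founder_freqs") <- freqs
    pop
  })
}

# logistic distance-dependent escape probability from one parent's
# mortality zone; total Janzen-Connell survival is the product over the
# two parents (each parent is an independent source of density-dependent
# mortality, so proximity to either depresses recruitment)
jc_survival_prob <- function(d, d50, slope) 1 / (1 + exp(-(d - d50) / slope))

#' Simulate seeds with known pedigree, dispersal and Janzen-Connell thinning
#'
#' For each seed a mother is drawn uniformly among females (`true_sex` is
#' used when some adults are relabelled undetermined); the father among
#' males with probability proportional to `exp(-d(mother, male) /
#' pollen_kernel_mean)`; the offspring genotype by Mendelian sampling; the
#' deposition point at the mother plus a displacement with exponential
#' length and uniform direction, redrawn until inside the window (the plot
#' truncates observation the same way); survival is Bernoulli with
#' probability `s(d_mother) * s(d_father)` where
#' `s(d) = 1 / (1 + exp(-(d - jc_d50)/jc_slope))` and the distances run
#' from the deposition point to each parent: each parent is an independent
#' source of distance-dependent (Janzen-Connell) mortality, so recruitment
#' is depressed near mothers and fathers alike. The full seed set is the
#' "effective" sample, the survivors the "realized" sample.
#'
#' @param adults adult [population()] from [simulate_adults()].
#' @param params a [sim_params()]; `rng_seed` governs this step too.
#' @return list with `offspring` (a [population()] of all seeds, true
#'   pre-error genotypes, cohort `"I"`) and `truth` (data.frame: ids of
#'   seed, mother and father, pollen distance = mother-father, seed
#'   distance = deposition-mother, deposition coordinates, survival flag).
#' @export
simulate_progeny <- function(adults, params) {
  stopifnot(inherits(params, "sim_params"))
  sex <- adults$ind$true_sex %||% adults$ind$sex
  females <- which(sex == "female")
  males <- which(sex == "male")
  if (!length(females) || !length(males)) stopf("need adults of both sexes")
  n <- params$n_seeds
  L <- length(adults$loci)
  with_seed(if (is.null(params$rng_seed)) NULL else params$rng_seed + 1L, {
    mothers <- sample(females, n, replace = TRUE)
    # pollen kernel: father weight decays exponentially in distance
    dmm <- sqrt(outer(adults$ind$x[females], adults$ind$x[males], "-")^2 +
                outer(adults$ind$y[females], adults$ind$y[males], "-")^2)
    fathers <- integer(n)
    mi <- match(mothers, females)
    for (fi in unique(mi)) {
      k <- which(mi == fi)
      w <- exp(-dmm[fi, ] / params$pollen_kernel_mean)
      fathers[k] <- males[sample.int(length(males), length(k),
                                     replace = TRUE, prob = w)]
    }
    # Mendelian genotypes: one uniformly chosen allele from each parent
    geno <- array(NA_integer_, c(n, L, 2))
    pick <- function(g2) ifelse(stats::runif(nrow(g2)) < 0.5, g2[, 1], g2[, 2])
    for (l in seq_len(L)) {
      geno[, l, 1] <- pick(adults$geno[mothers, l, , drop = FALSE][, 1, ])
      geno[, l, 2] <- pick(adults$geno[fathers, l, , drop = FALSE][, 1, ])
    }
    # seed deposition: exponential distance, uniform direction, rejection
    # sampling keeps depositions inside the window
    mx <- adults$ind$x[mothers]; my <- adults$ind$y[mothers]
    dep_x <- rep(NA_real_, n); dep_y <- rep(NA_real_, n)
    todo <- seq_len(n)
    while (length(todo)) {
      r <- stats::rexp(length(todo), rate = 1 / params$seed_kernel_mean)
      th <- stats::runif(length(todo), 0, 2 * pi)
      px <- mx[todo] + r * cos(th); py <- my[todo] + r * sin(th)
      ok <- px >= 0 & px <= params$window[1] & py >= 0 & py <= params$window[2]
      dep_x[todo[ok]] <- px[ok]; dep_y[todo[ok]] <- py[ok]
      todo <- todo[!ok]
    }
    seed_dist <- sqrt((dep_x - mx)^2 + (dep_y - my)^2)
    fx <- adults$ind$x[fathers]; fy <- adults$ind$y[fathers]
    pollen_dist <- sqrt((mx - fx)^2 + (my - fy)^2)
    d_father <- sqrt((dep_x - fx)^2 + (dep_y - fy)^2)
    surv_p <- jc_survival_prob(seed_dist, params$jc_d50, params$jc_slope) *
      jc_survival_prob(d_father, params$jc_d50, params$jc_slope)
    survived <- stats::runif(n) < surv_p

    ids <- sprintf("S%04d", seq_len(n))
    ind <- data.frame(id = ids, x = dep_x, y = dep_y,
                      dbh = stats::runif(n, 0.5, 9.5), sex = "undetermined",
                      cohort = "I", stringsAsFactors = FALSE)
    offspring <- population(ind, geno, adults$loci, params$window)
    truth <- data.frame(id = ids,
                        mother = adults$ind$id[mothers],
                        father = adults$ind$id[fathers],
                        pollen_dist = pollen_dist,
                        seed_dist = seed_dist,
                        dep_x = dep_x, dep_y = dep_y,
                        survived = survived,
                        stringsAsFactors = FALSE)
    list(offspring = offspring, truth = truth)
  })
}

#' Overlay genotyping error and missing data on observed genotypes
#'
#' Independently per individual and locus: with probability `error_rate`
#' the true genotype is replaced by a random Hardy-Weinberg genotype at the
#' reference allele frequencies, then with probability `missing_rate` the
#' locus is set missing. This is exactly the observation model the
#' parentage likelihood assumes.
#'
#' @param pop a genotyped [population()].
#' @param error_rate,missing_rate probabilities in `[0, 1)`.
#' @param rng_seed integer seed.
#' @param freqs reference [allele_frequencies()]; default: frequencies of
#'   `pop` itself.
#' @return the population with perturbed genotypes.
#' @export
apply_genotyping_error <- function(pop, error_rate, missing_rate = 0,
                                   rng_seed = NULL, freqs = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (error_rate == 0 && missing_rate == 0) return(pop)
  freqs <- freqs %||% allele_frequencies(pop)
  n <- n_individuals(pop)
  with_seed(rng_seed, {
    geno <- pop$geno
    for (l in seq_along(pop$loci)) {
      p <- freqs$loci[[pop$loci[l]]]$freq
      if (error_rate > 0) {
        err <- stats::runif(n) < error_rate
        if (any(err)) geno[err, l, ] <- r_hwe_genotypes(sum(err), p)
      }
      if (missing_rate > 0) {
        mis <- stats::runif(n) < missing_rate
        geno[mis, l, ] <- NA_integer_
      }
    }
    out <- pop
    out$geno <- geno
    dimnames(out$geno) <- list(out$ind$id, out$loci, NULL)
    out
  })
}

#' Keep only the seeds that survived Janzen-Connell thinning
#' @param offspring offspring [population()] from [simulate_progeny()].
#' @param truth matching truth table.
#' @export
realized_offspring <- function(offspring, truth) {
  subset_population(offspring, truth$id[truth$survived])
}
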