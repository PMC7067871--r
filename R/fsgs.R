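#' Pairwise multilocus kinship (Loiselle estimator)
#'
#' For locus `l` with allele dosages `x_ia` in \{0, 0.5, 1\} and reference
#' allele frequencies `p_a` estimated from `n_l` individuals,
#' \deqn{F_{ij,l} = \frac{\sum_a (x_{ia}-p_a)(x_{ja}-p_a) +
#'   \sum_a p_a(1-p_a)/(n_l-1)}{\sum_a p_a(1-p_a)}}
#' and the multilocus value is the average over loci weighted by the locus
#' polymorphism `w_l = sum(p_a (1 - p_a))`. A pair missing a genotype at a
#' locus drops that locus from both sums; monomorphic loci carry zero
#' weight. The estimator is centred on the reference sample: unrelated
#' pairs average slightly below zero (about `-1/(n-1)`).
#'
#' @param pop the [population()] whose pairs are evaluated.
#' @param reference population supplying allele frequencies (must contain
#'   all individuals of `pop`); default `pop` itself.
#' @return object of class `"kinship"`: `F` (symmetric matrix, diagonal
#'   `NA`), per-locus numerator/weight components (used by the jackknife),
#'   the reference frequencies, and per-locus reference sample sizes.
#' @export
kinship_matrix <- function(pop, reference = pop) {
  if (is.null(pop$geno)) stopf("population is not genotyped")
  if (!all(pop$loci == reference$loci)) stopf("locus lists differ")
  if (!all(pop$ind$id %in% reference$ind$id)) {
    stopf("reference must contain every analyzed individual")
  }
  fr <- allele_frequencies(reference)
  n <- n_individuals(pop)
  L <- length(pop$loci)
  NUM <- matrix(0, n, n)
  DEN <- matrix(0, n, n)
  num_l <- vector("list", L)
  mask_l <- vector("list", L)
  w <- numeric(L)
  n_ref <- integer(L)
  for (l in seq_len(L)) {
    f <- fr$loci[[l]]
    p <- as.numeric(f$freq)
    labels <- as.integer(names(f$freq))
    w[l] <- sum(p * (1 - p))
    n_ref[l] <- f$n_genes / 2L
    a1 <- pop$geno[, l, 1]; a2 <- pop$geno[, l, 2]
    avail <- !is.na(a1) & !is.na(a2)
    if (any(avail & (!(a1 %in% labels) | !(a2 %in% labels)))) {
      stopf("allele at locus %s absent from the reference", pop$loci[l])
    }
    mask <- outer(avail, avail)
    mask_l[[l]] <- mask
    if (w[l] == 0 || n_ref[l] < 2) {   # monomorphic: zero weight
      num_l[[l]] <- matrix(0, n, n)
      w[l] <- 0
      next
    }
    X <- matrix(0, n, length(p))
    i1 <- match(a1[avail], labels); i2 <- match(a2[avail], labels)
    rows <- which(avail)
    X[cbind(rows, i1)] <- X[cbind(rows, i1)] + 0.5
    X[cbind(rows, i2)] <- X[cbind(rows, i2)] + 0.5
    Xc <- sweep(X, 2, p)
    Xc[!avail, ] <- 0
    corr <- sum(p * (1 - p)) / (n_ref[l] - 1)
    num_l[[l]] <- (Xc %*% t(Xc) + corr) * mask
    NUM <- NUM + num_l[[l]]
    DEN <- DEN + w[l] * mask
  }
  if (all(w == 0)) stopf("all loci are monomorphic in the reference")
  F_ij <- NUM / DEN
  F_ij[DEN == 0] <- NA_real_
  diag(F_ij) <- NA_real_
  dimnames(F_ij) <- list(pop$ind$id, pop$ind$id)
  structure(list(F = F_ij, NUM = NUM, DEN = DEN, num_l = num_l,
                 mask_l = mask_l, w = w, n_ref = n_ref, loci = pop$loci,
                 freqs = fr, ids = pop$ind$id),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship: %d individuals, %d loci (%d polymorphic)\n",
              nrow(x$F), length(x$loci), sum(x$w > 0)))
  cat(sprintf("  mean pairwise F_ij = %.5f\n", mean(x$F, na.rm = TRUE)))
  invisible(x)
}

# class index of each pairwise distance under half-open (lower, upper]
# intervals; NA for distances outside (0, max(bounds)]
distance_class_of <- function(d, bounds) {
  cls <- rep(NA_integer_, length(d))
  inside <- d > 0 & d <= bounds[length(bounds)]
  cls[inside] <- findInterval(d[inside], bounds, left.open = TRUE) + 1L
  cls
}

# Shared engine for within- and between-cohort autocorrelograms. The null
# permutes the genotype-to-location assignment: location pairs (and hence
# distance classes) stay fixed while genotypes (and cohort labels, for the
# between analysis) are shuffled across locations.
autocorrelogram_core <- function(Fm, distances, bounds, n_perm, rng_seed,
                                 group = NULL) {
  n <- nrow(Fm)
  iu <- which(upper.tri(distances), arr.ind = TRUE)
  d <- distances[iu]
  cls <- distance_class_of(d, bounds)
  keep <- !is.na(cls)
  iu <- iu[keep, , drop = FALSE]
  cls <- cls[keep]
  k <- length(bounds)
  pair_value <- function(perm) Fm[cbind(perm[iu[, 1]], perm[iu[, 2]])]
  pair_in <- function(perm) {
    if (is.null(group)) rep(TRUE, nrow(iu))
    else {
      g1 <- group[perm[iu[, 1]]]; g2 <- group[perm[iu[, 2]]]
      !is.na(g1) & !is.na(g2) & g1 != g2
    }
  }
  class_means <- function(perm) {
    v <- pair_value(perm)
    use <- pair_in(perm) & !is.na(v)
    out <- rep(NA_real_, k)
    cnt <- integer(k)
    for (c in seq_len(k)) {
      sel <- use & cls == c
      cnt[c] <- sum(sel)
      if (cnt[c]) out[c] <- mean(v[sel])
    }
    list(mean = out, count = cnt)
  }
  obs <- class_means(seq_len(n))
  if (any(obs$count == 0)) {
    stopf("empty distance class (upper bound %g m)",
          bounds[which(obs$count == 0)[1]])
  }
  with_seed(rng_seed, {
    null <- matrix(NA_real_, n_perm, k)
    for (b in seq_len(n_perm)) {
      null[b, ] <- class_means(sample.int(n))$mean
    }
    env <- apply(null, 2, perm_envelope)
    p <- vapply(seq_len(k), function(c)
      perm_p_two_sided(obs$mean[c], null[, c][!is.na(null[, c])]), numeric(1))
    data.frame(lower = c(0, bounds[-k]), upper = bounds,
               mean_kinship = obs$mean, n_pairs = obs$count,
               env_lower = env[1, ], env_upper = env[2, ], p = p)
  })
}

#' Kinship autocorrelogram over distance classes with permutation envelopes
#'
#' Mean pairwise kinship per distance class, with a null distribution built
#' by permuting the genotype-to-location assignment (`n_perm` random
#' relocations of individuals in space). The envelope is the order-statistic
#' 95% band of the null class means; `p` is the two-sided permutation rank
#' p-value.
#'
#' @param kin a [kinship_matrix()] result.
#' @param distances matching matrix from [pairwise_distances()].
#' @param classes distance-class upper bounds, see [distance_classes()].
#' @param n_perm number of permutations (>= 99; field studies use 10000).
#' @param rng_seed integer seed.
#' @return data.frame: class bounds, `mean_kinship`, `n_pairs`,
#'   `env_lower`, `env_upper`, `p`.
#' @export
autocorrelogram <- function(kin, distances, classes = distance_classes(),
                            n_perm = 999, rng_seed = NULL) {
  stopifnot(inherits(kin, "kinship"), n_perm >= 99)
  bounds <- distance_classes(classes)
  autocorrelogram_core(kin$F, distances, bounds, n_perm, rng_seed)
}

#' Between-cohort kinship autocorrelogram
#'
#' Identical machinery restricted to pairs made of one individual from each
#' cohort (e.g. seedlings vs large adults, probing parent-offspring
#' proximity). Reference allele frequencies come from the union of the two
#' cohorts, and the null permutes locations within the union, cohort labels
#' travelling with the genotypes.
#'
#' @param pop_a,pop_b disjoint genotyped [population()]s sharing loci and
#'   window.
#' @inheritParams autocorrelogram
#' @return data.frame as [autocorrelogram()].
#' @export
between_class_autocorrelogram <- function(pop_a, pop_b,
                                          classes = distance_classes(),
                                          n_perm = 999, rng_seed = NULL) {
  if (!length(pop_a$ind$id) || !length(pop_b$ind$id)) stopf("empty cohort")
  if (any(pop_a$ind$id %in% pop_b$ind$id)) stopf("cohorts must be disjoint")
  if (!all(pop_a$loci == pop_b$loci)) stopf("locus lists differ")
  union <- population(rbind(pop_a$ind[c("id", "x", "y", "dbh", "sex", "cohort")],
                            pop_b$ind[c("id", "x", "y", "dbh", "sex", "cohort")]),
                      geno = abind3(pop_a$geno, pop_b$geno),
                      loci = pop_a$loci, window = pop_a$window)
  kin <- kinship_matrix(union)
  d <- pairwise_distances(union)
  group <- c(rep("a", n_individuals(pop_a)), rep("b", n_individuals(pop_b)))
  bounds <- distance_classes(classes)
  autocorrelogram_core(kin$F, d, bounds, n_perm, rng_seed, group = group)
}

# bind two n x L x 2 genotype arrays along individuals
abind3 <- function(a, b) {
  stopifnot(!is.null(a), !is.null(b), dim(a)[2] == dim(b)[2])
  out <- array(NA_integer_, c(dim(a)[1] + dim(b)[1], dim(a)[2], 2))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# closed-form OLS slope (used on pairwise kinship vs ln distance)
ols_slope <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::var(x) == 0) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' Regression of pairwise kinship on ln(distance)
#'
#' Ordinary least squares of `F_ij` on `ln(d_ij)` over all analyzed pairs
#' (not class means). The slope's standard error comes from a delete-one
#' jackknife over loci; the p-value from the same genotype-over-location
#' permutation null as the autocorrelogram. Co-located pairs (zero
#' distance) are excluded with a warning.
#'
#' @param kin a [kinship_matrix()] result (>= 2 polymorphic loci for the
#'   jackknife).
#' @param distances matrix from [pairwise_distances()].
#' @param n_perm permutations for the slope null (>= 99).
#' @param rng_seed integer seed.
#' @param max_dist optionally restrict pairs to `d_ij <= max_dist` (m).
#' @return list: `b_log`, `se_jackknife`, `p_perm`, `n_pairs`.
#' @export
kinship_log_regression <- function(kin, distances, n_perm = 999,
                                   rng_seed = NULL, max_dist = NULL) {
  stopifnot(inherits(kin, "kinship"), n_perm >= 99)
  n <- nrow(kin$F)
  iu <- which(upper.tri(distances), arr.ind = TRUE)
  d <- distances[iu]
  if (any(d == 0)) {
    warning("excluding ", sum(d == 0), " co-located pair(s) from the regression")
  }
  keep <- d > 0
  if (!is.null(max_dist)) keep <- keep & d <= max_dist
  iu <- iu[keep, , drop = FALSE]
  lnd <- log(d[keep])
  y <- kin$F[iu]
  if (sum(!is.na(y)) < 3) stopf("need at least three analyzed pairs")
  b <- ols_slope(lnd, y)

  # delete-one-locus jackknife on the multilocus kinship
  use_l <- which(kin$w > 0)
  if (length(use_l) < 2) stopf("jackknife needs at least two polymorphic loci")
  b_del <- vapply(use_l, function(l) {
    NUMd <- kin$NUM - kin$num_l[[l]]
    DENd <- kin$DEN - kin$w[l] * kin$mask_l[[l]]
    Fd <- NUMd / DENd
    Fd[DENd == 0] <- NA_real_
    ols_slope(lnd, Fd[iu])
  }, numeric(1))
  g <- length(use_l)
  se <- sqrt((g - 1) / g * sum((b_del - mean(b_del))^2))

  null <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(bb) {
      perm <- sample.int(n)
      ols_slope(lnd, kin$F[cbind(perm[iu[, 1]], perm[iu[, 2]])])
    }, numeric(1))
  })
  list(b_log = b, se_jackknife = se,
       p_perm = perm_p_two_sided(b, null[!is.na(null)]),
       n_pairs = sum(!is.na(y)))
}

#' The Sp statistic of FSGS intensity
#'
#' `Sp = -b_log / (1 - F1)` where `b_log` is the slope of kinship on
#' ln(distance) and `F1` the mean kinship in the first distance class.
#' Larger Sp means stronger fine-scale genetic structure; animal-dispersed
#' trees typically fall in 0.01-0.03.
#'
#' @param b_log regression slope from [kinship_log_regression()].
#' @param F1 first-distance-class mean kinship (< 1).
#' @return Sp (numeric).
#' @export
sp_statistic <- function(b_log, F1) {
  if (any(F1 >= 1)) stopf("F1 must be < 1")
  -b_log / (1 - F1)
}

#' One-call FSGS summary: autocorrelogram, regression and Sp
#'
#' @param pop a genotyped [population()] (a single cohort, typically).
#' @param classes distance-class upper bounds.
#' @param n_perm permutations for both envelope and slope null.
#' @param rng_seed integer seed.
#' @param reference population for allele frequencies (default: `pop`).
#' @param max_dist optional distance cap for the regression (m).
#' @return list of class `"sp_result"`: `correlogram` (data.frame),
#'   `b_log`, `se_jackknife`, `p_slope`, `F1`, `Sp`.
#' @export
sp_summary <- function(pop, classes = distance_classes(), n_perm = 999,
                       rng_seed = NULL, reference = pop, max_dist = NULL) {
  kin <- kinship_matrix(pop, reference)
  d <- pairwise_distances(pop)
  corr <- autocorrelogram(kin, d, classes, n_perm, rng_seed)
  reg <- kinship_log_regression(kin, d, n_perm, rng_seed, max_dist)
  F1 <- corr$mean_kinship[1]
  structure(list(correlogram = corr, b_log = reg$b_log,
                 se_jackknife = reg$se_jackknife, p_slope = reg$p_perm,
                 F1 = F1, Sp = sp_statistic(reg$b_log, F1)),
            class = "sp_result")
}

#' @export
print.sp_result <- function(x, ...) {
  cat(sprintf("FSGS: b_log = %.5f (SE %.5f, perm p = %.4g), F(1) = %.4f, Sp = %.4f\n",
              x$b_log, x$se_jackknife, x$p_slope, x$F1, x$Sp))
  print(x$correlogram, digits = 4)
  invisible(x)
}
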