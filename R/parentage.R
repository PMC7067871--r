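# Per-locus genotype machinery shared by exclusion and likelihood parentage.
#
# For a locus with k alleles the G = k(k+1)/2 unordered genotypes are
# enumerated once; `mendel` is the G x G x G array of transmission
# probabilities P(offspring | mother, father), `hwe` the Hardy-Weinberg
# genotype probabilities, `po_m` the P(offspring | mother, random father)
# marginal, and `gidx` an allele-pair -> genotype-index lookup.
locus_table <- function(freq) {
  p <- as.numeric(freq)
  labels <- as.integer(names(freq))
  k <- length(p)
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  A1 <- pairs[, 1]; A2 <- pairs[, 2]          # A1 <= A2
  G <- length(A1)
  hwe <- p[A1] * p[A2] * ifelse(A1 == A2, 1, 2)
  tr <- 0.5 * (outer(A1, seq_len(k), "==") + outer(A2, seq_len(k), "=="))
  mendel <- array(0, c(G, G, G))              # [offspring, mother, father]
  for (o in seq_len(G)) {
    m <- outer(tr[, A1[o]], tr[, A2[o]])
    if (A1[o] != A2[o]) m <- m + outer(tr[, A2[o]], tr[, A1[o]])
    mendel[o, , ] <- m
  }
  po_m <- apply(mendel, c(1, 2), function(v) sum(v * hwe))
  gidx <- matrix(NA_integer_, k, k)
  gidx[cbind(A1, A2)] <- seq_len(G)
  gidx[cbind(A2, A1)] <- seq_len(G)
  list(labels = labels, p = p, G = G, hwe = hwe, mendel = mendel,
       po_m = po_m, gidx = gidx, tr = tr, A1 = A1, A2 = A2)
}

locus_tables <- function(freqs) lapply(freqs$loci, function(f) locus_table(f$freq))

# genotype index per individual at one locus; NA where missing
encode_locus <- function(geno_l, tab, locus = "") {
  a1 <- geno_l[, 1]; a2 <- geno_l[, 2]
  ok <- !is.na(a1) & !is.na(a2)
  i1 <- match(a1, tab$labels); i2 <- match(a2, tab$labels)
  if (any(ok & (is.na(i1) | is.na(i2)))) {
    stopf("allele at locus %s not covered by the reference frequencies", locus)
  }
  out <- rep(NA_integer_, length(a1))
  out[ok] <- tab$gidx[cbind(i1[ok], i2[ok])]
  out
}

#' Parentage exclusion probabilities
#'
#' Probability that a random unrelated Hardy-Weinberg candidate is
#' genotype-incompatible (error-free logic) as: the first parent of an
#' offspring (no other parent known), the second parent given one known
#' parent, or jointly as a parent pair. Averaged over the HWE distribution
#' of offspring (and known-parent) genotypes by exhaustive enumeration of
#' genotype configurations, and combined over loci as
#' `1 - prod(1 - Q_l)`.
#'
#' @param freqs an [allele_frequencies()] object.
#' @return list: `per_locus` data.frame (`Q1`, `Q2`, `Qpair`) and
#'   `combined` named vector.
#' @export
exclusion_probabilities <- function(freqs) {
  tabs <- locus_tables(freqs)
  rows <- lapply(seq_along(tabs), function(l) {
    tb <- tabs[[l]]
    if (length(tb$p) < 2) {
      return(data.frame(locus = names(freqs$loci)[l], Q1 = 0, Q2 = 0,
                        Qpair = 0, stringsAsFactors = FALSE))
    }
    G <- tb$G; hwe <- tb$hwe
    # single parent: compatible iff the candidate carries >= 1 offspring allele
    carries <- function(o, c) tb$tr[c, tb$A1[o]] > 0 | tb$tr[c, tb$A2[o]] > 0
    compat1 <- outer(seq_len(G), seq_len(G), Vectorize(carries))
    Q1 <- sum(hwe * ((!compat1) %*% hwe))
    # second parent with a known mother: weight by P(m) P(o | m)
    incomp2 <- matrix(0, G, G)   # [o, m]: HWE mass of excluded candidates
    for (o in seq_len(G)) incomp2[o, ] <- (tb$mendel[o, , ] == 0) %*% hwe
    Q2 <- sum(sweep(tb$po_m * incomp2, 2, hwe, "*"))
    # parent pair: offspring HWE vs a random HWE pair
    Qpair <- sum(vapply(seq_len(G), function(o)
      hwe[o] * sum(outer(hwe, hwe) * (tb$mendel[o, , ] == 0)), numeric(1)))
    data.frame(locus = names(freqs$loci)[l], Q1 = Q1, Q2 = Q2, Qpair = Qpair,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_locus = per,
       combined = c(Q1 = 1 - prod(1 - per$Q1),
                    Q2 = 1 - prod(1 - per$Q2),
                    Qpair = 1 - prod(1 - per$Qpair)))
}

#' Single-locus transition probability under the genotyping-error model
#'
#' `P(g_obs | parents) = (1 - eps) * P_Mendel(g_obs | g_m, g_f) +
#' eps * P_HWE(g_obs)`: with probability `eps` the observed offspring
#' genotype is an unrelated Hardy-Weinberg draw. A missing genotype (any of
#' the three) contributes likelihood 1.
#'
#' @param g_offspring,g_mother,g_father length-2 integer allele pairs
#'   (`NA` = missing; `NULL` treats the genotype as missing).
#' @param freq named allele-frequency vector for the locus.
#' @param eps genotyping-error probability in `[0, 1)`.
#' @return the likelihood contribution of the locus.
#' @export
transition_probability <- function(g_offspring, g_mother, g_father, freq,
                                   eps = 0) {
  stopifnot(eps >= 0, eps < 1)
  miss <- function(g) is.null(g) || any(is.na(g))
  if (miss(g_offspring) || miss(g_mother) || miss(g_father)) return(1)
  tab <- locus_table(freq)
  enc <- function(g) {
    i <- match(as.integer(g), tab$labels)
    if (anyNA(i)) {
      if (eps > 0) stopf("allele not covered by the reference frequencies")
      return(NA_integer_)
    }
    tab$gidx[i[1], i[2]]
  }
  o <- enc(g_offspring); m <- enc(g_mother); f <- enc(g_father)
  if (is.na(o) || is.na(m) || is.na(f)) return(0)  # eps = 0, foreign allele
  (1 - eps) * tab$mendel[o, m, f] + eps * tab$hwe[o]
}

# LOD matrix (offspring x candidate fathers) for paternity with known
# mothers: sum over loci of
# log[ ((1-e) T[o,m,c] + e HWE[o]) / ((1-e) P(o|m) + e HWE[o]) ].
# Also returns the Mendelian mismatch count per (offspring, candidate).
paternity_lod <- function(go, gm, gc, tabs, eps) {
  n <- nrow(go); nc <- nrow(gc)
  lod <- matrix(0, n, nc)
  mism <- matrix(0L, n, nc)
  for (l in seq_len(ncol(go))) {
    tb <- tabs[[l]]
    ok_o <- !is.na(go[, l]) & !is.na(gm[, l])
    ok_c <- !is.na(gc[, l])
    if (!any(ok_o) || !any(ok_c)) next
    io <- which(ok_o); ic <- which(ok_c)
    idx <- cbind(rep(go[io, l], times = length(ic)),
                 rep(gm[io, l], times = length(ic)),
                 rep(gc[ic, l], each = length(io)))
    tmen <- tb$mendel[idx]
    hw <- tb$hwe[go[io, l]]
    den <- (1 - eps) * tb$po_m[cbind(go[io, l], gm[io, l])] + eps * hw
    contrib <- log((1 - eps) * tmen + eps * rep(hw, length(ic))) -
      log(rep(den, length(ic)))
    lod[io, ic] <- lod[io, ic] + matrix(contrib, length(io), length(ic))
    mism[io, ic] <- mism[io, ic] +
      matrix(as.integer(tmen == 0), length(io), length(ic))
  }
  list(lod = lod, mismatch = mism)
}

# pick the best candidate per row subject to tier thresholds and the
# near-tie rule; returns index (NA = unassigned), LOD, tier, mismatches
pick_best <- function(lod, mism, thresholds, tie_tol = 1e-9) {
  n <- nrow(lod)
  best <- integer(n); bl <- numeric(n); tier <- character(n); mm <- integer(n)
  for (i in seq_len(n)) {
    v <- lod[i, ]
    j <- which.max(v)
    b <- v[j]
    tied <- sum(v >= b - tie_tol)
    if (!is.finite(b) || tied > 1) {
      best[i] <- NA_integer_; bl[i] <- b; tier[i] <- "unassigned"; mm[i] <- NA
      next
    }
    best[i] <- j; bl[i] <- b; mm[i] <- mism[i, j]
    tier[i] <- if (b >= thresholds["95%"]) "95%"
    else if (b >= thresholds["80%"]) "80%"
    else "unassigned"
    if (tier[i] == "unassigned") best[i] <- NA_integer_
  }
  list(index = best, lod = bl, tier = tier, mismatch = mm)
}

# HWE genotype-index draws for calibration simulations
r_geno_idx <- function(n, tab) sample.int(tab$G, n, TRUE, prob = tab$hwe)

# Mendelian offspring genotype index given parent indices
r_offspring_idx <- function(m_idx, f_idx, tab) {
  k <- length(tab$p)
  pick_allele <- function(g_idx) {
    ifelse(stats::runif(length(g_idx)) < 0.5, tab$A1[g_idx], tab$A2[g_idx])
  }
  a <- pick_allele(m_idx); b <- pick_allele(f_idx)
  tab$gidx[cbind(a, b)]
}

#' Calibrate LOD confidence thresholds for paternity assignment
#'
#' Monte Carlo calibration in the spirit of categorical-likelihood
#' parentage software: simulate offspring whose true father is inside the
#' candidate pool with probability `prop_inside` (Hardy-Weinberg mothers
#' and outside fathers), apply the genotyping-error model, and find the
#' smallest best-candidate LOD cutoffs at which at least 95% / 80% of
#' assignments above the cutoff are correct.
#'
#' @param candidates genotyped [population()] of candidate fathers.
#' @param freqs reference [allele_frequencies()].
#' @param error_rate assumed genotyping-error probability.
#' @param n_sim simulated offspring (>= 200 recommended).
#' @param rng_seed integer seed.
#' @param prop_inside prior probability that the true father is sampled.
#' @return named numeric: thresholds `"95%"` and `"80%"` (`Inf` when a tier
#'   is unattainable).
#' @export
calibrate_paternity_thresholds <- function(candidates, freqs, error_rate = 0,
                                           n_sim = 1000, rng_seed = NULL,
                                           prop_inside = 0.5) {
  tabs <- locus_tables(freqs)
  gc <- encode_pop_idx(candidates, tabs)
  nc <- nrow(gc)
  L <- length(tabs)
  with_seed(rng_seed, {
    inside <- stats::runif(n_sim) < prop_inside
    true_f <- ifelse(inside, sample.int(nc, n_sim, TRUE), NA_integer_)
    gm <- matrix(NA_integer_, n_sim, L)
    go <- matrix(NA_integer_, n_sim, L)
    for (l in seq_len(L)) {
      tb <- tabs[[l]]
      gm[, l] <- r_geno_idx(n_sim, tb)
      f_idx <- ifelse(inside, gc[true_f, l], r_geno_idx(n_sim, tb))
      # candidate genotype can be missing: replace by an HWE draw
      f_idx[is.na(f_idx)] <- r_geno_idx(sum(is.na(f_idx)), tb)
      go[, l] <- r_offspring_idx(gm[, l], f_idx, tb)
      if (error_rate > 0) {
        err <- stats::runif(n_sim) < error_rate
        if (any(err)) go[err, l] <- r_geno_idx(sum(err), tb)
      }
    }
    sc <- paternity_lod(go, gm, gc, tabs, error_rate)
    calibrate_from_scores(sc$lod, true_f)
  })
}

# shared threshold search: best-LOD vs correctness of the best candidate
calibrate_from_scores <- function(lod, true_idx, tie_tol = 1e-9) {
  n <- nrow(lod)
  best_lod <- numeric(n); correct <- logical(n)
  for (i in seq_len(n)) {
    v <- lod[i, ]
    j <- which.max(v)
    best_lod[i] <- v[j]
    correct[i] <- !is.na(true_idx[i]) && j == true_idx[i] &&
      sum(v >= v[j] - tie_tol) == 1
  }
  usable <- is.finite(best_lod)
  best_lod <- best_lod[usable]; correct <- correct[usable]
  ord <- order(best_lod, decreasing = TRUE)
  acc <- cumsum(correct[ord]) / seq_along(ord)
  thr_at <- function(target) {
    ok <- which(acc >= target)
    if (!length(ok)) return(Inf)
    best_lod[ord][max(ok)]
  }
  c("95%" = thr_at(0.95), "80%" = thr_at(0.80))
}

# genotype-index matrix (n x L) for a population under the given tables
encode_pop_idx <- function(pop, tabs) {
  n <- n_individuals(pop)
  out <- matrix(NA_integer_, n, length(tabs))
  for (l in seq_along(tabs)) {
    out[, l] <- encode_locus(cbind(pop$geno[, l, 1], pop$geno[, l, 2]),
                             tabs[[l]], pop$loci[l])
  }
  out
}

#' Likelihood paternity assignment with known mothers
#'
#' Multilocus LOD of each candidate father against the random-father
#' hypothesis, under the genotyping-error model. The best candidate is
#' assigned when its LOD reaches the simulated confidence threshold
#' (tiers 95% and 80%); near-ties (< 1e-9 apart) and offspring with no
#' finite-LOD candidate are left unassigned. With `error_rate = 0` an
#' offspring whose compatible-candidate set is a single male is assigned
#' outright (exclusion logic and likelihood agree).
#'
#' @param offspring genotyped [population()] of offspring (seeds/embryos).
#' @param mother_ids character vector: known mother id per offspring (must
#'   exist in `adults`).
#' @param adults genotyped [population()] holding mothers and candidates.
#' @param freqs reference [allele_frequencies()] (default: from `adults`).
#' @param error_rate genotyping-error probability (the study estimate
#'   0.0923 is a typical value).
#' @param candidates candidate fathers (default: all males in `adults`).
#' @param n_sim,rng_seed,prop_inside threshold calibration controls, see
#'   [calibrate_paternity_thresholds()]; pass `thresholds` to skip
#'   calibration.
#' @param thresholds optional named numeric (`"95%"`, `"80%"`).
#' @return data.frame of class `"parentage"`: offspring id, mother id,
#'   assigned father id (`NA` = unassigned), `lod`, `tier`, `mismatch`,
#'   and `pollen_dist` (mother-father distance, m). The calibrated
#'   thresholds ride along as `attr(, "thresholds")`.
#' @export
assign_paternity <- function(offspring, mother_ids, adults,
                             freqs = allele_frequencies(adults),
                             error_rate = 0, candidates = NULL,
                             n_sim = 1000, rng_seed = NULL,
                             prop_inside = 0.5, thresholds = NULL) {
  stopifnot(length(mother_ids) == n_individuals(offspring))
  candidates <- candidates %||%
    subset_population(adults, adults$ind$sex == "male")
  if (!n_individuals(candidates)) stopf("no candidate fathers")
  tabs <- locus_tables(freqs)
  go <- encode_pop_idx(offspring, tabs)
  gc <- encode_pop_idx(candidates, tabs)
  mi <- match(mother_ids, adults$ind$id)
  if (anyNA(mi)) stopf("unknown mother id(s)")
  gm_all <- encode_pop_idx(adults, tabs)
  gm <- gm_all[mi, , drop = FALSE]
  thresholds <- thresholds %||%
    calibrate_paternity_thresholds(candidates, freqs, error_rate, n_sim,
                                   rng_seed, prop_inside)
  sc <- paternity_lod(go, gm, gc, tabs, error_rate)
  res <- pick_best(sc$lod, sc$mismatch, thresholds)
  if (error_rate == 0) {
    # a unique compatible candidate is assigned by exclusion
    for (i in seq_len(nrow(sc$lod))) {
      fin <- which(is.finite(sc$lod[i, ]))
      if (is.na(res$index[i]) && length(fin) == 1 && any(!is.na(go[i, ]))) {
        res$index[i] <- fin
        res$lod[i] <- sc$lod[i, fin]
        res$tier[i] <- "95%"
        res$mismatch[i] <- sc$mismatch[i, fin]
      }
    }
  }
  father_id <- ifelse(is.na(res$index), NA_character_,
                      candidates$ind$id[res$index])
  md <- adults$ind[mi, ]
  fd <- match(father_id, adults$ind$id)
  pollen <- sqrt((md$x - adults$ind$x[fd])^2 + (md$y - adults$ind$y[fd])^2)
  out <- data.frame(offspring = offspring$ind$id, mother = mother_ids,
                    father = father_id, lod = res$lod, tier = res$tier,
                    mismatch = res$mismatch, pollen_dist = pollen,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("parentage", "data.frame")
  out
}

# joint parent-pair LOD arrays; returns per offspring the best pair
parent_pair_lod <- function(go_i, gf, gm, tabs, eps) {
  nf <- nrow(gf); nm <- nrow(gm)
  lod <- matrix(0, nf, nm)
  mism <- matrix(0L, nf, nm)
  for (l in seq_along(tabs)) {
    o <- go_i[l]
    if (is.na(o)) next
    tb <- tabs[[l]]
    fok <- !is.na(gf[, l]); mok <- !is.na(gm[, l])
    if (!any(fok) || !any(mok)) next
    Tm <- tb$mendel[o, , ]
    sub <- Tm[gf[fok, l], gm[mok, l], drop = FALSE]
    hw <- tb$hwe[o]
    lod[fok, mok] <- lod[fok, mok] + log((1 - eps) * sub + eps * hw) - log(hw)
    mism[fok, mok] <- mism[fok, mok] + (sub == 0)
  }
  list(lod = lod, mismatch = mism)
}

#' Parent-pair assignment on established seedlings
#'
#' Joint LOD of every (female, male) candidate pair against the hypothesis
#' that the offspring is a random Hardy-Weinberg draw. Dioecy resolves the
#' parent roles: the female member of the best pair is the mother. Tier
#' thresholds are calibrated by simulating offspring of in-pool pairs
#' against out-of-pool pairs, mirroring the paternity calibration. Derived
#' distances follow the two field definitions: mother-father (realized
#' pollen) and offspring-mother (realized seed).
#'
#' @param offspring genotyped [population()] (e.g. the seedling cohort).
#' @param adults genotyped [population()] of candidate parents.
#' @param freqs reference [allele_frequencies()] (default from `adults`).
#' @param error_rate genotyping-error probability.
#' @param females,males candidate subsets (defaults: by sex in `adults`).
#' @param n_sim,rng_seed,prop_inside calibration controls.
#' @param thresholds optional named numeric (`"95%"`, `"80%"`).
#' @return data.frame of class `"parentage"`: offspring, mother, father,
#'   `lod`, `tier`, `mismatch`, `pollen_dist`, `seed_dist`.
#' @export
assign_parent_pair <- function(offspring, adults,
                               freqs = allele_frequencies(adults),
                               error_rate = 0, females = NULL, males = NULL,
                               n_sim = 1000, rng_seed = NULL,
                               prop_inside = 0.5, thresholds = NULL) {
  females <- females %||%
    subset_population(adults, adults$ind$sex == "female")
  males <- males %||% subset_population(adults, adults$ind$sex == "male")
  if (!n_individuals(females) || !n_individuals(males)) {
    stopf("need candidates of both sexes")
  }
  tabs <- locus_tables(freqs)
  go <- encode_pop_idx(offspring, tabs)
  gf <- encode_pop_idx(females, tabs)
  gm <- encode_pop_idx(males, tabs)
  thresholds <- thresholds %||%
    calibrate_pair_thresholds(gf, gm, tabs, error_rate, n_sim, rng_seed,
                              prop_inside)
  n <- n_individuals(offspring)
  mother <- father <- rep(NA_character_, n)
  lod <- rep(NA_real_, n); tier <- rep("unassigned", n)
  mism <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (all(is.na(go[i, ]))) next
    sc <- parent_pair_lod(go[i, ], gf, gm, tabs, error_rate)
    j <- which.max(sc$lod)
    b <- sc$lod[j]
    if (!is.finite(b)) next
    tied <- sum(sc$lod >= b - 1e-9)
    unique_compat <- error_rate == 0 && sum(is.finite(sc$lod)) == 1
    if (tied > 1) next
    this_tier <- if (b >= thresholds["95%"]) "95%"
    else if (b >= thresholds["80%"]) "80%"
    else "unassigned"
    if (this_tier == "unassigned" && unique_compat) this_tier <- "95%"
    if (this_tier == "unassigned") next
    fi <- row(sc$lod)[j]; mi <- col(sc$lod)[j]
    mother[i] <- females$ind$id[fi]
    father[i] <- males$ind$id[mi]
    lod[i] <- b; tier[i] <- this_tier; mism[i] <- sc$mismatch[j]
  }
  mo <- match(mother, females$ind$id)
  fa <- match(father, males$ind$id)
  pollen <- sqrt((females$ind$x[mo] - males$ind$x[fa])^2 +
                 (females$ind$y[mo] - males$ind$y[fa])^2)
  seed <- sqrt((offspring$ind$x - females$ind$x[mo])^2 +
               (offspring$ind$y - females$ind$y[mo])^2)
  out <- data.frame(offspring = offspring$ind$id, mother = mother,
                    father = father, lod = lod, tier = tier, mismatch = mism,
                    pollen_dist = pollen, seed_dist = seed,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("parentage", "data.frame")
  out
}

# threshold calibration for parent pairs: in-pool pairs vs out-of-pool pairs
calibrate_pair_thresholds <- function(gf, gm, tabs, eps, n_sim, rng_seed,
                                      prop_inside = 0.5) {
  nf <- nrow(gf); nm <- nrow(gm)
  L <- length(tabs)
  with_seed(rng_seed, {
    inside <- stats::runif(n_sim) < prop_inside
    tf <- ifelse(inside, sample.int(nf, n_sim, TRUE), NA_integer_)
    tm <- ifelse(inside, sample.int(nm, n_sim, TRUE), NA_integer_)
    go <- matrix(NA_integer_, n_sim, L)
    for (l in seq_len(L)) {
      tb <- tabs[[l]]
      f_idx <- ifelse(inside, gf[tf, l], r_geno_idx(n_sim, tb))
      m_idx <- ifelse(inside, gm[tm, l], r_geno_idx(n_sim, tb))
      f_idx[is.na(f_idx)] <- r_geno_idx(sum(is.na(f_idx)), tb)
      m_idx[is.na(m_idx)] <- r_geno_idx(sum(is.na(m_idx)), tb)
      go[, l] <- r_offspring_idx(f_idx, m_idx, tb)
      if (eps > 0) {
        err <- stats::runif(n_sim) < eps
        if (any(err)) go[err, l] <- r_geno_idx(sum(err), tb)
      }
    }
    best_lod <- numeric(n_sim); correct <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      sc <- parent_pair_lod(go[i, ], gf, gm, tabs, eps)
      j <- which.max(sc$lod)
      best_lod[i] <- sc$lod[j]
      correct[i] <- inside[i] && row(sc$lod)[j] == tf[i] &&
        col(sc$lod)[j] == tm[i] && sum(sc$lod >= sc$lod[j] - 1e-9) == 1
    }
    usable <- is.finite(best_lod)
    ord <- order(best_lod[usable], decreasing = TRUE)
    acc <- cumsum(correct[usable][ord]) / seq_along(ord)
    thr_at <- function(target) {
      ok <- which(acc >= target)
      if (!length(ok)) return(Inf)
      best_lod[usable][ord][max(ok)]
    }
    c("95%" = thr_at(0.95), "80%" = thr_at(0.80))
  })
}

#' Estimate the genotyping-error rate from mother-offspring duos
#'
#' The fraction of co-typed locus comparisons where the offspring shares no
#' allele with its known mother — the standard field estimate of the
#' per-locus error probability fed to the parentage likelihood.
#'
#' @param offspring genotyped [population()] of offspring with known
#'   mothers.
#' @param mother_ids character vector of mother ids, one per offspring.
#' @param adults genotyped [population()] containing the mothers.
#' @return list: `epsilon` (the rate), `mismatches`, `comparisons`.
#' @export
estimate_genotyping_error <- function(offspring, mother_ids, adults) {
  stopifnot(length(mother_ids) == n_individuals(offspring))
  mi <- match(mother_ids, adults$ind$id)
  if (anyNA(mi)) stopf("unknown mother id(s)")
  mismatches <- 0L; comparisons <- 0L
  for (l in seq_along(offspring$loci)) {
    o1 <- offspring$geno[, l, 1]; o2 <- offspring$geno[, l, 2]
    m1 <- adults$geno[mi, l, 1]; m2 <- adults$geno[mi, l, 2]
    ok <- !is.na(o1) & !is.na(o2) & !is.na(m1) & !is.na(m2)
    comparisons <- comparisons + sum(ok)
    share <- o1 == m1 | o1 == m2 | o2 == m1 | o2 == m2
    mismatches <- mismatches + sum(ok & !share)
  }
  if (comparisons == 0) stopf("no co-typed mother-offspring locus comparisons")
  list(epsilon = mismatches / comparisons, mismatches = mismatches,
       comparisons = comparisons)
}
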