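# Fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (explicit loops over pairs, alleles and
# genotype configurations) and share no code path with the package.

# small deterministic population builder
make_pop <- function(genotypes, x = NULL, y = NULL, window = c(100, 100),
                     sex = NULL, dbh = NULL) {
  # genotypes: list of per-individual lists of c(a, b) per locus
  n <- length(genotypes)
  L <- length(genotypes[[1]])
  geno <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) geno[i, l, ] <- genotypes[[i]][[l]]
  ind <- data.frame(id = sprintf("t%02d", seq_len(n)),
                    x = x %||% seq(0, 50, length.out = n),
                    y = y %||% rep(0, n),
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) ind$sex <- sex
  if (!is.null(dbh)) ind$dbh <- dbh
  population(ind, geno, sprintf("L%02d", seq_len(L)), window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random genotyped population with arbitrary allele labels and missingness
make_random_pop <- function(n = 10, L = 3, k = 4, miss = 0.1, seed = 1,
                            window = c(200, 200)) {
  set.seed(seed)
  geno <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    p <- as.numeric(stats::rgamma(k, 1)); p <- p / sum(p)
    labels <- sort(sample(100:300, k))
    g <- cbind(sample(labels, n, TRUE, p), sample(labels, n, TRUE, p))
    drop <- stats::runif(n) < miss
    g[drop, ] <- NA_integer_
    geno[, l, ] <- g
  }
  ind <- data.frame(id = sprintf("r%03d", seq_len(n)),
                    x = stats::runif(n, 0, window[1]),
                    y = stats::runif(n, 0, window[2]),
                    stringsAsFactors = FALSE)
  population(ind, geno, sprintf("L%02d", seq_len(L)), window)
}

# --- brute-force Loiselle kinship: explicit per-allele loops ---------------
loiselle_oracle <- function(pop, ref = pop) {
  n <- nrow(pop$ind)
  Fm <- matrix(NA_real_, n, n)
  L <- length(pop$loci)
  # reference frequencies per locus from complete genotypes only
  refstats <- lapply(seq_len(L), function(l) {
    ok <- !is.na(ref$geno[, l, 1]) & !is.na(ref$geno[, l, 2])
    als <- c(ref$geno[ok, l, 1], ref$geno[ok, l, 2])
    tab <- table(als)
    list(alleles = as.integer(names(tab)), p = as.numeric(tab) / sum(tab),
         n_ind = sum(ok))
  })
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (l in seq_len(L)) {
      gi <- pop$geno[i, l, ]; gj <- pop$geno[j, l, ]
      if (any(is.na(gi)) || any(is.na(gj))) next
      rs <- refstats[[l]]
      w <- sum(rs$p * (1 - rs$p))
      if (w == 0 || rs$n_ind < 2) next
      s <- 0
      for (a in seq_along(rs$alleles)) {
        xa <- mean(gi == rs$alleles[a])
        ya <- mean(gj == rs$alleles[a])
        s <- s + (xa - rs$p[a]) * (ya - rs$p[a]) +
          rs$p[a] * (1 - rs$p[a]) / (rs$n_ind - 1)
      }
      num <- num + s; den <- den + w
    }
    Fm[i, j] <- Fm[j, i] <- if (den > 0) num / den else NA_real_
  }
  Fm
}

# --- brute-force exclusion probabilities: allele-tuple enumeration ---------
# All sums run over ordered allele draws, so every term is an exact product
# of allele frequencies; compatibility rules are written from first
# principles rather than via genotype tables.
exclusion_oracle <- function(p) {
  k <- length(p)
  al <- seq_len(k)
  shares <- function(o1, o2, c1, c2) any(c(c1, c2) %in% c(o1, o2))
  pair_compat <- function(o1, o2, m1, m2, f1, f2) {
    (o1 %in% c(m1, m2) && o2 %in% c(f1, f2)) ||
      (o2 %in% c(m1, m2) && o1 %in% c(f1, f2))
  }
  Q1 <- 0; Q2 <- 0; Qp <- 0
  for (m1 in al) for (m2 in al) for (f1 in al) for (f2 in al) {
    w_par <- p[m1] * p[m2] * p[f1] * p[f2]
    for (oi in 1:2) for (oj in 1:2) {
      o1 <- c(m1, m2)[oi]; o2 <- c(f1, f2)[oj]
      w_off <- w_par / 4
      for (c1 in al) for (c2 in al) {
        w <- w_off * p[c1] * p[c2]
        if (!shares(o1, o2, c1, c2)) Q1 <- Q1 + w
        if (!pair_compat(o1, o2, m1, m2, c1, c2)) Q2 <- Q2 + w
      }
    }
  }
  # parent pair: offspring is an independent HWE draw vs a random pair
  for (o1 in al) for (o2 in al) {
    w_o <- p[o1] * p[o2]
    for (m1 in al) for (m2 in al) for (f1 in al) for (f2 in al) {
      w <- w_o * p[m1] * p[m2] * p[f1] * p[f2]
      if (!pair_compat(o1, o2, m1, m2, f1, f2)) Qp <- Qp + w
    }
  }
  c(Q1 = Q1, Q2 = Q2, Qpair = Qp)
}

# allele_freqs object from explicit per-locus frequency vectors
freqs_from_list <- function(freq_list, n_genes = 200L) {
  loci <- lapply(freq_list, function(p) list(freq = p, n_genes = n_genes))
  names(loci) <- names(freq_list) %||% sprintf("L%02d", seq_along(freq_list))
  structure(list(loci = loci), class = "allele_freqs")
}

# equifrequent-allele population of a given sex, HWE genotypes
make_hwe_pop <- function(n, L = 9, k = 7, sex = "male", window = c(1000, 300),
                         prefix = "m") {
  geno <- array(sample.int(k, n * L * 2, TRUE), c(n, L, 2))
  ind <- data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
                    x = stats::runif(n, 0, window[1]),
                    y = stats::runif(n, 0, window[2]),
                    sex = sex, stringsAsFactors = FALSE)
  population(ind, geno, sprintf("L%02d", seq_len(L)), window)
}
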