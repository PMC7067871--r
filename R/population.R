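#' Mapped, sexed, genotyped population inside a rectangular plot
#'
#' A `population` bundles the three things every analysis in this package
#' needs: a table of individuals (id, planar coordinates in meters, dbh in
#' cm, sex, size-class cohort), a multilocus codominant genotype array, and
#' the rectangular observation window. Genotypes are unordered allele pairs
#' with integer labels (microsatellite fragment sizes or arbitrary codes);
#' either allele may be missing (`NA`).
#'
#' @param ind data.frame with columns `id`, `x`, `y` and optionally `dbh`,
#'   `sex` (one of `"male"`, `"female"`, `"undetermined"`) and `cohort`
#'   (`"I"`, `"II"`, `"III"` or `NA`). Missing `dbh` is allowed (`NA`).
#' @param geno integer array of dimension `n x n_loci x 2` (individuals,
#'   loci, the two alleles), or `NULL` for an ungenotyped population.
#'   `NA` marks a missing allele.
#' @param loci character vector of locus names (column names of `geno`).
#' @param window numeric length-2: width and height of the plot (m). The
#'   window is the axis-aligned rectangle `[0, width] x [0, height]`.
#' @return An object of class `"population"`.
#' @export
population <- function(ind, geno = NULL, loci = character(), window) {
  stopifnot(is.data.frame(ind))
  need <- c("id", "x", "y")
  if (!all(need %in% names(ind))) {
    stopf("individual table must have columns %s", paste(need, collapse = ", "))
  }
  ind$id <- as.character(ind$id)
  if (anyDuplicated(ind$id)) {
    stopf("duplicate individual id(s): %s",
          paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  window <- as.numeric(window)
  if (length(window) != 2 || any(!is.finite(window)) || any(window <= 0)) {
    stopf("window must be two positive numbers (width, height) in meters")
  }
  if (any(!is.finite(ind$x)) || any(!is.finite(ind$y))) {
    stopf("non-finite coordinates")
  }
  out_w <- ind$x < 0 | ind$x > window[1] | ind$y < 0 | ind$y > window[2]
  if (any(out_w)) {
    stopf("individual(s) outside the %g x %g window: %s", window[1], window[2],
          paste(utils::head(ind$id[out_w], 5), collapse = ", "))
  }
  if (is.null(ind$dbh)) ind$dbh <- NA_real_
  if (any(!is.na(ind$dbh) & ind$dbh < 0)) stopf("negative dbh")
  if (is.null(ind$sex)) ind$sex <- "undetermined"
  ind$sex <- as.character(ind$sex)
  bad_sex <- !ind$sex %in% c("male", "female", "undetermined")
  if (any(bad_sex)) stopf("invalid sex label(s): %s",
                          paste(unique(ind$sex[bad_sex]), collapse = ", "))
  if (is.null(ind$cohort)) ind$cohort <- NA_character_
  ind$cohort <- as.character(ind$cohort)
  bad_coh <- !is.na(ind$cohort) & !ind$cohort %in% c("I", "II", "III")
  if (any(bad_coh)) stopf("invalid cohort label(s)")

  loci <- as.character(loci)
  if (!is.null(geno)) {
    geno <- array(as.integer(geno), dim = dim(geno))
    if (length(dim(geno)) != 3 || dim(geno)[1] != nrow(ind) ||
        dim(geno)[2] != length(loci) || dim(geno)[3] != 2) {
      stopf("geno must be an n x n_loci x 2 array matching the locus list")
    }
    dimnames(geno) <- list(ind$id, loci, NULL)
  } else if (length(loci)) {
    stopf("loci declared but no genotype array given")
  }
  structure(list(ind = ind, geno = geno, loci = loci, window = window),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals in a %g x %g m window, %d loci\n",
              nrow(x$ind), x$window[1], x$window[2], length(x$loci)))
  tab <- table(factor(x$ind$sex, c("male", "female", "undetermined")))
  cat(sprintf("  sex: %d male / %d female / %d undetermined\n",
              tab[1], tab[2], tab[3]))
  if (any(!is.na(x$ind$cohort))) {
    ct <- table(factor(x$ind$cohort, c("I", "II", "III")))
    cat(sprintf("  cohorts: I=%d II=%d III=%d\n", ct[1], ct[2], ct[3]))
  }
  invisible(x)
}

n_individuals <- function(pop) nrow(pop$ind)

#' Assign diametric size classes from dbh
#'
#' Cohort I is `[0, b1)`, cohort II `[b1, b2]`, cohort III `(b2, Inf)`; with
#' the default breaks 10 and 20 cm a 10.0 or 20.0 cm stem is cohort II. The
#' boundary convention is configurable because field studies rarely state
#' how exact-boundary stems were classified.
#'
#' @param dbh numeric vector of diameters (cm), `NA` allowed.
#' @param breaks two increasing positive class boundaries (cm).
#' @return character vector of `"I"`, `"II"`, `"III"` (NA where dbh is NA).
#' @export
assign_size_class <- function(dbh, breaks = c(10, 20)) {
  stopifnot(length(breaks) == 2, breaks[1] > 0, breaks[2] > breaks[1])
  if (any(!is.na(dbh) & dbh < 0)) stopf("negative dbh")
  out <- rep(NA_character_, length(dbh))
  ok <- !is.na(dbh)
  out[ok & dbh < breaks[1]] <- "I"
  out[ok & dbh >= breaks[1] & dbh <= breaks[2]] <- "II"
  out[ok & dbh > breaks[2]] <- "III"
  out
}

#' Pairwise Euclidean distances between individuals
#'
#' @param pop a [population()].
#' @return symmetric n x n matrix of planar distances (m), zero diagonal.
#' @export
pairwise_distances <- function(pop) {
  if (n_individuals(pop) < 2) stopf("need at least two individuals")
  d <- as.matrix(stats::dist(cbind(pop$ind$x, pop$ind$y)))
  dimnames(d) <- list(pop$ind$id, pop$ind$id)
  d
}

#' Subset a population by individual id or logical/integer index
#' @param pop a [population()].
#' @param i character ids, or a logical/integer index into the table.
#' @export
subset_population <- function(pop, i) {
  if (is.character(i)) {
    idx <- match(i, pop$ind$id)
    if (anyNA(idx)) stopf("unknown id(s): %s",
                          paste(i[is.na(idx)], collapse = ", "))
  } else if (is.logical(i)) {
    stopifnot(length(i) == n_individuals(pop))
    idx <- which(i)
  } else {
    idx <- as.integer(i)
  }
  ind <- pop$ind[idx, , drop = FALSE]
  rownames(ind) <- NULL
  geno <- if (!is.null(pop$geno)) pop$geno[idx, , , drop = FALSE]
  population(ind, geno, pop$loci, pop$window)
}

#' Read a population from a delimited text file
#'
#' Expects columns `id`, `x`, `y`, `dbh`, `sex` plus one column per locus
#' holding `"a/b"` allele pairs, `"a/?"` for a half-missing call and `"?"`
#' (or `"?/?"`) for a fully missing locus. A `cohort` column is honoured if
#' present, otherwise cohorts are assigned from dbh via
#' [assign_size_class()]. Malformed rows are an error, never skipped.
#'
#' @param path file path of a comma-separated table.
#' @param window plot width and height (m).
#' @param sep field separator (default comma).
#' @return a [population()].
#' @export
read_population <- function(path, window, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("id", "x", "y")
  if (!all(need %in% names(df))) stopf("missing required column(s)")
  meta_cols <- intersect(c("id", "x", "y", "dbh", "sex", "cohort"), names(df))
  loci <- setdiff(names(df), meta_cols)
  n <- nrow(df)
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !(v %in% c("", "NA")))) stopf("malformed %s value", what)
    out
  }
  ind <- data.frame(id = df$id, x = num(df$x, "x"), y = num(df$y, "y"),
                    stringsAsFactors = FALSE)
  ind$dbh <- if ("dbh" %in% names(df)) num(df$dbh, "dbh") else NA_real_
  ind$sex <- if ("sex" %in% names(df)) df$sex else "undetermined"
  ind$cohort <- if ("cohort" %in% names(df)) {
    ifelse(df$cohort %in% c("", "NA"), NA_character_, df$cohort)
  } else assign_size_class(ind$dbh)

  geno <- NULL
  if (length(loci)) {
    geno <- array(NA_integer_, dim = c(n, length(loci), 2))
    for (l in seq_along(loci)) {
      g <- parse_genotypes(df[[loci[l]]], loci[l])
      geno[, l, ] <- g
    }
  }
  population(ind, geno, loci, window)
}

# "a/b" -> integer pair; "?" missing on either side; no other forms allowed.
parse_genotypes <- function(v, locus) {
  v <- trimws(v)
  v[v == "?"] <- "?/?"
  parts <- strsplit(v, "/", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stopf("malformed genotype '%s' at locus %s", v[bad][1], locus)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  conv <- function(a) {
    out <- rep(NA_integer_, length(a))
    known <- a != "?"
    val <- suppressWarnings(as.integer(a[known]))
    if (anyNA(val)) stopf("malformed allele label at locus %s", locus)
    out[known] <- val
    out
  }
  cbind(conv(m[, 1]), conv(m[, 2]))
}

#' Write a population to a delimited text file (round-trips with
#' [read_population()])
#' @param pop a [population()].
#' @param path output file path.
#' @export
write_population <- function(pop, path) {
  df <- pop$ind[c("id", "x", "y", "dbh", "sex", "cohort")]
  if (!is.null(pop$geno)) {
    for (l in seq_along(pop$loci)) {
      a1 <- pop$geno[, l, 1]; a2 <- pop$geno[, l, 2]
      s1 <- ifelse(is.na(a1), "?", as.character(a1))
      s2 <- ifelse(is.na(a2), "?", as.character(a2))
      df[[pop$loci[l]]] <- paste(s1, s2, sep = "/")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distance-class specification for autocorrelograms
#'
#' Classes are the half-open intervals `(0, b1], (b1, b2], ...`; pairs
#' beyond the last bound are not analyzed. The default follows the common
#' field design for a 1000 x 300 m plot: 20-m classes to 100 m, then 25-m
#' classes to 200 m.
#'
#' @param upper_bounds strictly increasing positive distances (m).
#' @return numeric vector of validated class bounds.
#' @export
distance_classes <- function(upper_bounds = default_distance_classes()) {
  b <- as.numeric(upper_bounds)
  if (!length(b) || any(!is.finite(b)) || any(b <= 0) ||
      is.unsorted(b, strictly = TRUE)) {
    stopf("upper_bounds must be strictly increasing positive distances")
  }
  b
}

#' @rdname distance_classes
#' @export
default_distance_classes <- function() c(20, 40, 60, 80, 100, 125, 150, 175, 200)

#' Diagnostics for a population: missing data, monomorphic loci, cohorts
#'
#' @param pop a [population()].
#' @return list with `per_locus` (missing-data rate, allele count,
#'   monomorphic flag per locus), `cohort_counts`, `sex_counts` and
#'   `n`. Monomorphic loci are flagged unusable for kinship.
#' @export
validate_population <- function(pop) {
  n <- n_individuals(pop)
  per_locus <- NULL
  if (!is.null(pop$geno)) {
    miss <- vapply(seq_along(pop$loci), function(l) {
      mean(is.na(pop$geno[, l, 1]) | is.na(pop$geno[, l, 2]))
    }, numeric(1))
    n_all <- vapply(seq_along(pop$loci), function(l) {
      length(unique(stats::na.omit(c(pop$geno[, l, ]))))
    }, integer(1))
    per_locus <- data.frame(locus = pop$loci, missing_rate = miss,
                            n_alleles = n_all, monomorphic = n_all <= 1,
                            stringsAsFactors = FALSE)
  }
  list(n = n,
       per_locus = per_locus,
       cohort_counts = table(factor(pop$ind$cohort, c("I", "II", "III"))),
       sex_counts = table(factor(pop$ind$sex,
                                 c("male", "female", "undetermined"))))
}
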