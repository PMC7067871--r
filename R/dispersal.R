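#' Dispersal distance sample from a parentage assignment table
#'
#' The three field definitions: `effective_pollen` and `realized_pollen`
#' are the mother-father distance (from paternity on embryos and from
#' parent-pair assignment on seedlings respectively); `realized_seed` is
#' the offspring-mother distance. Only assigned rows contribute; the count
#' of unassigned offspring rides along (they are usually read as parents
#' outside the plot).
#'
#' @param assignments a `"parentage"` table from [assign_paternity()] or
#'   [assign_parent_pair()].
#' @param mode one of `"effective_pollen"`, `"realized_pollen"`,
#'   `"realized_seed"`.
#' @return list of class `"dispersal_sample"`: `mode`, `distances` (m),
#'   `n_assigned`, `n_unassigned`.
#' @export
dispersal_distances <- function(assignments,
                                mode = c("effective_pollen",
                                         "realized_pollen", "realized_seed")) {
  mode <- match.arg(mode)
  col <- if (mode == "realized_seed") "seed_dist" else "pollen_dist"
  if (is.null(assignments[[col]])) {
    stopf("assignment table carries no %s column for mode %s", col, mode)
  }
  if (mode == "realized_seed" && is.null(assignments$seed_dist)) {
    stopf("seed distances need a parent-pair assignment")
  }
  d <- assignments[[col]]
  keep <- !is.na(assignments$father) & !is.na(d)
  if (mode == "realized_seed") keep <- !is.na(assignments$mother) & !is.na(d)
  structure(list(mode = mode, distances = d[keep],
                 n_assigned = sum(keep), n_unassigned = sum(!keep)),
            class = "dispersal_sample")
}

#' @export
print.dispersal_sample <- function(x, ...) {
  cat(sprintf("%s: %d assigned (%d unassigned), median %.1f m\n", x$mode,
              x$n_assigned, x$n_unassigned, stats::median(x$distances)))
  invisible(x)
}

as_distances <- function(sample) {
  if (inherits(sample, "dispersal_sample")) sample$distances
  else as.numeric(sample)
}

#' Proportions of dispersal events per distance band
#'
#' Fractions of distances in `[0, b1], (b1, b2], ..., (b_k, Inf)`. The
#' default breaks 150 and 600 m mirror the bands in which tropical-tree
#' dispersal results are commonly reported.
#'
#' @param sample a `dispersal_sample` or numeric distances (m).
#' @param breaks strictly increasing band edges (m).
#' @return named numeric vector of proportions (sums to 1).
#' @export
band_proportions <- function(sample, breaks = c(150, 600)) {
  d <- as_distances(sample)
  if (!length(d)) stopf("empty sample")
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE)) stopf("breaks must increase")
  edges <- c(-Inf, breaks, Inf)
  cnt <- table(cut(d, edges, right = TRUE))
  labs <- c(sprintf("<=%gm", breaks),
            sprintf(">%gm", breaks[length(breaks)]))
  stats::setNames(as.numeric(cnt) / length(d), labs)
}

#' Summary of a dispersal kernel sample
#'
#' @param sample a `dispersal_sample` or numeric distances (m).
#' @return named vector: `n`, `mean`, `se` (sd/sqrt(n), `NA` for n = 1),
#'   `median`, `min`, `max`.
#' @export
kernel_summary <- function(sample) {
  d <- as_distances(sample)
  if (!length(d)) stopf("empty sample")
  c(n = length(d), mean = mean(d),
    se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
    median = stats::median(d), min = min(d), max = max(d))
}

#' Compare two dispersal kernels
#'
#' Two-sample Kolmogorov-Smirnov statistic plus per-band proportion
#' differences, and a directional verdict: `"b larger"` when b's empirical
#' CDF is at or below a's at every break (b stochastically larger),
#' symmetric for `"a larger"`, else `"mixed"`. Comparing the effective
#' (pre-thinning) with the realized (established) kernel this way is the
#' genetic probe for Janzen-Connell recruitment: distance-dependent
#' mortality shifts the realized kernel outward.
#'
#' @param a,b `dispersal_sample`s or numeric distance vectors (m).
#' @param breaks band edges (m) for the proportion deltas.
#' @return list: `D`, `p`, `bands` (data.frame of proportions and delta),
#'   `verdict`.
#' @export
compare_kernels <- function(a, b, breaks = c(150, 600)) {
  da <- as_distances(a); db <- as_distances(b)
  if (!length(da) || !length(db)) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(da, db, exact = FALSE))
  pa <- band_proportions(da, breaks)
  pb <- band_proportions(db, breaks)
  bands <- data.frame(band = names(pa), prop_a = as.numeric(pa),
                      prop_b = as.numeric(pb),
                      delta = as.numeric(pb - pa))
  ecdf_a <- stats::ecdf(da); ecdf_b <- stats::ecdf(db)
  at <- breaks
  verdict <- if (identical(da, db)) "equal"
  else if (all(ecdf_b(at) <= ecdf_a(at))) "b larger"
  else if (all(ecdf_a(at) <= ecdf_b(at))) "a larger"
  else "mixed"
  list(D = unname(kt$statistic), p = kt$p.value, bands = bands,
       verdict = verdict)
}

#' Progeny-count fitness regression
#'
#' Ordinary least squares of the number of established progeny assigned to
#' each adult on a predictor (dbh, or distance), the standard realized-
#' fitness screen after parentage assignment.
#'
#' @param progeny_counts nonnegative counts, one per adult.
#' @param predictor numeric predictor of the same length, non-constant.
#' @return list: `slope`, `intercept`, `r_squared`, `p` (two-sided slope
#'   test), `n`.
#' @export
fitness_regression <- function(progeny_counts, predictor) {
  stopifnot(length(progeny_counts) == length(predictor))
  ok <- !is.na(progeny_counts) & !is.na(predictor)
  y <- progeny_counts[ok]; x <- predictor[ok]
  if (length(y) < 3) stopf("need at least three adults")
  if (stats::var(x) == 0) stopf("constant predictor")
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = 1,
                n = length(y)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(y))
}

#' Count established progeny per adult from an assignment table
#'
#' @param assignments a `"parentage"` table.
#' @param adults adult [population()].
#' @param role count per `"father"` (sired progeny) or `"mother"`.
#' @return named integer vector over all adults (zeros included).
#' @export
progeny_counts <- function(assignments, adults, role = c("father", "mother")) {
  role <- match.arg(role)
  ids <- assignments[[role]]
  cnt <- table(factor(ids[!is.na(ids)], levels = adults$ind$id))
  stats::setNames(as.integer(cnt), adults$ind$id)
}
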