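#' Ripley isotropic edge correction on a rectangular window
#'
#' Fraction of the circle centred at `(x, y)` with radius `r` that lies
#' inside the rectangle `[0, w] x [0, h]`. Each edge closer than `r`
#' removes an arc of `2 * acos(d_edge / r)`; where two adjacent edges are
#' both crossed and the corner is inside the circle the two arcs overlap by
#' `acos(d1/r) + acos(d2/r) - pi/2`, which is added back. Valid for
#' `r <= min(w, h) / 2`.
#'
#' @param x,y circle centres inside the window.
#' @param r radii (recycled against `x`).
#' @param window width and height (m).
#' @return numeric vector of inside fractions in (0, 1].
#' @keywords internal
ripley_fraction_inside <- function(x, y, r, window) {
  w <- window[1]; h <- window[2]
  d <- cbind(x, w - x, y, h - y)   # left, right, bottom, top
  r <- rep_len(r, length(x))
  out <- numeric(length(x))
  pos <- r > 0
  if (any(pos)) {
    ratio <- pmin(d[pos, , drop = FALSE] / r[pos], 1)
    arcs <- 2 * acos(ratio)                    # zero when edge beyond r
    a <- acos(ratio)
    # corners: (left,bottom) (left,top) (right,bottom) (right,top)
    corner_pairs <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
    overlap <- 0
    for (k in seq_len(4)) {
      o <- a[, corner_pairs[k, 1]] + a[, corner_pairs[k, 2]] - pi / 2
      overlap <- overlap + pmax(o, 0)
    }
    out[pos] <- rowSums(arcs) - overlap
  }
  1 - out / (2 * pi)
}

#' Bivariate Ripley's K12 and L12 on a rectangular plot
#'
#' \eqn{\hat K_{12}(t) = \frac{|A|}{n_1 n_2} \sum_{i \in 1}\sum_{j \in 2}
#' \mathbf{1}(d_{ij} \le t) / c_{ij}} with the isotropic edge correction
#' `c_ij` = fraction of the circle centred on the class-1 point `i` with
#' radius `d_ij` inside the window. `L12(t) = sqrt(K12(t)/pi) - t` is zero
#' in expectation under independence of the two classes; positive values
#' indicate spatial association, negative repulsion. A symmetrized
#' estimator averaging circles on both classes is available.
#'
#' @param points_a,points_b two-column matrices (or data.frames) of
#'   coordinates of the two classes.
#' @param window plot width and height (m).
#' @param t_grid evaluation distances, each in `(0, min(window)/2]`.
#' @param symmetrized average the two directed estimators.
#' @return data.frame of class `"ripley12"`: `t`, `K12`, `L12`.
#' @export
ripley_l12 <- function(points_a, points_b, window,
                       t_grid = seq(5, 150, by = 5), symmetrized = FALSE) {
  pa <- as.matrix(points_a); pb <- as.matrix(points_b)
  if (!nrow(pa) || !nrow(pb)) stopf("empty point set")
  t_grid <- as.numeric(t_grid)
  if (any(t_grid <= 0) || any(t_grid > min(window) / 2)) {
    stopf("t values must lie in (0, %g]", min(window) / 2)
  }
  K <- k12_directed(pa, pb, window, t_grid)
  if (symmetrized) K <- (K + k12_directed(pb, pa, window, t_grid)) / 2
  structure(data.frame(t = t_grid, K12 = K, L12 = sqrt(K / pi) - t_grid),
            class = c("ripley12", "data.frame"))
}

# directed K12 with circles centred on class-a points
k12_directed <- function(pa, pb, window, t_grid) {
  n1 <- nrow(pa); n2 <- nrow(pb)
  area <- window[1] * window[2]
  acc <- numeric(length(t_grid))
  tmax <- max(t_grid)
  for (i in seq_len(n1)) {
    d <- sqrt((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2)
    sel <- d <= tmax
    if (!any(sel)) next
    ds <- d[sel]
    wgt <- 1 / ripley_fraction_inside(rep(pa[i, 1], length(ds)),
                                      rep(pa[i, 2], length(ds)), ds, window)
    # accumulate into the grid: each pair contributes to all t >= d
    ord <- order(ds)
    cum <- cumsum(wgt[ord])
    idx <- findInterval(t_grid, ds[ord])
    acc <- acc + ifelse(idx > 0, cum[pmax(idx, 1)], 0)
  }
  area / (n1 * n2) * acc
}

#' Random-labeling envelope for bivariate L12
#'
#' Holds the pooled locations fixed and reassigns the class labels
#' (`n1` of class a) uniformly at random `n_perm` times, recomputing `L12`
#' each time. The pointwise order-statistic 95% envelope classifies each
#' `t`: association where the observed `L12` exceeds the upper envelope,
#' repulsion below the lower one, random in between.
#'
#' @inheritParams ripley_l12
#' @param n_perm number of label permutations (>= 39; field studies use 999).
#' @param rng_seed integer seed.
#' @return data.frame of class `"ripley12"`: `t`, `K12`, `L12`,
#'   `env_lower`, `env_upper`, `verdict`.
#' @export
random_labeling_envelope <- function(points_a, points_b, window,
                                     t_grid = seq(5, 150, by = 5),
                                     n_perm = 999, rng_seed = NULL,
                                     symmetrized = FALSE) {
  stopifnot(n_perm >= 39)
  pa <- as.matrix(points_a); pb <- as.matrix(points_b)
  n1 <- nrow(pa); n2 <- nrow(pb)
  if (n1 + n2 < 2) stopf("need at least two points")
  obs <- ripley_l12(pa, pb, window, t_grid, symmetrized)
  pooled <- rbind(pa, pb)
  null <- with_seed(rng_seed, {
    m <- matrix(NA_real_, n_perm, length(t_grid))
    for (b in seq_len(n_perm)) {
      lab <- sample.int(n1 + n2, n1)
      K <- k12_directed(pooled[lab, , drop = FALSE],
                        pooled[-lab, , drop = FALSE], window, t_grid)
      if (symmetrized) {
        K <- (K + k12_directed(pooled[-lab, , drop = FALSE],
                               pooled[lab, , drop = FALSE], window, t_grid)) / 2
      }
      m[b, ] <- sqrt(K / pi) - t_grid
    }
    m
  })
  env <- apply(null, 2, perm_envelope)
  obs$env_lower <- env[1, ]
  obs$env_upper <- env[2, ]
  obs$verdict <- ifelse(obs$L12 > obs$env_upper, "association",
                        ifelse(obs$L12 < obs$env_lower, "repulsion", "random"))
  obs
}
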