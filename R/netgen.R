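# Spatial generation of weighted interaction networks and their measurement.
#
# Individuals are scattered in the unit square, nudged toward their nearest
# neighbour, and connected with a Gaussian decay kernel of the pairwise
# distance. An optional similarity multiplier models homophily/heterophily on
# the nonplastic phenotype, and weak edges are removed by a hard threshold.

#' Sample individual positions in the unit square
#'
#' Draws `n` independent positions with both coordinates uniform on \[0, 1\].
#' Positions are the spatial substrate from which interaction strengths decay.
#'
#' @param n Number of individuals (at least 2).
#' @return A tibble with columns `id`, `x`, `y`.
#' @examples
#' set.seed(1)
#' sample_positions(5)
#' @export
sample_positions <- function(n) {
  check_group_size(n)
  tibble(id = seq_len(n), x = runif(n), y = runif(n))
}

#' Move each individual toward its nearest neighbour
#'
#' Every individual is displaced along the segment to its nearest neighbour by
#' `fraction` of the distance between them. The move is a single synchronous
#' step: nearest neighbours and displacements are computed from the input
#' configuration, so the result does not depend on individual ordering.
#' Nearest-neighbour ties are broken toward the lowest id. Moving toward an
#' interior point cannot leave the unit square.
#'
#' @param points A tibble of positions as returned by [sample_positions()].
#' @param fraction Proportion of the nearest-neighbour distance to move,
#'   in \[0, 1). Default 0.15.
#' @return A tibble of the same shape with updated `x`, `y`.
#' @examples
#' pts <- tibble::tibble(id = 1:2, x = c(0, 1), y = c(0, 0))
#' attract_to_nearest(pts, 0.15)
#' @export
attract_to_nearest <- function(points, fraction = 0.15) {
  stopifnot(is.data.frame(points), nrow(points) >= 2)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction >= 1) {
    abort("`fraction` must be a single value in [0, 1).")
  }
  xy <- as.matrix(points[, c("x", "y")])
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  # max.col with ties.method = "first" on -d picks the lowest-index minimum
  nn <- max.col(-d, ties.method = "first")
  new_xy <- xy + fraction * (xy[nn, , drop = FALSE] - xy)
  out <- points
  out$x <- new_xy[, 1]
  out$y <- new_xy[, 2]
  out
}

#' Distance-decay connection strengths
#'
#' Connection strength between two individuals is `exp(-d^2 / r)` with `d`
#' their Euclidean distance and `r` the interaction range. `r = 0` is taken as
#' the kernel limit from above: the empty network (all off-diagonal weights 0).
#'
#' @param points A tibble of positions (`x`, `y` columns).
#' @param r Interaction range, `r >= 0`. Larger `r` strengthens all dyads.
#' @return An n-by-n symmetric weight matrix with zero diagonal.
#' @examples
#' pts <- tibble::tibble(id = 1:2, x = c(0, 0.5), y = c(0, 0))
#' base_weights(pts, r = 1)[1, 2] # exp(-0.25)
#' @export
base_weights <- function(points, r) {
  stopifnot(is.data.frame(points))
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0) {
    abort("`r` must be a single nonnegative interaction range.")
  }
  n <- nrow(points)
  d2 <- as.matrix(dist(as.matrix(points[, c("x", "y")])))^2
  if (r == 0) {
    w <- matrix(0, n, n)
  } else {
    w <- exp(-d2 / r)
    diag(w) <- 0
  }
  dimnames(w) <- NULL
  w
}

#' Phenotype-similarity multiplier
#'
#' Sigmoidal preference weighting of an interaction by the absolute trait
#' difference of the two individuals. With `L(d) = 1 / (1 + exp(20 * (d -
#' 0.5)))`, the multiplier is `0.5 + H * L(d)` under homophily and
#' `0.5 - H * L(d)` under heterophily, so it stays within `0.5 +/- H`: near
#' `0.5 + H` (or `0.5 - H`) for identical individuals and 0.5 when the trait
#' difference is at the average scale 0.5. Mode `"none"` bypasses the
#' preference entirely (multiplier 1).
#'
#' @param trait_diff Nonnegative absolute trait difference(s).
#' @param H Homophily magnitude in \[0, 0.5\].
#' @param mode One of `"none"`, `"homophily"`, `"heterophily"`.
#' @return Multiplier value(s), same length as `trait_diff`.
#' @export
similarity_multiplier <- function(trait_diff, H,
                                  mode = c("none", "homophily", "heterophily")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(rep(1, length(trait_diff)))
  }
  if (!is.numeric(H) || length(H) != 1 || is.na(H) || H < 0 || H > 0.5) {
    abort("`H` must be a single value in [0, 0.5].")
  }
  stopifnot(all(trait_diff >= 0))
  sigma <- if (mode == "homophily") 1 else -1
  0.5 + sigma * H * stats::plogis(-20 * (trait_diff - 0.5))
}

#' Apply phenotype-based interaction preference to a weight matrix
#'
#' Multiplies every dyadic weight by [similarity_multiplier()] of the pair's
#' absolute trait difference. The trait used is the nonplastic phenotype
#' `a + e`, so preferences do not depend on the network they shape. Symmetry
#' and the zero diagonal are preserved.
#'
#' @param w Symmetric weight matrix.
#' @param traits Per-individual trait values, length `nrow(w)`.
#' @inheritParams similarity_multiplier
#' @return Weight matrix of the same dimension.
#' @export
apply_similarity <- function(w, traits,
                             H = 0,
                             mode = c("none", "homophily", "heterophily")) {
  mode <- match.arg(mode)
  check_weight_matrix(w)
  if (length(traits) != nrow(w)) {
    abort("`traits` must have one value per row of `w`.")
  }
  if (mode == "none") {
    return(w)
  }
  dif <- abs(outer(traits, traits, "-"))
  m <- matrix(similarity_multiplier(dif, H, mode), nrow(w), ncol(w))
  out <- w * m
  diag(out) <- 0
  out
}

#' Remove weak edges
#'
#' Sets every weight strictly below `cutoff` to zero; weights equal to the
#' cutoff are retained. The default 0.05 prevents the decay kernel from
#' producing a fully connected network at every range.
#'
#' @param w Weight matrix.
#' @param cutoff Threshold in \[0, 1\]. Default 0.05.
#' @return Thresholded weight matrix.
#' @export
threshold_weights <- function(w, cutoff = 0.05) {
  check_weight_matrix(w)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  w[w < cutoff] <- 0
  w
}

#' Weighted network density
#'
#' The sum of realized edge weights divided by the maximum possible sum were
#' every dyad connected at weight 1; equivalently the mean dyadic weight. This
#' is the mean connection strength of the group.
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @return Density in \[0, 1\].
#' @export
network_density <- function(w) {
  check_weight_matrix(w)
  n <- nrow(w)
  if (n < 2) abort("density needs at least 2 individuals.")
  sum(w[upper.tri(w)]) / (n * (n - 1) / 2)
}

#' Weighted continuous-trait assortativity
#'
#' Newman-style assortativity coefficient for a continuous trait on a weighted
#' undirected network, with each undirected edge counted once in each
#' direction. Writing `W` for the total directed weight and `xbar_w` for the
#' weight-averaged trait over edge origins, the coefficient is
#' `(sum(w_ij x_i x_j)/W - xbar_w^2) / (sum(w_ij x_i^2)/W - xbar_w^2)`.
#' Positive values indicate that strong edges join similar trait values.
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @param traits Per-individual trait values.
#' @return Assortativity in \[-1, 1\], or `NA` when the network is empty or
#'   the trait has no variance over edge ends.
#' @export
weighted_assortativity <- function(w, traits) {
  check_weight_matrix(w)
  if (length(traits) != nrow(w)) {
    abort("`traits` must have one value per row of `w`.")
  }
  W <- sum(w)
  if (W <= 0) {
    return(NA_real_)
  }
  x <- traits
  xbar <- sum(w * x) / W          # row-wise: sum_ij w_ij * x_i
  cross <- sum(w * outer(x, x)) / W
  sq <- sum(w * x^2) / W
  den <- sq - xbar^2
  if (den <= .Machine$double.eps * max(1, sq)) {
    return(NA_real_)
  }
  (cross - xbar^2) / den
}

#' Density and assortativity of one network
#'
#' Convenience wrapper returning both metrics as a one-row tibble; this is the
#' entry point for measuring user-supplied networks (see [read_edge_csv()]).
#'
#' @inheritParams weighted_assortativity
#' @return A tibble with columns `density`, `assortativity`.
#' @export
network_metrics <- function(w, traits) {
  tibble(
    density = network_density(w),
    assortativity = weighted_assortativity(w, traits)
  )
}

check_group_size <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2 || n != round(n)) {
    abort("group size `n` must be a single integer >= 2.")
  }
  invisible(as.integer(n))
}

check_weight_matrix <- function(w) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w)) {
    abort("`w` must be a square numeric matrix.")
  }
  invisible(w)
}
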