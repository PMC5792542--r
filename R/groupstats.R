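# Per-group summary statistics: the quantities tracked across density and
# homophily sweeps, including the covariance-based response to selection.

#' Summarise one group
#'
#' Computes the per-group statistics of the interacting-phenotype model from a
#' table of individuals and the final weight matrix. All sample statistics use
#' the n - 1 denominator; undefined correlations propagate as `NA`, never 0.
#'
#' Fields returned:
#' \describe{
#'   \item{mean_z}{group mean phenotype.}
#'   \item{var_indirect}{variance across individuals of the realized indirect
#'     contribution `psi_g * eta`.}
#'   \item{corr_direct_indirect}{Pearson correlation between the nonplastic
#'     value `a + e` and the social environment `eta`.}
#'   \item{var_z, var_z_ratio}{phenotypic variance, and its ratio to
#'     `Var(a + e)` (the variance absent interactions).}
#'   \item{var_t, var_t_ratio}{variance of total breeding values, and its
#'     ratio to `Var(a)`.}
#'   \item{response}{predicted one-generation change in mean phenotype under a
#'     linear selection gradient: `beta * Cov(t, z)` (Robertson-Price).}
#'   \item{r_hat}{empirical genetic-assortment coefficient
#'     `Cov(a_i, ahat_i) / Var(a)`, where `ahat_i` is the weight-averaged mean
#'     of i's partners' breeding values; individuals with no partners are
#'     excluded, and `NA` is returned if fewer than 2 remain.}
#' }
#'
#' @param individuals A tibble with columns `a`, `e`, `eta`, `z`, `t` (one row
#'   per individual), e.g. the `individuals` element of [run_group()].
#' @param w The final (thresholded) weight matrix.
#' @param psi_g Interaction coefficient used to generate the group.
#' @param beta Linear selection gradient. Default 0.2.
#' @return A one-row tibble.
#' @export
summarize_group <- function(individuals, w, psi_g, beta = 0.2) {
  stopifnot(is.data.frame(individuals))
  check_weight_matrix(w)
  n <- nrow(individuals)
  if (n < 3) abort("group summaries need at least 3 individuals.")
  if (nrow(w) != n) abort("`w` must match the number of individuals.")
  a <- individuals$a
  e <- individuals$e
  eta <- individuals$eta
  z <- individuals$z
  t <- individuals$t
  direct <- a + e

  var_direct <- var(direct)
  var_a <- var(a)
  corr_di <- if (var_direct > 0 && var(eta) > 0) cor(direct, eta) else NA_real_
  var_z <- var(z)

  tibble(
    mean_z = mean(z),
    var_indirect = var(psi_g * eta),
    corr_direct_indirect = corr_di,
    var_z = var_z,
    var_z_ratio = if (var_direct > 0) var_z / var_direct else NA_real_,
    var_t = var(t),
    var_t_ratio = if (var_a > 0) var(t) / var_a else NA_real_,
    response = beta * cov(t, z),
    r_hat = genetic_assortment(w, a)
  )
}

#' Empirical genetic assortment
#'
#' `Cov(a_i, ahat_i) / Var(a)` with `ahat_i = sum_j w_ij a_j / (n - 1)`, the
#' connection-weighted mean of i's partners' breeding values under the same
#' `n - 1` divisor convention as the social environment, so that the
#' coefficient measures how strongly an individual's genes covary with the
#' genetic part of the social environment it experiences, per unit of genetic
#' variance. Plays the role relatedness plays in dyadic
#' indirect-genetic-effect models; slightly negative under random association
#' in dense networks because individuals are excluded from their own social
#' environment. Individuals with no partners are excluded from the
#' covariance.
#'
#' @inheritParams total_breeding_values
#' @return A scalar, or `NA` if fewer than 2 individuals have partners or
#'   `Var(a)` is zero.
#' @export
genetic_assortment <- function(w, a) {
  check_weight_matrix(w)
  n <- nrow(w)
  connected <- rowSums(w) > 0
  if (sum(connected) < 2) return(NA_real_)
  var_a <- var(a)
  if (!(var_a > 0)) return(NA_real_)
  ahat <- as.numeric(w[connected, , drop = FALSE] %*% a) / (n - 1)
  cov(a[connected], ahat) / var_a
}

#' Dispersion of summaries among groups
#'
#' Variance across groups of the group mean phenotype, of the response to
#' selection, and of the relative phenotypic variance. Captures the fan-out of
#' group outcomes as density or assortment grows.
#'
#' @param summaries A tibble of group summaries (rows from
#'   [summarize_group()] or a sweep table).
#' @return A one-row tibble with `n_groups`, `var_mean_z`, `var_response`,
#'   `var_var_z_ratio`.
#' @export
among_group_dispersion <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) < 2) abort("dispersion needs at least 2 groups.")
  tibble(
    n_groups = nrow(summaries),
    var_mean_z = var(summaries$mean_z),
    var_response = var(summaries$response),
    var_var_z_ratio = var(summaries$var_z_ratio)
  )
}
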