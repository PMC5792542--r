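# Genetic and environmental sampling, and the no-feedback interacting
# phenotype model: z = a + e + psi_g * eta, with eta the weighted mean of
# partners' nonplastic values scaled by 1/(n - 1).

#' Sample direct breeding values
#'
#' Draws per-individual additive genetic values from a centred distribution:
#' uniform on \[-1, 1\] (variance 1/3) or standard normal (variance 1).
#'
#' @param n Number of individuals (at least 2).
#' @param dist `"uniform_pm1"` (default) or `"normal_01"`.
#' @return Numeric vector of length `n`.
#' @export
sample_breeding_values <- function(n, dist = c("uniform_pm1", "normal_01")) {
  check_group_size(n)
  dist <- match.arg(dist)
  switch(dist,
    uniform_pm1 = runif(n, -1, 1),
    normal_01 = rnorm(n)
  )
}

#' Sample nonsocial environmental deviations
#'
#' Independent normal draws with mean 0 and the given variance. The default
#' variance used throughout the simulations is 0.0625 (sd 0.25).
#'
#' @param n Number of individuals.
#' @param variance Environmental variance, `>= 0`. Default 0.0625.
#' @return Numeric vector of length `n`.
#' @export
sample_env <- function(n, variance = 0.0625) {
  check_group_size(n)
  if (!is.numeric(variance) || length(variance) != 1 || is.na(variance) ||
      variance < 0) {
    abort("`variance` must be a single nonnegative number.")
  }
  rnorm(n, mean = 0, sd = sqrt(variance))
}

#' Social environment experienced by each individual
#'
#' `eta_i = (1 / (n - 1)) * sum_{j != i} w_ij * (a_j + e_j)`: the focal
#' individual's connection-weighted mean of its partners' nonplastic values.
#' The divisor is `n - 1` (the number of possible partners), not the sum of
#' weights, so eta scales with realized connection strength and vanishes on
#' the empty network. Individual i's own values never enter `eta_i`.
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @param a Direct breeding values.
#' @param e Environmental deviations.
#' @return Numeric vector `eta` of length `n`.
#' @export
social_environment <- function(w, a, e) {
  check_weight_matrix(w)
  n <- nrow(w)
  if (n < 2) abort("social environment needs at least 2 individuals.")
  if (length(a) != n || length(e) != n) {
    abort("`a` and `e` must each have one value per row of `w`.")
  }
  as.numeric(w %*% (a + e)) / (n - 1)
}

#' Individual phenotypes under social plasticity
#'
#' `z = a + e + psi_g * eta`. The interaction coefficient `psi_g` scales how
#' strongly the focal phenotype tracks the social environment: positive
#' values converge toward partners, negative values diverge.
#'
#' @param a Direct breeding values.
#' @param e Environmental deviations.
#' @param eta Social environment values from [social_environment()].
#' @param psi_g Interaction coefficient (shared by all individuals).
#' @return Numeric vector `z`.
#' @export
phenotypes <- function(a, e, eta, psi_g) {
  stopifnot(length(a) == length(e), length(a) == length(eta),
            is.numeric(psi_g), length(psi_g) == 1)
  a + e + psi_g * eta
}

#' Total breeding values
#'
#' An individual's total breeding value is its direct breeding value plus the
#' effect of its genes on group-mates via indirect genetic effects:
#' `t_i = a_i * (1 + psi_g * mean_j w_ij)`, where the mean outgoing
#' connection strength uses the `n - 1` divisor. On an equal-weight complete
#' network with weight `s`, this is the linear map `t = a * (1 + psi_g * s)`,
#' so `Var(t) = (1 + psi_g * s)^2 * Var(a)` exactly.
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @param a Direct breeding values.
#' @param psi_g Interaction coefficient.
#' @return Numeric vector `t` of length `n`.
#' @export
total_breeding_values <- function(w, a, psi_g) {
  check_weight_matrix(w)
  n <- nrow(w)
  if (length(a) != n) abort("`a` must have one value per row of `w`.")
  stopifnot(is.numeric(psi_g), length(psi_g) == 1)
  s_i <- rowSums(w) / (n - 1)
  a * (1 + psi_g * s_i)
}
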