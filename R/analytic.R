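# Closed-form predictions of the no-feedback interacting-phenotype model,
# used to cross-validate the simulator.

#' Predicted group mean phenotype
#'
#' `(1 + psi_g * s_bar) * a_bar`: social plasticity amplifies the group's mean
#' genetic value in proportion to mean connection strength. With centred
#' breeding values the expected mean is 0 at every density.
#'
#' @param psi_g Interaction coefficient.
#' @param s_bar Mean connection strength (network density), in \[0, 1\].
#' @param a_bar Mean direct breeding value of the group.
#' @return Predicted mean phenotype.
#' @export
predict_mean <- function(psi_g, s_bar, a_bar) {
  (1 + psi_g * s_bar) * a_bar
}

#' Predicted within-group phenotypic variance
#'
#' `G + E + psi_g^2 * var_social + 2 * psi_g * cov_direct_social`, where
#' `var_social` is the variance among individuals of the social environment
#' they experience and `cov_direct_social` the covariance between the
#' nonplastic value and the social environment. Fed a group's own sample
#' moments, this is an exact algebraic decomposition of the sample `Var(z)`,
#' since the phenotype equation is linear.
#'
#' @param G Additive genetic variance.
#' @param E Environmental variance.
#' @param psi_g Interaction coefficient.
#' @param var_social Variance of the social environment (`Var(eta)`).
#' @param cov_direct_social Covariance of `a + e` with the social environment.
#' @return Predicted phenotypic variance.
#' @export
predict_variance <- function(G, E, psi_g, var_social, cov_direct_social) {
  stopifnot(all(G >= 0), all(E >= 0), all(var_social >= 0))
  G + E + psi_g^2 * var_social + 2 * psi_g * cov_direct_social
}

#' Predicted response to selection
#'
#' `(1 + psi_g * s_bar) * G * (1 + R * psi_g) * beta`: the breeder's equation
#' `G * beta` amplified by mean connection strength and by genetic assortment
#' `R` (homophily playing the role of relatedness). The expression is an
#' approximation; agreement with simulation is assessed with Monte-Carlo
#' tolerance bands.
#'
#' @param psi_g Interaction coefficient.
#' @param s_bar Mean connection strength (network density).
#' @param G Additive genetic variance.
#' @param R Genetic-assortment coefficient (0 under random association).
#' @param beta Linear selection gradient.
#' @return Predicted change in mean phenotype over one generation.
#' @export
predict_response <- function(psi_g, s_bar, G, R = 0, beta = 0.2) {
  (1 + psi_g * s_bar) * G * (1 + R * psi_g) * beta
}

#' Predicted variance of total breeding values
#'
#' `(1 + psi_g * s_bar)^2 * G`: total breeding values are a linear
#' amplification of direct breeding values by mean connection strength, so
#' their variance does not involve the variance of indirect effects nor the
#' direct-indirect covariance.
#'
#' @inheritParams predict_response
#' @return Predicted `Var(t)`.
#' @export
predict_var_tbv <- function(G, psi_g, s_bar) {
  stopifnot(all(G >= 0))
  (1 + psi_g * s_bar)^2 * G
}

#' All four closed-form predictions as one row
#'
#' @inheritParams predict_response
#' @param E Environmental variance.
#' @param a_bar Mean direct breeding value.
#' @param var_social Variance of the social environment (for the variance
#'   prediction); defaults to 0 (empty network).
#' @param cov_direct_social Covariance of `a + e` with the social environment;
#'   defaults to 0.
#' @return A one-row tibble with `pred_mean`, `pred_var_z`, `pred_response`,
#'   `pred_var_tbv`.
#' @export
analytic_predictions <- function(psi_g, s_bar, G, E, a_bar = 0, R = 0,
                                 beta = 0.2, var_social = 0,
                                 cov_direct_social = 0) {
  tibble(
    pred_mean = predict_mean(psi_g, s_bar, a_bar),
    pred_var_z = predict_variance(G, E, psi_g, var_social, cov_direct_social),
    pred_response = predict_response(psi_g, s_bar, G, R, beta),
    pred_var_tbv = predict_var_tbv(G, psi_g, s_bar)
  )
}
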