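# broom-style accessors for simulated objects.

#' Tidy a simulated group
#'
#' Returns the per-individual table: positions, breeding value `a`,
#' environmental deviation `e`, social environment `eta`, phenotype `z` and
#' total breeding value `t`.
#'
#' @param x An `ipn_group`.
#' @param ... Unused.
#' @return A tibble with one row per individual.
#' @method tidy ipn_group
#' @export
tidy.ipn_group <- function(x, ...) {
  x$individuals
}

#' One-row overview of a simulated group
#'
#' Network metrics (density, assortativity) followed by the group summary
#' statistics.
#'
#' @param x An `ipn_group`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance ipn_group
#' @export
glance.ipn_group <- function(x, ...) {
  if (is.null(x$summary)) {
    return(x$metrics)
  }
  dplyr::bind_cols(x$metrics, x$summary)
}

#' Per-grid-value means of a sweep
#'
#' Collapses a sweep to one row per grid value: replicate means of the
#' network metrics and summary statistics, plus the among-group dispersion of
#' the mean phenotype and the response.
#'
#' @param x An `ipn_sweep`.
#' @param ... Unused.
#' @return A tibble with one row per grid value.
#' @method tidy ipn_sweep
#' @export
tidy.ipn_sweep <- function(x, ...) {
  x %>%
    dplyr::group_by(.data$r, .data$H, .data$mode) %>%
    dplyr::summarise(
      n_groups = dplyr::n(),
      var_mean_z = var(.data$mean_z),
      var_response = var(.data$response),
      dplyr::across(
        c("density", "assortativity", "mean_z", "var_indirect",
          "corr_direct_indirect", "var_z", "var_z_ratio", "var_t",
          "var_t_ratio", "response", "r_hat"),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    )
}

#' One-row overview of a sweep
#'
#' @param x An `ipn_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with the sweep extent and overall means.
#' @method glance ipn_sweep
#' @export
glance.ipn_sweep <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    n_grid = dplyr::n_distinct(x$r, x$H),
    mean_density = mean(x$density),
    mean_response = mean(x$response),
    master_seed = attr(x, "master_seed") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
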