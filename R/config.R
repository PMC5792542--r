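# Simulation configuration with the study's default parameter values.

#' Default interaction-range grid
#'
#' Sixteen values from 0 to 9 spaced at an increasing rate, so that the
#' realized densities they induce cover the \[0, 1\] axis. Results are indexed
#' by measured density, so the grid only controls coverage.
#'
#' @return Numeric vector of length 16.
#' @export
default_r_grid <- function() {
  c(0, 0.02, 0.04, 0.07, 0.12, 0.2, 0.33, 0.55, 0.9,
    1.5, 2.2, 3.2, 4.5, 6, 7.5, 9)
}

#' Default homophily-magnitude grid
#'
#' Nine values spanning the studied range 0 to 0.2.
#'
#' @return Numeric vector of length 9.
#' @export
default_h_grid <- function() {
  seq(0, 0.2, by = 0.025)
}

#' Simulation configuration
#'
#' Bundles every tunable parameter of one simulation scenario with its default
#' value. `r` and `H` may be scalars (for [run_group()]) or grids (for the
#' sweep functions).
#'
#' @param n Group size. Default 50 (20 is the other studied size).
#' @param r Interaction range, scalar or grid. Default [default_r_grid()].
#' @param move_fraction Fraction of the nearest-neighbour distance moved in
#'   the attraction step. Default 0.15.
#' @param edge_cutoff Weights strictly below this are removed. Default 0.05.
#' @param psi_g Interaction coefficient. Default 4.
#' @param beta Linear selection gradient. Default 0.2.
#' @param bv_dist Breeding-value distribution, `"uniform_pm1"` or
#'   `"normal_01"`.
#' @param env_var Environmental variance. Default 0.0625.
#' @param H Homophily magnitude, scalar or grid. Default [default_h_grid()].
#' @param mode Interaction preference: `"none"`, `"homophily"` or
#'   `"heterophily"`. Default `"none"`.
#' @param n_replicates Replicate groups per grid value. Default 50.
#' @return A list with class `"ipn_config"`.
#' @examples
#' cfg <- sim_config(n = 20, r = 0.9)
#' cfg$psi_g
#' @export
sim_config <- function(n = 50,
                       r = default_r_grid(),
                       move_fraction = 0.15,
                       edge_cutoff = 0.05,
                       psi_g = 4,
                       beta = 0.2,
                       bv_dist = c("uniform_pm1", "normal_01"),
                       env_var = 0.0625,
                       H = default_h_grid(),
                       mode = c("none", "homophily", "heterophily"),
                       n_replicates = 50) {
  check_group_size(n)
  bv_dist <- match.arg(bv_dist)
  mode <- match.arg(mode)
  stopifnot(is.numeric(r), all(r >= 0), length(r) >= 1)
  stopifnot(is.numeric(H), all(H >= 0), all(H <= 0.5))
  stopifnot(n_replicates >= 1)
  structure(
    list(
      n = as.integer(n), r = r, move_fraction = move_fraction,
      edge_cutoff = edge_cutoff, psi_g = psi_g, beta = beta,
      bv_dist = bv_dist, env_var = env_var, H = H, mode = mode,
      n_replicates = as.integer(n_replicates)
    ),
    class = "ipn_config"
  )
}

#' @export
print.ipn_config <- function(x, ...) {
  cat("<ipn_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-13s %s\n", nm,
                paste(format(v, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' The YAML keys mirror the [sim_config()] argument names exactly; missing
#' keys fall back to the defaults.
#'
#' @param path File path.
#' @return `read_config()` returns an `ipn_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(vals)[names(vals) == "FALSE"] <- "n"
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_config
#' @param config An `ipn_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ipn_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
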