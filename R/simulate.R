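# Seeded orchestration: one group, and replicate sweeps over interaction
# range (density) and homophily magnitude.

#' Simulate one group
#'
#' Runs the full pipeline for a single group: sample positions, one
#' synchronous nearest-neighbour attraction step, distance-decay weights,
#' optional similarity preference on the nonplastic phenotype `a + e`,
#' thresholding of weak edges, then the social environment, phenotypes, total
#' breeding values and the group summary. Density and assortativity are
#' measured on the final thresholded matrix, with `a + e` as the trait.
#'
#' @param config An [sim_config()] whose `r` and `H` are scalars (for grids
#'   use [sweep_density()] / [sweep_homophily()]).
#' @param seed Optional integer seed fixing every draw of this group.
#' @return An object of class `"ipn_group"`: a list with elements
#'   `individuals` (tibble `id, x, y, a, e, eta, z, t`), `w` (final weight
#'   matrix), `metrics` (one-row tibble `density, assortativity`), `summary`
#'   (one-row tibble from [summarize_group()]), `config`, `seed`.
#' @examples
#' g <- run_group(sim_config(n = 20, r = 0.9, H = 0), seed = 1)
#' glance(g)
#' @export
run_group <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ipn_config"))
  if (length(config$r) != 1 || length(config$H) != 1) {
    abort("`run_group()` needs scalar `r` and `H`; use the sweep functions for grids.")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- config$n
  a <- sample_breeding_values(n, config$bv_dist)
  e <- sample_env(n, config$env_var)
  nonplastic <- a + e

  pts <- sample_positions(n)
  pts <- attract_to_nearest(pts, config$move_fraction)
  w <- base_weights(pts, config$r)
  w <- apply_similarity(w, nonplastic, config$H, config$mode)
  w <- threshold_weights(w, config$edge_cutoff)

  eta <- social_environment(w, a, e)
  z <- phenotypes(a, e, eta, config$psi_g)
  t <- total_breeding_values(w, a, config$psi_g)

  individuals <- tibble(
    id = pts$id, x = pts$x, y = pts$y,
    a = a, e = e, eta = eta, z = z, t = t
  )
  structure(
    list(
      individuals = individuals,
      w = w,
      metrics = network_metrics(w, nonplastic),
      summary = summarize_group(individuals, w, config$psi_g, config$beta),
      config = config,
      seed = seed
    ),
    class = "ipn_group"
  )
}

#' @export
print.ipn_group <- function(x, ...) {
  n <- nrow(x$individuals)
  cat(sprintf(
    "<ipn_group> n = %d, density = %.3f, assortativity = %s\n",
    n, x$metrics$density,
    ifelse(is.na(x$metrics$assortativity), "NA",
           sprintf("%.3f", x$metrics$assortativity))
  ))
  print(x$summary)
  invisible(x)
}

#' Replicate seed matrix
#'
#' Derives one seed per (grid value, replicate) cell from a master seed: a
#' single RNG stream seeded at `master_seed` fills a grid-by-replicate matrix
#' with distinct integers below 2^31. The layout is fixed, so a master seed
#' reproduces every group exactly and replicates share no stream.
#'
#' @param master_seed Integer master seed.
#' @param n_grid Number of grid values.
#' @param n_replicates Replicates per grid value.
#' @return An `n_grid` by `n_replicates` integer matrix.
#' @export
replicate_seeds <- function(master_seed, n_grid, n_replicates) {
  stopifnot(n_grid >= 1, n_replicates >= 1)
  set.seed(master_seed)
  matrix(
    sample.int(.Machine$integer.max, n_grid * n_replicates),
    nrow = n_grid, ncol = n_replicates
  )
}

sweep_over <- function(config, grid_name, grid, seed, progress = FALSE) {
  seeds <- replicate_seeds(seed, length(grid), config$n_replicates)
  rows <- purrr::map(seq_along(grid), function(gi) {
    if (progress) {
      message(sprintf("%s = %g (%d/%d)", grid_name, grid[gi], gi, length(grid)))
    }
    purrr::map(seq_len(config$n_replicates), function(ri) {
      cfg_i <- config
      cfg_i[[grid_name]] <- grid[gi]
      g <- run_group(cfg_i, seed = seeds[gi, ri])
      dplyr::bind_cols(
        tibble(
          r = cfg_i$r, H = cfg_i$H, mode = cfg_i$mode,
          psi_g = cfg_i$psi_g, beta = cfg_i$beta, bv_dist = cfg_i$bv_dist,
          n = cfg_i$n, seed = seeds[gi, ri], replicate = ri
        ),
        g$metrics, g$summary
      )
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()
  structure(rows, class = c("ipn_sweep", class(tibble())),
            config = config, master_seed = seed)
}

#' Sweep over interaction range (network density)
#'
#' Simulates `n_replicates` groups at each value of the `r` grid with no
#' interaction preference (mode `"none"`), returning one row per group in
#' long format: configuration columns, measured network metrics and the
#' group summary. Density is an emergent property of `r`, so results are
#' indexed by the measured density.
#'
#' @param config An [sim_config()] whose `r` holds the grid; `mode` is forced
#'   to `"none"` and `H` to 0.
#' @param seed Master seed for the whole sweep (see [replicate_seeds()]).
#' @param progress Emit a message per grid value.
#' @return A tibble of class `"ipn_sweep"` with
#'   `length(r) * n_replicates` rows.
#' @examples
#' sw <- sweep_density(sim_config(n = 20, n_replicates = 3), seed = 1)
#' dplyr::count(sw, r)
#' @export
sweep_density <- function(config, seed = 1L, progress = FALSE) {
  stopifnot(inherits(config, "ipn_config"))
  config$mode <- "none"
  config$H <- 0
  sweep_over(config, "r", config$r, seed, progress)
}

#' Sweep over homophily magnitude
#'
#' Simulates `n_replicates` groups at each value of the `H` grid at a fixed
#' interaction range, with mode `"homophily"` or `"heterophily"`. The default
#' baseline range `r = 0.9` yields intermediate baseline density; measured
#' assortativity is recorded per group.
#'
#' @param config An [sim_config()] whose `H` holds the grid and whose `mode`
#'   is not `"none"`; `r` must be scalar (the baseline range).
#' @inheritParams sweep_density
#' @return A tibble of class `"ipn_sweep"`.
#' @export
sweep_homophily <- function(config, seed = 1L, progress = FALSE) {
  stopifnot(inherits(config, "ipn_config"))
  if (config$mode == "none") {
    abort("`sweep_homophily()` needs mode \"homophily\" or \"heterophily\".")
  }
  if (length(config$r) != 1) {
    abort("`sweep_homophily()` needs a scalar baseline `r` (default 0.9).")
  }
  sweep_over(config, "H", config$H, seed, progress)
}

#' Deterministic fixture groups
#'
#' Hand-constructible networks with known densities and assortativities:
#' `"dyad"` (two connected individuals), `"complete"` (every dyad at equal
#' weight), `"star"` (node 1 a hub), `"two_cliques"` (two disjoint complete
#' halves). Environmental deviations are zero, so the trait equals the
#' supplied breeding values.
#'
#' @param kind One of `"dyad"`, `"complete"`, `"star"`, `"two_cliques"`.
#' @param n Group size (`dyad` forces 2; `two_cliques` needs even `n`).
#' @param traits Breeding values; default `seq(-1, 1, length.out = n)`, or
#'   clique labels +1/-1 for `"two_cliques"`.
#' @param weight Edge weight for present edges. Default 1.
#' @param psi_g,beta Model coefficients used for phenotypes and the summary.
#' @return An `"ipn_group"` object.
#' @examples
#' make_fixture("star", 5)$metrics$density # 0.4
#' @export
make_fixture <- function(kind = c("dyad", "complete", "star", "two_cliques"),
                         n = 4, traits = NULL, weight = 1,
                         psi_g = 4, beta = 0.2) {
  kind <- match.arg(kind)
  if (kind == "dyad") n <- 2L
  check_group_size(n)
  if (kind == "two_cliques" && n %% 2 != 0) {
    abort("`two_cliques` needs an even group size.")
  }
  w <- matrix(0, n, n)
  if (kind %in% c("dyad", "complete")) {
    w[] <- weight
  } else if (kind == "star") {
    w[1, ] <- weight
    w[, 1] <- weight
  } else {
    half <- n / 2
    idx1 <- seq_len(half)
    idx2 <- half + seq_len(half)
    w[idx1, idx1] <- weight
    w[idx2, idx2] <- weight
  }
  diag(w) <- 0
  if (is.null(traits)) {
    traits <- if (kind == "two_cliques") {
      rep(c(1, -1), each = n / 2)
    } else {
      seq(-1, 1, length.out = n)
    }
  }
  stopifnot(length(traits) == n)

  a <- as.numeric(traits)
  e <- rep(0, n)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pts <- tibble(id = seq_len(n),
                x = 0.5 + 0.4 * cos(theta), y = 0.5 + 0.4 * sin(theta))
  eta <- social_environment(w, a, e)
  z <- phenotypes(a, e, eta, psi_g)
  t <- total_breeding_values(w, a, psi_g)
  individuals <- tibble(id = pts$id, x = pts$x, y = pts$y,
                        a = a, e = e, eta = eta, z = z, t = t)
  summary <- if (n >= 3) {
    summarize_group(individuals, w, psi_g, beta)
  } else {
    NULL
  }
  structure(
    list(individuals = individuals, w = w,
         metrics = network_metrics(w, a + e),
         summary = summary,
         config = sim_config(n = n, r = 0, psi_g = psi_g, beta = beta,
                             H = 0, n_replicates = 1),
         seed = NULL),
    class = "ipn_group"
  )
}
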