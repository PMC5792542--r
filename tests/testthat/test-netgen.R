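test_that("positions are uniform in the unit square and respect group size", {
  set.seed(1)
  pts <- sample_positions(50)
  expect_equal(nrow(pts), 50)
  expect_true(all(pts$x >= 0 & pts$x <= 1))
  expect_true(all(pts$y >= 0 & pts$y <= 1))

  expect_equal(nrow(sample_positions(2)), 2)
  expect_error(sample_positions(1), "group size")

  set.seed(42)
  big <- sample_positions(1e5)
  se <- sqrt(1 / 12) / sqrt(1e5)
  expect_lt(abs(mean(big$x) - 0.5), 3 * se)
  expect_lt(abs(mean(big$y) - 0.5), 3 * se)
})

test_that("attraction moves each point 15% toward its nearest neighbour, synchronously", {
  two <- tibble::tibble(id = 1:2, x = c(0, 1), y = c(0, 0))
  moved <- attract_to_nearest(two, 0.15)
  expect_equal(moved$x, c(0.15, 0.85))
  expect_equal(moved$y, c(0, 0))

  # collinear triple: 1 and 2 are mutual nearest neighbours, 3 moves toward 2
  tri <- tibble::tibble(id = 1:3, x = c(0, 0.4, 1), y = c(0, 0, 0))
  expect_equal(bf_nearest(tri), c(2L, 1L, 2L))
  moved <- attract_to_nearest(tri, 0.15)
  expect_equal(moved$x, c(0.06, 0.34, 0.91))

  set.seed(3)
  pts <- sample_positions(30)
  expect_equal(attract_to_nearest(pts, 0), pts)
  moved <- attract_to_nearest(pts, 0.15)
  expect_true(all(moved$x >= 0 & moved$x <= 1 & moved$y >= 0 & moved$y <= 1))
  expect_error(attract_to_nearest(pts, 1), "fraction")
})

test_that("attraction resolves nearest-neighbour ties toward the lowest id", {
  # points 2 and 3 are equidistant from point 1
  pts <- tibble::tibble(id = 1:3, x = c(0, 1, -1), y = c(0, 0, 0))
  moved <- attract_to_nearest(pts, 0.5)
  expect_equal(moved$x[1], 0.5)
})

test_that("distance-decay weights follow exp(-d^2/r) with the r = 0 empty limit", {
  pts <- tibble::tibble(id = 1:2, x = c(0, 0.5), y = c(0, 0))
  w <- base_weights(pts, r = 1)
  expect_equal(w[1, 2], exp(-0.25))
  expect_equal(diag(w), c(0, 0))

  coincident <- tibble::tibble(id = 1:2, x = c(0.3, 0.3), y = c(0.7, 0.7))
  expect_equal(base_weights(coincident, r = 2)[1, 2], 1)

  set.seed(5)
  pts <- sample_positions(8)
  expect_equal(base_weights(pts, r = 0), matrix(0, 8, 8))
  expect_error(base_weights(pts, r = -1), "nonnegative")

  for (r in c(0.1, 1, 5)) {
    expect_equal(base_weights(pts, r), bf_base_weights(pts, r))
  }
})

test_that("weights are symmetric, zero-diagonal, in [0, 1] through the whole chain", {
  set.seed(7)
  pts <- attract_to_nearest(sample_positions(25), 0.15)
  traits <- runif(25, -1, 1)
  for (mode in c("none", "homophily", "heterophily")) {
    w <- base_weights(pts, 0.5)
    w <- apply_similarity(w, traits, H = 0.2, mode = mode)
    w <- threshold_weights(w, 0.05)
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(0, 25))
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(w == 0 | w >= 0.05))
  }
})

test_that("similarity multiplier is sigmoidal with magnitude H around 0.5", {
  expect_equal(similarity_multiplier(c(0, 0.3, 2), H = 0.5, mode = "none"),
               rep(1, 3))
  # logistic at the midpoint is exactly 1/2
  expect_equal(similarity_multiplier(0.5, 0.2, "homophily"), 0.6)
  expect_equal(similarity_multiplier(0, 0.2, "heterophily"),
               0.5 - 0.2 / (1 + exp(-10)), tolerance = 1e-12)
  d <- seq(0, 2, by = 0.05)
  m <- similarity_multiplier(d, 0.2, "homophily")
  expect_true(all(m >= 0.3 & m <= 0.7))
  expect_true(all(diff(m) <= 0)) # dissimilarity never increases the weight
  expect_error(similarity_multiplier(0.1, H = 0.7, mode = "homophily"),
               "0.5")
})

test_that("similarity application rescales dyads by trait difference, preserving symmetry", {
  w <- equal_weight_complete(3)
  traits <- c(0.4, 0.4, 2)
  expect_identical(apply_similarity(w, traits, 0.2, "none"), w)
  out <- apply_similarity(w, traits, 0.2, "homophily")
  # identical pair: multiplier ~ 0.5 + H
  expect_equal(out[1, 2], 0.5 + 0.2 * plogis(10), tolerance = 1e-6)
  expect_equal(out[1, 2], 0.7, tolerance = 1e-4)
  # very different pair: multiplier ~ 0.5
  expect_equal(out[1, 3], 0.5, tolerance = 1e-6)
  expect_equal(out, t(out))
  expect_error(apply_similarity(w, c(1, 2), 0.2, "homophily"), "one value")
})

test_that("thresholding removes strictly sub-cutoff weights and keeps the boundary", {
  w <- matrix(c(0, 0.049, 0.05, 0.049, 0, 0.9, 0.05, 0.9, 0), 3, 3)
  out <- threshold_weights(w, 0.05)
  expect_equal(out[1, 2], 0)
  expect_equal(out[1, 3], 0.05)
  expect_equal(out[2, 3], 0.9)
  expect_identical(threshold_weights(w, 0), w)
})

test_that("density is the mean dyadic weight", {
  expect_equal(network_density(equal_weight_complete(3)), 1)
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5
  expect_equal(network_density(w), 0.5 / 3)
  expect_equal(network_density(matrix(0, 4, 4)), 0)
  expect_error(network_density(matrix(0, 1, 1)), "at least 2")
})

test_that("density is monotone nondecreasing in r on fixed positions", {
  set.seed(11)
  pts <- attract_to_nearest(sample_positions(30), 0.15)
  dens <- vapply(default_r_grid(), function(r) {
    network_density(threshold_weights(base_weights(pts, r), 0.05))
  }, numeric(1))
  expect_true(all(diff(dens) >= 0))
})

test_that("assortativity hits the +/-1 limits and matches the directed-edge oracle", {
  # two disjoint dyads with equal traits inside each dyad
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_equal(weighted_assortativity(w, c(1, 1, -1, -1)), 1)
  expect_equal(weighted_assortativity(w, c(1, -1, 1, -1)), -1)

  # 4-node path, alternating traits
  path <- matrix(0, 4, 4)
  path[1, 2] <- path[2, 3] <- path[3, 4] <- 1
  path <- path + t(path)
  traits <- c(0, 1, 0, 1)
  expect_equal(weighted_assortativity(path, traits),
               bf_assortativity(path, traits))

  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    w <- random_weights(n)
    x <- rnorm(n)
    expect_equal(weighted_assortativity(w, x), bf_assortativity(w, x))
    expect_true(is.na(weighted_assortativity(w, x)) ||
                  abs(weighted_assortativity(w, x)) <= 1 + 1e-12)
  }
})

test_that("degenerate networks or constant traits give NA assortativity, not errors", {
  expect_true(is.na(weighted_assortativity(matrix(0, 5, 5), rnorm(5))))
  expect_true(is.na(weighted_assortativity(equal_weight_complete(5), rep(2, 5))))
})

test_that("homophily raises measured assortativity over the unmodified network on average", {
  set.seed(17)
  deltas <- replicate(50, {
    n <- 30
    pts <- attract_to_nearest(sample_positions(n), 0.15)
    traits <- runif(n, -1, 1)
    base <- threshold_weights(base_weights(pts, 0.9), 0.05)
    homo <- threshold_weights(
      apply_similarity(base_weights(pts, 0.9), traits, 0.2, "homophily"), 0.05)
    weighted_assortativity(homo, traits) -
      weighted_assortativity(base, traits)
  })
  expect_gt(mean(deltas, na.rm = TRUE), 0)
})
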