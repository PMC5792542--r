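# Brute-force double-loop oracles, kept independent of the vectorized
# implementations they check.

bf_eta <- function(w, a, e) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + w[i, j] * (a[j] + e[j])
    }
    out[i] <- acc / (n - 1)
  }
  out
}

bf_base_weights <- function(points, r) {
  n <- nrow(points)
  w <- matrix(0, n, n)
  if (r == 0) return(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d2 <- (points$x[i] - points$x[j])^2 + (points$y[i] - points$y[j])^2
        w[i, j] <- exp(-d2 / r)
      }
    }
  }
  w
}

# Assortativity accumulated edge by edge over directed pairs.
bf_assortativity <- function(w, x) {
  W <- 0; sx <- 0; sxy <- 0; sx2 <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && w[i, j] > 0) {
        W <- W + w[i, j]
        sx <- sx + w[i, j] * x[i]
        sxy <- sxy + w[i, j] * x[i] * x[j]
        sx2 <- sx2 + w[i, j] * x[i]^2
      }
    }
  }
  if (W == 0) return(NA_real_)
  xbar <- sx / W
  den <- sx2 / W - xbar^2
  if (den <= 0) return(NA_real_)
  (sxy / W - xbar^2) / den
}

# Nearest neighbour of each point by an all-pairs distance scan,
# lowest index on ties.
bf_nearest <- function(points) {
  n <- nrow(points)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j != i) {
        d <- sqrt((points$x[i] - points$x[j])^2 +
                    (points$y[i] - points$y[j])^2)
        if (d < best) { best <- d; best_j <- j }
      }
    }
    out[i] <- best_j
  }
  out
}

# A random symmetric weight matrix with zero diagonal, some zero entries.
random_weights <- function(n, p_zero = 0.3) {
  w <- matrix(runif(n * n), n, n)
  w[runif(n * n) < p_zero] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

equal_weight_complete <- function(n, s = 1) {
  w <- matrix(s, n, n)
  diag(w) <- 0
  w
}
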