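# shared test helpers: small deterministic fixtures and independent oracles

# random symmetric matrix with zero diagonal and node labels
rand_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  m
}

# brute-force partial correlation: correlate the residuals of each pair
# after regressing out all remaining nodes (independent of the precision
# route used by the package)
pcor_oracle <- function(x) {
  p <- ncol(x)
  out <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others)) resid(lm(x[, i] ~ others)) else x[, i] - mean(x[, i])
      rj <- if (ncol(others)) resid(lm(x[, j] ~ others)) else x[, j] - mean(x[, j])
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# a small, fast synthetic configuration for unit tests
tiny_config <- function(seed = 1, n_subjects = 12, ...) {
  synth_config(
    n_subjects = n_subjects, n_regions = 8, n_frames = 120, seed = seed,
    planted_edges = tibble::tibble(node_i = c(2L, 5L), node_j = c(6L, 8L),
                                   effect = c(0.35, -0.35)),
    ...
  )
}

# deterministic motion table with a single translation step
step_motion <- function(n_frames = 6, step_col = 4, step_at = 3, size = 0.1) {
  m <- matrix(0, n_frames, 6)
  m[step_at:n_frames, step_col] <- size
  m
}
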