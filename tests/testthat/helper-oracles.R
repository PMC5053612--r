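# Independent oracles used across the test files.

# Brute-force matching-law allocation: loop over every source and hand out
# its dispensed help share by share (equal split when the recipient pool has
# zero total weight).  Kept deliberately naive and separate from the package
# implementation.
oracle_help_received <- function(h, k, z) {
  n <- length(h)
  b <- h + k
  w <- b^z
  r <- numeric(n)
  for (j in seq_len(n)) {
    pool <- sum(w[-j])
    for (i in seq_len(n)[-j]) {
      share <- if (pool > 0) w[i] / pool else 1 / (n - 1)
      r[i] <- r[i] + b[j] * share
    }
  }
  r
}

# Two-type allocation at perfect matching, written straight from the
# closed-form r_p / r_m expressions (z = 1, k = 0 special case).
oracle_r_two_type_z1 <- function(h_p, h_m, P, M) {
  N <- P + M
  r_p <- (P - 1) * h_p^2 / ((P - 1) * h_p + M * h_m) +
    M * h_m * h_p / (P * h_p + (M - 1) * h_m)
  r_m <- P * h_p * h_m / ((P - 1) * h_p + M * h_m) +
    (M - 1) * h_m^2 / (P * h_p + (M - 1) * h_m)
  c(r_p = r_p, r_m = r_m)
}

# Single-deviant closed form (z = 1, k = 0).
oracle_r_single_mutant <- function(N, h_p, h_m) {
  (N - 1) * h_p * h_m / (h_m + (N - 2) * h_p)
}

# Focal-agent payoff against lagged opponents: agent i holds help v, every
# other agent keeps h_prev.
oracle_focal_payoff <- function(i, v, h_prev, k, z, m, x) {
  h_eval <- h_prev
  h_eval[i] <- v
  r <- oracle_help_received(h_eval, k, z)[i]
  m * r / (m * x + r) - v
}

# Central finite-difference Jacobian of a vector field R^2 -> R^2.
oracle_fd_jacobian <- function(f, y, eps = 1e-6) {
  J <- matrix(0, 2L, 2L)
  for (j in 1:2) {
    d <- c(0, 0)
    d[j] <- eps
    J[, j] <- (f(y + d) - f(y - d)) / (2 * eps)
  }
  J
}
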