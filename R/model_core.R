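# Primitive quantities of the market: help received under matching-law
# allocation, and the fitness payoff.

# Scalar workhorse for the two-type allocation.  P and M are individual
# counts (P + M = N).  Degenerate recipient pools (total weight 0, possible
# when k = 0 and all recipients provide no help with z > 0) fall back to an
# equal split so that every dispensed unit is conserved.
.tt_help_received <- function(h_p, h_m, P, M, N, k, z) {
  a <- h_p + k
  b <- h_m + k
  alpha <- a^z   # 0^0 == 1 in R, so z = 0 always means equal weights
  beta <- b^z
  pool_p <- (P - 1) * alpha + M * beta    # recipient pool of a p-source
  pool_m <- P * alpha + (M - 1) * beta    # recipient pool of an m-source
  share <- function(w, pool) if (pool > 0) w / pool else 1 / (N - 1)
  r_p <- if (P == 0) 0 else
    (P - 1) * a * share(alpha, pool_p) + M * b * share(alpha, pool_m)
  r_m <- if (M == 0) 0 else
    P * a * share(beta, pool_p) + (M - 1) * b * share(beta, pool_m)
  c(r_p = r_p, r_m = r_m)
}

#' Help received by each type under matching-law allocation
#'
#' Every individual dispenses its active help plus the passive amount `k`;
#' each dispensed unit is split among the other `N - 1` individuals in
#' proportion to their matching weights `(h + k)^z`.  This returns the total
#' help received by one individual of each type.
#'
#' A type with zero members reports zero help received by convention.  When a source's
#' recipient pool has zero total weight (possible when `k = 0` and all
#' recipients are non-helpers with `z > 0`) its help is split equally, which
#' preserves conservation and continuity with the `z = 0` case.
#'
#' @param state A [two_type_state()].
#' @param params A [model_params()] with finite `N`.
#' @param strict If `TRUE` (default), `S_p * N` and `S_m * N` must be whole
#'   numbers: the allocation counts individuals.  The replicator-dynamics
#'   layer relaxes this to treat proportions as continuous.
#'
#' @return Named numeric vector with components `r_p` and `r_m`.
#' @examples
#' p <- model_params(N = 10, z = 0)
#' s <- two_type_state(S_m = 0.5, h_p = 0.4, h_m = 0.2)
#' help_received_two_type(s, p)  # equal split: both receive 2.6/9
#' @export
help_received_two_type <- function(state, params, strict = TRUE) {
  stopifnot(inherits(state, "two_type_state"), inherits(params, "model_params"))
  .require_finite_N(params)
  P <- state$S_p * params$N
  M <- state$S_m * params$N
  if (strict) {
    if (abs(P - round(P)) > 1e-6 || abs(M - round(M)) > 1e-6)
      stop("'S_p * N' and 'S_m * N' must be whole numbers of individuals")
    P <- round(P)
    M <- round(M)
  }
  .tt_help_received(state$h_p, state$h_m, P, M, params$N, params$k, params$z)
}

#' Help received by every agent in a heterogeneous population
#'
#' Fully heterogeneous form of the matching-law allocation: agent `i` receives
#' `sum_{j != i} (h_j + k) * (h_i + k)^z / sum_{l != j} (h_l + k)^z`.
#' Sources whose recipient pool has zero total weight split their help
#' equally among the other `N - 1` agents.
#'
#' @param pop An [agent_population()].
#' @param z Degree of matching (>= 0); defaults to 1.
#'
#' @return Numeric vector of help received, one entry per agent.  The total
#'   received always equals the total dispensed, `sum(h + k)`.
#' @examples
#' help_received_agents(agent_population(c(1, 0, 0)), z = 1)  # c(0, 0.5, 0.5)
#' @export
help_received_agents <- function(pop, z = 1) {
  stopifnot(inherits(pop, "agent_population"), is.numeric(z), z >= 0)
  h <- pop$h
  k <- pop$k
  n <- length(h)
  b <- h + k
  w <- b^z
  # leave-one-out sums are computed directly rather than as sum(w) - w[j]:
  # when one matching weight dominates (large z), the subtraction cancels
  # catastrophically and the dispensed shares stop summing to one
  loo <- function(v) vapply(seq_len(n), function(i) sum(v[-i]), numeric(1))
  pool <- loo(w)                         # recipient pool of each source
  live <- pool > 0
  s <- ifelse(live, b / pool, 0)         # per-source contribution rate
  r <- w * loo(s)
  # degenerate sources split equally among the other n - 1 agents
  d_total <- sum(b[!live])
  if (d_total > 0)
    r <- r + (d_total - ifelse(!live, b, 0)) / (n - 1)
  r
}

#' Fitness payoff from help received
#'
#' Diminishing-returns benefit minus the linear cost of active help:
#' `W = m * r / (m * x + r) - h`.  The benefit saturates at `m` as `r` grows.
#'
#' @param r Help received (>= 0); vectorized.
#' @param h Own active help (>= 0); vectorized.
#' @param m Maximum fitness benefit (> 0).
#' @param x Diminishing-returns rate, in (0, 1].
#'
#' @return Numeric payoff(s).
#' @examples
#' payoff(r = 0.5, h = 0.1, m = 1, x = 0.5)  # 0.4
#' @export
payoff <- function(r, h, m = 1, x = 0.5) {
  stopifnot(is.numeric(r), is.numeric(h), m > 0, x > 0, x <= 1)
  if (any(r < 0) || any(h < 0)) stop("'r' and 'h' must be nonnegative")
  m * r / (m * x + r) - h
}

# Scalar payoffs for both types; absent types get W = 0 by convention.
.tt_payoffs <- function(h_p, h_m, P, M, N, m, x, k, z) {
  r <- .tt_help_received(h_p, h_m, P, M, N, k, z)
  W_p <- if (P == 0) 0 else m * r[[1L]] / (m * x + r[[1L]]) - h_p
  W_m <- if (M == 0) 0 else m * r[[2L]] / (m * x + r[[2L]]) - h_m
  c(W_p = W_p, W_m = W_m, r_p = r[[1L]], r_m = r[[2L]])
}

#' Payoff gap between the two types
#'
#' Returns `W_m - W_p` at the given state.  Zeros of the gap are the interior
#' equilibrium condition of the two-type replicator dynamics: when both types
#' earn the same payoff there is no incentive to switch strategy.
#'
#' @inheritParams help_received_two_type
#' @return The scalar payoff difference `W_m - W_p`.
#' @examples
#' p <- model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1)
#' payoff_gap(two_type_state(S_m = 0.5, h_p = 0, h_m = 0.5), p)  # 0
#' @export
payoff_gap <- function(state, params, strict = TRUE) {
  stopifnot(inherits(state, "two_type_state"), inherits(params, "model_params"))
  .require_finite_N(params)
  P <- state$S_p * params$N
  M <- state$S_m * params$N
  if (strict) {
    if (abs(P - round(P)) > 1e-6 || abs(M - round(M)) > 1e-6)
      stop("'S_p * N' and 'S_m * N' must be whole numbers of individuals")
    P <- round(P)
    M <- round(M)
  }
  W <- .tt_payoffs(state$h_p, state$h_m, P, M, params$N, params$m, params$x,
                   params$k, params$z)
  unname(W[[2L]] - W[[1L]])
}

#' Help received by a single deviant under perfect matching
#'
#' Closed form for the original single-mutant market: one individual providing
#' `h_m` among `N - 1` individuals providing `h_p`, with `z = 1` and `k = 0`:
#' `(N - 1) h_p h_m / (h_m + (N - 2) h_p)`.  A zero denominator (no help
#' in the market) yields zero.
#'
#' @param N Population size (>= 3).
#' @param h_p Help provided by each of the `N - 1` residents (>= 0).
#' @param h_m Help provided by the single deviant (>= 0).
#'
#' @return The deviant's help received.
#' @examples
#' legacy_r_single_mutant(3, 0.4, 0.2)  # 0.16 / 0.6
#' @export
legacy_r_single_mutant <- function(N, h_p, h_m) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 3, N == round(N),
            is.numeric(h_p), h_p >= 0, is.numeric(h_m), h_m >= 0)
  den <- h_m + (N - 2) * h_p
  if (den == 0) return(0)
  (N - 1) * h_p * h_m / den
}
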