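# Two-type incremental-mutation simulator.

test_that("a mutation step obeys the acceptance and clamping rules", {
  p <- model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1)
  cfg <- sim_config(mutation_increment = 0.01, both_directions = TRUE)
  hstar <- optimal_help_symmetric(p)
  # at a strict local optimum neither candidate improves: state unchanged
  s <- two_type_state(0.5, h_p = hstar, h_m = hstar)
  s2 <- step_types(s, s, p, cfg)
  expect_equal(s2$h_p, hstar)
  expect_equal(s2$h_m, hstar)
  # at zero help against a non-helping market, the downward candidate is
  # clamped and the upward one loses money: help stays at zero
  s0 <- two_type_state(0.5, h_p = 0, h_m = 0)
  p5 <- model_params(N = 100, z = 5)
  expect_equal(step_types(s0, s0, p5, sim_config(0.01))$h_m >= 0, TRUE)
  # moves are bounded by one increment per type per step
  set.seed(31)
  st <- two_type_state(0.5, h_p = 0.3, h_m = 0.45)
  for (i in 1:25) {
    nxt <- step_types(st, st, p, cfg)
    expect_lte(abs(nxt$h_p - st$h_p), cfg$mutation_increment + 1e-12)
    expect_lte(abs(nxt$h_m - st$h_m), cfg$mutation_increment + 1e-12)
    # accepted moves never decrease the expected payoff against the snapshot
    for (side in c("p", "m")) {
      h_new <- if (side == "p") nxt$h_p else nxt$h_m
      h_old <- if (side == "p") st$h_p else st$h_m
      if (h_new != h_old) {
        W_new <- if (side == "p")
          payoff(help_received_two_type(
            two_type_state(0.5, h_new, st$h_m), p)[["r_p"]], h_new)
        else
          payoff(help_received_two_type(
            two_type_state(0.5, st$h_p, h_new), p)[["r_m"]], h_new)
        W_old <- if (side == "p")
          payoff(help_received_two_type(
            two_type_state(0.5, h_old, st$h_m), p)[["r_p"]], h_old)
        else
          payoff(help_received_two_type(
            two_type_state(0.5, st$h_p, h_old), p)[["r_m"]], h_old)
        expect_gt(W_new, W_old)
      }
    }
    st <- nxt
  }
})

test_that("fixed proportions recover the equilibrium structure across z", {
  N <- 1000
  cfg <- function(seed) sim_config(mutation_increment = 0.005,
                                   max_steps = 20000, seed = seed)
  # z = 1: a single competitive equilibrium at (h*, h*) whatever the start
  p1 <- model_params(N = N, z = 1)
  hs <- optimal_help_symmetric(p1)
  for (seed in 1:2) {
    r <- run_fixed_proportions(0.5, p1, cfg(seed))
    expect_true(r$converged)
    expect_identical(r$label, "competitive")
    expect_lt(abs(r$equilibrium[["h_p"]] - hs), 2 * 0.005)
    expect_lt(abs(r$equilibrium[["h_m"]] - hs), 2 * 0.005)
  }
  # z = 0 at even proportions: helping collapses to (0, 0)
  r0 <- run_fixed_proportions(0.5, model_params(N = N, z = 0), cfg(3))
  expect_identical(r0$label, "collapse")
  # z = 5 from far-apart help: one type gives up, the survivor settles at
  # the monomorphic optimum
  r5 <- run_fixed_proportions(0.5, model_params(N = N, z = 5), cfg(4),
                              init = c(0.9, 0.1))
  expect_identical(r5$label, "m-quits")
  expect_lt(abs(r5$equilibrium[["h_p"]] - optimal_help_monomorphic(p1)),
            2 * 0.005)
  # monomorphic run: equilibrium at the closed form
  rm0 <- run_fixed_proportions(0, p1, cfg(5), init = c(0.8, 0))
  expect_lt(abs(rm0$equilibrium[["h_p"]] - optimal_help_monomorphic(p1)),
            2 * 0.005)
})

test_that("equilibrium help at z = 1 is independent of the proportion split", {
  p <- model_params(N = 1000, z = 1)
  cfg <- sim_config(mutation_increment = 0.005, max_steps = 20000, seed = 8)
  sw <- proportion_sweep(p, cfg, S_grid = c(0.2, 0.5, 0.8))
  expect_true(all(sw$converged))
  expect_lt(max(sw$h_p) - min(sw$h_p), 2 * 0.005)
  expect_lt(max(sw$h_m) - min(sw$h_m), 2 * 0.005)
})

test_that("uneven proportions make the larger type help more for less", {
  p <- model_params(N = 1000, z = 0.5)
  cfg <- sim_config(mutation_increment = 0.005, max_steps = 20000, seed = 9)
  r <- run_fixed_proportions(0.3, p, cfg)  # type p is the larger type
  expect_true(r$converged)
  expect_gt(r$equilibrium[["h_p"]], r$equilibrium[["h_m"]])
  expect_lt(r$equilibrium[["W_p"]], r$equilibrium[["W_m"]])
})

test_that("basin maps show one basin at z = 1 and three at z > 1", {
  N <- 200
  cfg <- sim_config(mutation_increment = 0.01, max_steps = 10000, seed = 10)
  grid <- list(h_p = c(0.05, 0.35, 0.65), h_m = c(0.05, 0.35, 0.65))
  b1 <- basin_map(grid, 0.5, model_params(N = N, z = 1), cfg)
  expect_identical(unique(b1$label), "competitive")
  b5 <- basin_map(grid, 0.5, model_params(N = N, z = 5), cfg)
  expect_setequal(unique(b5$label), c("competitive", "p-quits", "m-quits"))
  # the competitive basin contains the diagonal neighbourhood
  expect_identical(b5$label[b5$h_p0 == b5$h_m0], rep("competitive", 3))
  # label symmetry under swapping the two types
  for (i in seq_len(nrow(b5))) {
    j <- which(b5$h_p0 == b5$h_m0[i] & b5$h_m0 == b5$h_p0[i])
    mirror <- c(competitive = "competitive", `p-quits` = "m-quits",
                `m-quits` = "p-quits")
    expect_identical(unname(mirror[b5$label[i]]), b5$label[j])
  }
})

test_that("evolving proportions equalize the split below the threshold", {
  # z below 2/x - 1: the larger type earns less, so switching drives the
  # split to one half and the help levels to the common optimum
  p <- model_params(N = 1000, z = 0.5)
  hs <- optimal_help_symmetric(p)
  cfg <- sim_config(seed = 21)
  r <- run_evolving_proportions(p, cfg, S_m0 = 0.3, init = c(hs, hs))
  expect_true(r$converged)
  expect_lt(abs(r$equilibrium[["S_m"]] - 0.5), 0.05)
  expect_lt(abs(r$equilibrium[["h_p"]] - r$equilibrium[["h_m"]]), 0.01)
})

test_that("evolving proportions drive the quitting type extinct at high z", {
  p <- model_params(N = 1000, z = 5)
  cfg <- sim_config(mutation_increment = 0.005, max_steps = 20000, seed = 22)
  r <- run_evolving_proportions(p, cfg, S_m0 = 0.5, init = c(0.8, 0.1))
  expect_true(r$converged)
  # one type is driven out entirely; the survivor provides the monomorphic
  # optimum and the extinct type's help is frozen at zero
  S <- r$equilibrium[c("S_p", "S_m")]
  h <- r$equilibrium[c("h_p", "h_m")]
  loser <- which.min(S)
  expect_lt(S[loser], 0.01)
  expect_lt(h[loser], 0.02)
  expect_lt(abs(h[-loser] - optimal_help_monomorphic(model_params(N = 1000))),
            0.02)
})

test_that("equal payoffs imply constant proportions", {
  # symmetric start with deterministic both-direction moves keeps the types
  # identical, so the payoff gap stays zero and nobody switches
  p <- model_params(N = 1000, z = 2)
  cfg <- sim_config(mutation_increment = 0.005, max_steps = 5000,
                    both_directions = TRUE, seed = 23)
  r <- run_evolving_proportions(p, cfg, S_m0 = 0.5, init = c(0.2, 0.2))
  expect_equal(unique(r$trajectory$S_m), 0.5)
})
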