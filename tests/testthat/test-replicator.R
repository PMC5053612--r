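# Replicator dynamics, closed-form optima and stability analysis.

test_that("replicator field vanishes at boundaries and equal help", {
  p <- model_params(N = 1000, z = 1)
  rhs0 <- replicator_rhs(two_type_state(S_m = 0, h_p = 0.2, h_m = 0.3), p)
  expect_equal(unname(rhs0), c(0, 0), tolerance = 1e-14)
  for (S_m in c(0.2, 0.5, 0.9)) {
    rhs <- replicator_rhs(two_type_state(S_m, h_p = 0.25, h_m = 0.25), p)
    expect_equal(unname(rhs), c(0, 0), tolerance = 1e-13)
  }
})

test_that("replicator field factorizes as S_m (1 - S_m)(W_m - W_p)", {
  set.seed(5)
  for (i in 1:20) {
    n <- 1200
    M <- sample(1:(n - 1), 1)
    p <- model_params(N = n, m = runif(1, 0.5, 2), x = runif(1, 0.2, 0.9),
                      k = sample(c(0, 0.1), 1), z = runif(1, 0, 4))
    st <- two_type_state(M / n, h_p = runif(1, 0.01, 1),
                         h_m = runif(1, 0.01, 1))
    rhs <- replicator_rhs(st, p)
    gap <- payoff_gap(st, p)
    expect_equal(rhs[["dS_m"]], st$S_m * (1 - st$S_m) * gap,
                 tolerance = 1e-9)
    expect_lt(abs(rhs[["dS_p"]] + rhs[["dS_m"]]), 1e-12)
  }
})

test_that("integration conserves the simplex and finds the attracting corner", {
  p <- model_params(N = 10000, m = 1, x = 0.5, k = 0, z = 1)
  hstar <- optimal_help_monomorphic(p)
  tr <- integrate_replicator(two_type_state(S_m = 0.7, h_p = hstar, h_m = 0),
                             p, horizon = 500)
  expect_lt(attr(tr, "drift"), 1e-9)
  expect_true(attr(tr, "converged"))
  # the helping type earns W > 0 against a non-helping type, so it fixes
  expect_equal(tail(tr$S_p, 1), 1, tolerance = 1e-6)
  expect_true(all(diff(tr$time) > 0))

  # equal help: the flow vanishes identically and the state never moves
  trc <- suppressWarnings(integrate_replicator(
    two_type_state(S_m = 0.37, h_p = 0.2, h_m = 0.2), p, horizon = 50,
    tol = 1e-6))
  expect_equal(trc$S_m, rep(0.37, nrow(trc)), tolerance = 1e-9)
})

test_that("boundary solutions carry zero payoff for both types", {
  p <- model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1)
  bs <- boundary_solutions(p)
  expect_equal(bs$points$h_m[1], 0.5)
  expect_equal(bs$points$h_p[2], 0.5)
  expect_true(all(abs(bs$points$gap) <= 1e-9))
  expect_true(all(abs(c(bs$points$W_p, bs$points$W_m)) <= 1e-9))
  # degenerate at x = 1: no help level can beat its own cost
  b1 <- boundary_solutions(model_params(N = 100, x = 1))
  expect_equal(b1$points$h_m[1], 0)
  # the zero-payoff boundary holds for every z > 0 at k = 0
  for (z in c(0.5, 2, 5)) {
    bz <- boundary_solutions(model_params(N = 100, z = z))
    expect_true(all(abs(bz$points$gap) <= 1e-9))
  }
})

test_that("closed-form optima match a numeric best-response oracle", {
  # symmetric market: maximize one type's payoff over its own help with the
  # other type held at the closed-form optimum; at a fixed point the argmax
  # returns the optimum itself
  set.seed(23)
  n <- 1000
  draws <- 0
  while (draws < 20) {
    m <- runif(1, 0.5, 2); x <- runif(1, 0.15, 0.9)
    z <- runif(1, 0, 4); k <- sample(c(0, runif(1, 0, 0.05)), 1)
    p <- model_params(N = n, m = m, x = x, k = k, z = z)
    hs <- optimal_help_symmetric(p)
    if (hs <= 0.01 || hs > 2 * m) next  # keep interior optima
    draws <- draws + 1
    f <- function(g) {
      st <- two_type_state(0.5, h_p = g, h_m = hs)
      r <- help_received_two_type(st, p)
      payoff(r[["r_p"]], g, m, x)
    }
    opt <- optimize(f, c(0, 3 * m), maximum = TRUE, tol = 1e-7)$maximum
    expect_equal(opt, hs, tolerance = 1e-3)
  }

  # monomorphic market: the optimum is independent of z and N and matches a
  # numeric maximization through the allocation engine
  for (i in 1:10) {
    m <- runif(1, 0.5, 2); x <- runif(1, 0.1, 0.9)
    p <- model_params(N = 50, m = m, x = x)
    hs <- optimal_help_monomorphic(p)
    f <- function(g) {
      r <- help_received_two_type(two_type_state(0, h_p = g, h_m = 0), p)
      payoff(r[["r_p"]], g, m, x)
    }
    opt <- optimize(f, c(0, 2 * m), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(opt, hs, tolerance = 1e-4)
  }
  for (z in c(0, 1, 5)) for (N in c(10, 1000)) {
    expect_equal(optimal_help_monomorphic(model_params(N = N, m = 1.3,
                                                       x = 0.3, z = z)),
                 (-0.3 + sqrt(0.3)) * 1.3, tolerance = 1e-12)
  }
  expect_equal(optimal_help_monomorphic(model_params(N = 10, x = 0.25)), 0.25)
  # passive help displaces active help one for one, down to zero
  koff <- (-0.5 + sqrt(0.5)) * 1
  expect_equal(optimal_help_symmetric(model_params(N = Inf, k = koff)), 0,
               tolerance = 1e-12)
  expect_identical(optimal_help_monomorphic(model_params(N = 10, k = 1)), 0)
})

test_that("symmetric optimum crosses m(1 - x) exactly at z = 2/x - 1", {
  for (x in c(0.3, 0.5, 0.8)) {
    zc <- 2 / x - 1
    for (z in zc + c(-0.5, -0.1, -0.01, 0.01, 0.1, 0.5)) {
      hs <- optimal_help_symmetric(model_params(N = Inf, m = 1, x = x, z = z))
      if (z < zc) expect_lt(hs, 1 - x) else expect_gt(hs, 1 - x)
    }
  }
  # the large-N limit is the N -> Inf value
  expect_equal(optimal_help_symmetric(model_params(N = 1e7, z = 2)),
               optimal_help_symmetric(model_params(N = Inf, z = 2)),
               tolerance = 1e-6)
})

test_that("analytic Jacobian agrees with finite differences", {
  p <- model_params(N = 5000, m = 1, x = 0.5, k = 0, z = 1.5)
  h <- 0.21
  for (S_m in c(0.25, 0.5, 0.8)) {
    J <- helpmarket:::.rep_jacobian(1 - S_m, S_m, h, h, p, method = "analytic")
    Jf <- oracle_fd_jacobian(function(y) {
      helpmarket:::.rep_rhs_raw(y[1], y[2], h, h, p)
    }, c(1 - S_m, S_m))
    expect_equal(unname(J), Jf, tolerance = 1e-6)
  }
})

test_that("monomorphic corner carries the repeated invasion eigenvalue", {
  p <- model_params(N = 10000, m = 1, x = 0.5, k = 0, z = 1)
  hstar <- optimal_help_monomorphic(p)
  lambda <- hstar * (hstar + p$m * p$x - p$m) / (hstar + p$m * p$x)
  rep0 <- jacobian_stability(two_type_state(S_m = 0, h_p = hstar, h_m = 0), p)
  expect_equal(sort(Re(rep0$eigenvalues)), rep(lambda, 2), tolerance = 1e-6)
  expect_identical(rep0$classification, "stable")
  expect_lt(lambda, 0)  # h* < m(1 - x) for every m, x
  # with the extinct type instead carried at h*, the payoffs tie and one
  # eigenvalue collapses to zero (sensitivity to the extinct type's help)
  reph <- jacobian_stability(two_type_state(S_m = 0, h_p = hstar,
                                            h_m = hstar), p)
  ev <- sort(Re(reph$eigenvalues))
  expect_equal(ev[1], lambda, tolerance = 1e-6)
  expect_equal(ev[2], 0, tolerance = 1e-8)
  # non-equilibrium states are rejected
  expect_error(jacobian_stability(two_type_state(0.4, 0.3, 0.1), p),
               "not an equilibrium")
})

test_that("interior symmetric equilibrium flips stability at z = 2/x - 1", {
  for (z in c(2.5, 3.5)) {
    p <- model_params(N = 10000, m = 1, x = 0.5, k = 0, z = z)
    hs <- optimal_help_symmetric(p)
    repi <- jacobian_stability(two_type_state(0.5, h_p = hs, h_m = hs), p)
    expect_true(repi$on_neutral_set)
    expect_identical(repi$classification,
                     if (z < 3) "stable" else "unstable")
  }
})

test_that("no-help markets resist lone invaders but not pairs", {
  p <- model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1)
  inv <- invasion_analysis(0.1, p)
  expect_identical(inv$E_00, 0)
  expect_equal(inv$E_H0, -0.1)
  expect_true(inv$zero_help_is_ess)
  expect_identical(inv$min_invaders, 2L)
  # two helpers exchange their full help: W = m H/(m x + H) - H
  expect_equal(inv$payoff_by_count$W_helper[2], 0.1 / 0.6 - 0.1,
               tolerance = 1e-12)
  # E(H, [0]) = -H for any trial level
  for (H in c(0.01, 0.3, 0.9)) {
    expect_equal(invasion_analysis(H, p)$E_H0, -H)
  }
})
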