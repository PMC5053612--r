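# Two-type replicator dynamics: right-hand sides, integration, closed-form
# equilibria and Jacobian stability analysis.
#
# The replicator layer treats the type proportions as continuous coordinates,
# so it evaluates the allocation algebra directly rather than through the
# individual-counting interface of help_received_two_type().

# Raw allocation/payoff algebra as strings, shared between the numerical
# right-hand side and the symbolic (deriv-based) Jacobian.
.rp_str <- paste0(
  "(Sp*N - 1)*(hp + k)*(hp + k)^z/((Sp*N - 1)*(hp + k)^z + Sm*N*(hm + k)^z)",
  " + Sm*N*(hm + k)*(hp + k)^z/(Sp*N*(hp + k)^z + (Sm*N - 1)*(hm + k)^z)")
.rm_str <- paste0(
  "Sp*N*(hp + k)*(hm + k)^z/((Sp*N - 1)*(hp + k)^z + Sm*N*(hm + k)^z)",
  " + (Sm*N - 1)*(hm + k)*(hm + k)^z/(Sp*N*(hp + k)^z + (Sm*N - 1)*(hm + k)^z)")
.Wp_str <- sprintf("(m*(%s)/(m*x + (%s)) - hp)", .rp_str, .rp_str)
.Wm_str <- sprintf("(m*(%s)/(m*x + (%s)) - hm)", .rm_str, .rm_str)
.fp_str <- sprintf("Sp*(%s - (Sp*%s + Sm*%s))", .Wp_str, .Wp_str, .Wm_str)
.fm_str <- sprintf("Sm*(%s - (Sp*%s + Sm*%s))", .Wm_str, .Wp_str, .Wm_str)

.rep_args <- c("Sp", "Sm", "hp", "hm", "N", "m", "x", "k", "z")
.fp_grad <- deriv(parse(text = .fp_str)[[1L]], c("Sp", "Sm"),
                  function.arg = .rep_args)
.fm_grad <- deriv(parse(text = .fm_str)[[1L]], c("Sp", "Sm"),
                  function.arg = .rep_args)

# Continuous-proportion payoffs (no individual counting, no degenerate-pool
# conventions: the smooth field the ODE and Jacobian act on).
.cont_payoffs <- function(Sp, Sm, hp, hm, params) {
  N <- params$N; m <- params$m; x <- params$x; k <- params$k; z <- params$z
  a <- hp + k; b <- hm + k
  alpha <- a^z; beta <- b^z
  d1 <- (Sp * N - 1) * alpha + Sm * N * beta
  d2 <- Sp * N * alpha + (Sm * N - 1) * beta
  rp <- (Sp * N - 1) * a * alpha / d1 + Sm * N * b * alpha / d2
  rm <- Sp * N * a * beta / d1 + (Sm * N - 1) * b * beta / d2
  c(W_p = m * rp / (m * x + rp) - hp, W_m = m * rm / (m * x + rm) - hm,
    r_p = rp, r_m = rm)
}

.rep_rhs_raw <- function(Sp, Sm, hp, hm, params) {
  W <- .cont_payoffs(Sp, Sm, hp, hm, params)
  Wbar <- Sp * W[[1L]] + Sm * W[[2L]]
  c(Sp * (W[[1L]] - Wbar), Sm * (W[[2L]] - Wbar))
}

#' Replicator right-hand side for the two-type market
#'
#' Time derivatives of the type proportions,
#' `dS_i/dt = S_i (W_i - (S_p W_p + S_m W_m))`, with the payoffs evaluated at
#' the state's help levels.  On the simplex the two components sum to zero,
#' and the flow factorizes as `dS_m/dt = S_m (1 - S_m) (W_m - W_p)`.
#'
#' @param state A [two_type_state()] (proportions treated as continuous).
#' @param params A [model_params()] with finite `N`.
#'
#' @return Named numeric vector `c(dS_p, dS_m)`.
#' @examples
#' p <- model_params(N = 1000)
#' replicator_rhs(two_type_state(S_m = 0.3, h_p = 0.2, h_m = 0.1), p)
#' @export
replicator_rhs <- function(state, params) {
  stopifnot(inherits(state, "two_type_state"), inherits(params, "model_params"))
  .require_finite_N(params)
  out <- .rep_rhs_raw(state$S_p, state$S_m, state$h_p, state$h_m, params)
  if (any(!is.finite(out)))
    stop("replicator field is undefined here (a zero-weight allocation pool);",
         " use positive help or passive help k > 0")
  c(dS_p = out[[1L]], dS_m = out[[2L]])
}

#' Integrate the two-type replicator dynamics
#'
#' Integrates the proportion dynamics at fixed help levels with an adaptive
#' stiff-capable solver (via \pkg{deSolve}), renormalizing the terminal
#' simplex coordinates and reporting the accumulated drift.
#'
#' @param state0 Initial [two_type_state()].
#' @param params A [model_params()] with finite `N`.
#' @param horizon Integration horizon (model time, > 0).
#' @param tol Equilibrium tolerance: the run is flagged converged when the
#'   max-norm of the right-hand side at the terminal state is below `tol`.
#' @param n_out Number of output samples along the trajectory.
#' @param method Solver passed to [deSolve::ode()].
#'
#' @return A `data.frame` of class `helpmarket_trajectory` with columns
#'   `time, S_p, S_m, h_p, h_m, W_p, W_m` and attributes `converged` (logical)
#'   and `drift` (max simplex violation).
#' @examples
#' p <- model_params(N = 1000, z = 1)
#' tr <- integrate_replicator(two_type_state(0.7, h_p = 0.2, h_m = 0),
#'                            p, horizon = 200)
#' tail(tr, 1)
#' @export
integrate_replicator <- function(state0, params, horizon = 1000, tol = 1e-8,
                                 n_out = 201L, method = "lsoda") {
  stopifnot(inherits(state0, "two_type_state"),
            inherits(params, "model_params"), horizon > 0, tol > 0)
  .require_finite_N(params)
  times <- seq(0, horizon, length.out = n_out)
  f <- function(t, y, parms) {
    list(.rep_rhs_raw(y[[1L]], y[[2L]], state0$h_p, state0$h_m, params))
  }
  sol <- deSolve::ode(y = c(Sp = state0$S_p, Sm = state0$S_m), times = times,
                      func = f, parms = NULL, method = method,
                      rtol = 1e-10, atol = 1e-12)
  Sp <- sol[, "Sp"]; Sm <- sol[, "Sm"]
  drift <- max(abs(Sp + Sm - 1))
  # renormalize onto the simplex
  tot <- Sp + Sm
  Sp <- Sp / tot; Sm <- Sm / tot
  W <- t(vapply(seq_along(Sp), function(i) {
    .cont_payoffs(Sp[i], Sm[i], state0$h_p, state0$h_m, params)[1:2]
  }, numeric(2L)))
  rhs_end <- .rep_rhs_raw(Sp[length(Sp)], Sm[length(Sm)],
                          state0$h_p, state0$h_m, params)
  converged <- max(abs(rhs_end)) <= tol
  if (!converged)
    warning("trajectory did not reach an equilibrium within the horizon ",
            sprintf("(|rhs| = %.3g > %g)", max(abs(rhs_end)), tol))
  out <- data.frame(time = times, S_p = Sp, S_m = Sm,
                    h_p = state0$h_p, h_m = state0$h_m,
                    W_p = W[, 1L], W_m = W[, 2L])
  structure(out, class = c("helpmarket_trajectory", "data.frame"),
            converged = converged, drift = drift)
}

#' Boundary solutions of the equal-payoff condition
#'
#' The equal-payoff condition `W_m = W_p` has the symmetric family
#' `h_p = h_m` (any common level, any proportion split) and, when one type
#' provides no help, the boundary points `(0, m - m x)` and `(m - m x, 0)`:
#' at those points both types' benefits equal their costs and the payoff is
#' zero for everyone.  The boundary values hold for every `z > 0` at `k = 0`
#' (a non-helping type has zero matching weight, so the helping type's help
#' recirculates within itself and `r` `= h`); at `z = 0` the non-helping type
#' receives equal shares and the boundary points no longer solve the
#' condition.
#'
#' @param params A [model_params()] with finite `N`.
#'
#' @return An object of class `boundary_solutions`: a list with the symmetric
#'   family description and a `data.frame` `points` with columns
#'   `h_p, h_m, W_p, W_m, gap` evaluated at `S_p = S_m = 1/2` under the
#'   supplied parameters.
#' @examples
#' boundary_solutions(model_params(N = 100, m = 1, x = 0.5))
#' @export
boundary_solutions <- function(params) {
  stopifnot(inherits(params, "model_params"))
  .require_finite_N(params)
  hb <- params$m - params$m * params$x
  pts <- data.frame(h_p = c(0, hb), h_m = c(hb, 0))
  # evaluate through the allocation engine at a balanced split
  M <- floor(params$N / 2)
  P <- params$N - M
  eva <- t(vapply(seq_len(nrow(pts)), function(i) {
    .tt_payoffs(pts$h_p[i], pts$h_m[i], P, M, params$N, params$m, params$x,
                params$k, params$z)[1:2]
  }, numeric(2L)))
  pts$W_p <- eva[, 1L]
  pts$W_m <- eva[, 2L]
  pts$gap <- pts$W_m - pts$W_p
  structure(list(symmetric_family = "h_p = h_m (any common level, any S)",
                 points = pts, params = params),
            class = "boundary_solutions")
}

#' @export
print.boundary_solutions <- function(x, ...) {
  cat("Equal-payoff solutions\n")
  cat("  symmetric family:", x$symmetric_family, "\n")
  cat("  boundary points:\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Optimal help at the symmetric interior equilibrium
#'
#' Closed-form level of active help that maximizes a type's payoff when both
#' types provide the same help and occupy equal halves of the market,
#' obtained by solving `dW/dh = 0` at the symmetric state:
#' `h* = m (-x + sqrt(x (N-2)((z+1)N - 1) / (2 (N-1)^2))) - k`,
#' clamped at zero.  As `N` grows the radicand tends to `x (z + 1) / 2`, so
#' the optimum stops depending on the population size; `h*` stays below
#' `m (1 - x)` exactly when `z < 2/x - 1`.
#'
#' @param params A [model_params()]; `N` may be `Inf` for the
#'   infinite-population limit, otherwise `N >= 3` is required.
#'
#' @return The optimal common help level `h*` (>= 0).
#' @examples
#' optimal_help_symmetric(model_params(N = Inf, m = 1, x = 0.5, z = 1))
#' @export
optimal_help_symmetric <- function(params) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N
  if (is.finite(N) && N < 3)
    stop("the symmetric optimum requires N >= 3")
  g <- if (is.infinite(N)) (params$z + 1) / 2
       else (N - 2) * ((params$z + 1) * N - 1) / (2 * (N - 1)^2)
  h <- params$m * (-params$x + sqrt(params$x * g)) - params$k
  max(0, h)
}

#' Optimal help in a monomorphic population
#'
#' When a single type occupies the whole market, every dispensed unit returns
#' to the type itself, so `r` `= h + k` and the payoff-maximizing active help is
#' `h* = (-x + sqrt(x)) m - k`, clamped at zero.  The optimum depends on
#' neither the degree of matching `z` nor the population size `N`.
#'
#' @param params A [model_params()].
#'
#' @return The optimal help level `h*` (>= 0).
#' @examples
#' optimal_help_monomorphic(model_params(N = 100, m = 1, x = 0.25))  # 0.25
#' @export
optimal_help_monomorphic <- function(params) {
  stopifnot(inherits(params, "model_params"))
  max(0, params$m * (-params$x + sqrt(params$x)) - params$k)
}

# 2x2 Jacobian of the replicator field with respect to (S_p, S_m), treating
# the two proportions as free coordinates.
.rep_jacobian <- function(Sp, Sm, hp, hm, params,
                          method = c("analytic", "fd"), eps = 1e-6) {
  method <- match.arg(method)
  if (method == "analytic") {
    gp <- attr(.fp_grad(Sp, Sm, hp, hm, params$N, params$m, params$x,
                        params$k, params$z), "gradient")
    gm <- attr(.fm_grad(Sp, Sm, hp, hm, params$N, params$m, params$x,
                        params$k, params$z), "gradient")
    J <- rbind(gp[1L, ], gm[1L, ])
  } else {
    J <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      dp <- dm <- 0
      if (j == 1L) dp <- eps else dm <- eps
      up <- .rep_rhs_raw(Sp + dp, Sm + dm, hp, hm, params)
      dn <- .rep_rhs_raw(Sp - dp, Sm - dm, hp, hm, params)
      J[, j] <- (up - dn) / (2 * eps)
    }
  }
  dimnames(J) <- list(c("dS_p", "dS_m"), c("S_p", "S_m"))
  J
}

#' Jacobian stability of a replicator equilibrium
#'
#' Evaluates the Jacobian of the replicator field at an equilibrium, treating
#' `(S_p, S_m)` as two free coordinates (the convention under which the
#' monomorphic corners with the extinct type at `h = 0` and `k = 0` carry the
#' repeated eigenvalue `h*(h* + m x - m)/(h* + m x)`), together with the
#' constrained one-dimensional derivative along the simplex.
#'
#' States on the neutral set `h_p = h_m` have an identically vanishing flow in
#' the proportions, so their stability is decided transversally: a rare
#' quit-invader (`h = 0`) grows against a resident earning `W` at rate
#' `-W` per unit time.  The report therefore carries a `help_eigenvalue`
#' `-W(resident)`; for a resident at the symmetric optimum this is negative
#' exactly when `z < 2/x - 1`.
#'
#' @param at A [two_type_state()] that is an equilibrium of the flow
#'   (max-norm of [replicator_rhs()] at most `tol`).
#' @param params A [model_params()] with finite `N`.
#' @param tol Equilibrium tolerance on the right-hand side.
#' @param method `"analytic"` (symbolic differentiation, default) or `"fd"`
#'   (central finite differences).
#'
#' @return An object of class `equilibrium_report`: location, the 2x2
#'   Jacobian, its eigenvalues, the constrained derivative, the transverse
#'   `help_eigenvalue`, and a `classification` in
#'   `{"stable", "unstable", "neutral-line", "non-hyperbolic"}`.
#' @examples
#' p <- model_params(N = 10000, m = 1, x = 0.5, k = 0, z = 1)
#' hstar <- optimal_help_monomorphic(p)
#' jacobian_stability(two_type_state(S_m = 0, h_p = hstar, h_m = 0), p)
#' @export
jacobian_stability <- function(at, params, tol = 1e-8,
                               method = c("analytic", "fd")) {
  stopifnot(inherits(at, "two_type_state"), inherits(params, "model_params"))
  .require_finite_N(params)
  method <- match.arg(method)
  rhs <- .rep_rhs_raw(at$S_p, at$S_m, at$h_p, at$h_m, params)
  if (any(!is.finite(rhs)) || max(abs(rhs)) > tol)
    stop(sprintf("state is not an equilibrium (|rhs| = %.3g > %g)",
                 max(abs(rhs)), tol))
  J <- .rep_jacobian(at$S_p, at$S_m, at$h_p, at$h_m, params, method = method)
  eig <- eigen(J, only.values = TRUE)$values
  # constrained derivative along the simplex: d/dSm of Sm (1 - Sm)(Wm - Wp)
  eps <- 1e-6
  g <- function(Sm) {
    W <- .cont_payoffs(1 - Sm, Sm, at$h_p, at$h_m, params)
    Sm * (1 - Sm) * (W[[2L]] - W[[1L]])
  }
  constrained <- (g(at$S_m + eps) - g(at$S_m - eps)) / (2 * eps)
  # transverse (invasion) eigenvalue: -W of the resident strategy
  W <- .cont_payoffs(at$S_p, at$S_m, at$h_p, at$h_m, params)
  W_res <- if (at$S_p >= 1 - 1e-9) W[[1L]]
           else if (at$S_m >= 1 - 1e-9) W[[2L]]
           else if (abs(at$h_p - at$h_m) <= 1e-12) W[[1L]]
           else NA_real_
  help_eig <- -W_res
  tol_eig <- 1e-6
  re <- Re(eig)
  classification <- if (any(re > tol_eig)) {
    "unstable"
  } else if (all(re < -tol_eig)) {
    "stable"
  } else if (!is.na(help_eig)) {
    # zero eigenvalue from the neutral direction: decide transversally
    if (help_eig < -tol_eig) "stable"
    else if (help_eig > tol_eig) "unstable"
    else "neutral-line"
  } else {
    "non-hyperbolic"
  }
  neutral <- abs(at$h_p - at$h_m) <= 1e-12 && at$S_p > 1e-9 && at$S_m > 1e-9
  structure(list(location = c(S_p = at$S_p, S_m = at$S_m,
                              h_p = at$h_p, h_m = at$h_m),
                 jacobian = J, eigenvalues = eig,
                 constrained_derivative = constrained,
                 help_eigenvalue = help_eig,
                 on_neutral_set = neutral,
                 classification = classification),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Replicator equilibrium report\n")
  cat(sprintf("  location: S_p = %g, S_m = %g, h_p = %g, h_m = %g\n",
              x$location[1L], x$location[2L], x$location[3L], x$location[4L]))
  cat("  eigenvalues (2-D):", paste(format(x$eigenvalues, digits = 6),
                                    collapse = ", "), "\n")
  cat(sprintf("  constrained derivative: %s\n",
              format(x$constrained_derivative, digits = 6)))
  cat(sprintf("  transverse help eigenvalue: %s\n",
              format(x$help_eigenvalue, digits = 6)))
  cat("  classification:", x$classification,
      if (x$on_neutral_set) "(on the neutral set h_p = h_m)" else "", "\n")
  invisible(x)
}

#' Invasion analysis of helping against a market of non-helpers
#'
#' With no passive help, a lone helper's help is dispensed but nothing comes
#' back (non-helpers have zero matching weight), so its payoff is `-H` while
#' non-helpers earn 0: providing no help is evolutionarily stable.  Helping
#' pays only once at least two individuals help in the same time step; this
#' returns the smallest such count.
#'
#' @param H Trial help level of the invaders (> 0).
#' @param params A [model_params()] with finite `N` and `k = 0`.
#'
#' @return An object of class `invasion_report`: payoffs `E_00` (non-helper
#'   among non-helpers), `E_H0` (lone helper), a table of helper payoffs by
#'   invader count, the minimum invader count with positive helper payoff
#'   (`NA` if none up to `N`), and whether `h = 0` resists invasion by `H`.
#' @examples
#' invasion_analysis(0.1, model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1))
#' @export
invasion_analysis <- function(H, params) {
  stopifnot(is.numeric(H), length(H) == 1L, H > 0,
            inherits(params, "model_params"))
  .require_finite_N(params)
  if (params$k != 0)
    stop("invasion analysis applies to the k = 0 regime")
  N <- params$N
  E_00 <- payoff(help_received_agents(agent_population(rep(0, N), k = 0),
                                      z = params$z)[1L],
                 0, params$m, params$x)
  js <- seq_len(min(N - 1, 50L))
  W_helper <- vapply(js, function(j) {
    pop <- agent_population(c(rep(H, j), rep(0, N - j)), k = 0)
    r <- help_received_agents(pop, z = params$z)
    payoff(r[1L], H, params$m, params$x)
  }, numeric(1L))
  pos <- which(W_helper > 0)
  structure(list(H = H, E_00 = E_00, E_H0 = W_helper[1L],
                 payoff_by_count = data.frame(helpers = js,
                                              W_helper = W_helper),
                 min_invaders = if (length(pos)) js[min(pos)] else NA_integer_,
                 zero_help_is_ess = W_helper[1L] < E_00),
            class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat("Invasion analysis (k = 0)\n")
  cat(sprintf("  E(0,[0]) = %g; E(H,[0]) = %g at H = %g\n",
              x$E_00, x$E_H0, x$H))
  cat(sprintf("  minimum simultaneous helpers for positive payoff: %s\n",
              format(x$min_invaders)))
  cat(sprintf("  no-help strategy is an ESS: %s\n", x$zero_help_is_ess))
  invisible(x)
}
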