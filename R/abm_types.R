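# Two-type incremental-mutation simulator.  Both types are homogeneous; at
# each step each type proposes a candidate help level one increment away,
# evaluates the expected payoff of the whole type adopting it against the
# other type's help from the previous step, and adopts the candidate only on
# strict improvement.  Proportions are fixed or evolve by payoff-driven
# switching.

# Single synchronous update of the two help levels.  `lag_hp`/`lag_hm` are
# the other-type help levels from the previous step; both types update from
# the same snapshot.  Returns the new help pair and whether anything changed.
.step_types_core <- function(h_p, h_m, lag_hp, lag_hm, P, M, N, m, x, k, z,
                             delta, both_directions) {
  new_hp <- h_p
  new_hm <- h_m
  if (both_directions) {
    dirs_p <- c(delta, -delta)
    dirs_m <- c(delta, -delta)
  } else {
    d <- runif(2L)
    dirs_p <- if (d[1L] < 0.5) delta else -delta
    dirs_m <- if (d[2L] < 0.5) delta else -delta
  }
  if (P > 0) {
    cur <- .tt_payoffs(h_p, lag_hm, P, M, N, m, x, k, z)[[1L]]
    best <- cur
    for (dd in dirs_p) {
      cand <- max(0, h_p + dd)
      if (cand == h_p) next
      W <- .tt_payoffs(cand, lag_hm, P, M, N, m, x, k, z)[[1L]]
      if (W > best) { best <- W; new_hp <- cand }
    }
  }
  if (M > 0) {
    cur <- .tt_payoffs(lag_hp, h_m, P, M, N, m, x, k, z)[[2L]]
    best <- cur
    for (dd in dirs_m) {
      cand <- max(0, h_m + dd)
      if (cand == h_m) next
      W <- .tt_payoffs(lag_hp, cand, P, M, N, m, x, k, z)[[2L]]
      if (W > best) { best <- W; new_hm <- cand }
    }
  }
  list(h_p = new_hp, h_m = new_hm,
       changed = (new_hp != h_p) || (new_hm != h_m))
}

#' One synchronous mutation step of the two-type simulator
#'
#' Each type draws a candidate help level one mutation increment away
#' (direction sampled uniformly, or both directions evaluated when
#' `config$both_directions` is set), computes the expected payoff of the whole
#' type adopting the candidate against the other type's help in `prev_state`,
#' and adopts it only if the expected payoff strictly exceeds the current one.
#' Help never goes below zero and both types update simultaneously from the
#' same lagged snapshot.
#'
#' @param state Current [two_type_state()].
#' @param prev_state Lagged snapshot supplying the other type's help levels;
#'   defaults to `state`.
#' @param params A [model_params()] with finite `N`.
#' @param config A [sim_config()].
#'
#' @return The updated [two_type_state()] (proportions unchanged).
#' @examples
#' p <- model_params(N = 100, z = 1)
#' s <- two_type_state(S_m = 0.5, h_p = 0.1, h_m = 0.1)
#' step_types(s, s, p, sim_config(mutation_increment = 0.01))
#' @export
step_types <- function(state, prev_state = state, params,
                       config = sim_config()) {
  stopifnot(inherits(state, "two_type_state"),
            inherits(prev_state, "two_type_state"),
            inherits(params, "model_params"), inherits(config, "sim_config"))
  .require_finite_N(params)
  P <- round(state$S_p * params$N)
  M <- round(state$S_m * params$N)
  if (abs(P - state$S_p * params$N) > 1e-6)
    stop("'S_p * N' must be a whole number of individuals")
  st <- .step_types_core(state$h_p, state$h_m, prev_state$h_p,
                         prev_state$h_m, P, M, params$N, params$m, params$x,
                         params$k, params$z, config$mutation_increment,
                         config$both_directions)
  two_type_state(S_m = state$S_m, h_p = st$h_p, h_m = st$h_m,
                 S_p = state$S_p)
}

# Shared engine behind run_fixed_proportions() and
# run_evolving_proportions().
.run_types_engine <- function(params, config, S_m0, h_p0, h_m0, evolve) {
  N <- params$N; m <- params$m; x <- params$x; k <- params$k; z <- params$z
  delta <- config$mutation_increment
  M <- round(S_m0 * N)
  if (abs(M - S_m0 * N) > 1e-6)
    stop("'S_m * N' must be a whole number of individuals")
  P <- N - M
  h_p <- if (P > 0) h_p0 else 0
  h_m <- if (M > 0) h_m0 else 0
  lag_hp <- h_p
  lag_hm <- h_m
  nrec <- floor(config$max_steps / config$record_every) + 2L
  rec <- matrix(NA_real_, nrec, 7L)
  colnames(rec) <- c("step", "S_p", "S_m", "h_p", "h_m", "W_p", "W_m")
  irec <- 0L
  quiet <- 0L
  converged <- FALSE
  accepted <- 0L
  step <- 0L
  W <- .tt_payoffs(h_p, h_m, P, M, N, m, x, k, z)
  record <- function(step) {
    irec <<- irec + 1L
    rec[irec, ] <<- c(step, P / N, M / N, h_p, h_m, W[[1L]], W[[2L]])
  }
  record(0L)
  while (step < config$max_steps) {
    step <- step + 1L
    st <- .step_types_core(h_p, h_m, lag_hp, lag_hm, P, M, N, m, x, k, z,
                           delta, config$both_directions)
    lag_hp <- h_p
    lag_hm <- h_m
    h_p <- st$h_p
    h_m <- st$h_m
    if (st$changed) accepted <- accepted + 1L
    switched <- FALSE
    W <- .tt_payoffs(h_p, h_m, P, M, N, m, x, k, z)
    if (evolve && P > 0L && M > 0L) {
      gap <- W[[2L]] - W[[1L]]
      p_sw <- min(config$switch_fraction_scale * abs(gap), config$switch_cap)
      if (p_sw > 0) {
        loser <- if (gap > 0) P else M
        n_sw <- rbinom(1L, loser, p_sw)
        if (n_sw > 0L) {
          if (gap > 0) { P <- P - n_sw; M <- M + n_sw }
          else { M <- M - n_sw; P <- P + n_sw }
          switched <- TRUE
          if (P == 0L) h_p <- 0
          if (M == 0L) h_m <- 0
          W <- .tt_payoffs(h_p, h_m, P, M, N, m, x, k, z)
        }
      }
    }
    if (st$changed || switched) quiet <- 0L else quiet <- quiet + 1L
    if (step %% config$record_every == 0L) record(step)
    if (quiet >= config$convergence_window) { converged <- TRUE; break }
  }
  if (step %% config$record_every != 0L) record(step)
  traj <- as.data.frame(rec[seq_len(irec), , drop = FALSE])
  label <- .label_type_outcome(h_p, h_m, P, M, config$tolerance, converged)
  structure(list(equilibrium = c(h_p = h_p, h_m = h_m, S_p = P / N,
                                 S_m = M / N, W_p = W[[1L]], W_m = W[[2L]]),
                 trajectory = traj, converged = converged, label = label,
                 steps = step, accepted_moves = accepted,
                 params = params, config = config, evolve = evolve),
            class = "type_sim_result")
}

# Outcome labelling.  "competitive": both types actively helping at a common
# level; "p-quits"/"m-quits": one type at (or near) zero help; "collapse":
# nobody helps; "indeterminate": anything else (e.g. a non-converged run).
.label_type_outcome <- function(h_p, h_m, P, M, tol, converged) {
  if (!converged) return("indeterminate")
  if (M == 0L || (h_m <= tol && h_p > tol)) {
    if (P == 0L) return("collapse")
    return("m-quits")
  }
  if (P == 0L || (h_p <= tol && h_m > tol)) return("p-quits")
  if (h_p <= tol && h_m <= tol) return("collapse")
  if (abs(h_p - h_m) <= tol) return("competitive")
  "indeterminate"
}

#' @export
print.type_sim_result <- function(x, ...) {
  cat("Two-type simulation",
      if (x$evolve) "(evolving proportions)" else "(fixed proportions)", "\n")
  eq <- x$equilibrium
  cat(sprintf("  equilibrium: h_p = %g, h_m = %g, S_p = %g, S_m = %g\n",
              eq[["h_p"]], eq[["h_m"]], eq[["S_p"]], eq[["S_m"]]))
  cat(sprintf("  payoffs: W_p = %.4g, W_m = %.4g\n",
              eq[["W_p"]], eq[["W_m"]]))
  cat(sprintf("  label: %s; converged: %s after %d steps (%d accepted moves)\n",
              x$label, x$converged, x$steps, x$accepted_moves))
  invisible(x)
}

#' Two-type simulation at fixed proportions
#'
#' Iterates [step_types()] at a fixed proportion split until neither type
#' accepts a change for a full convergence window (or `max_steps` is
#' reached).  Initial help levels default to independent uniform draws on
#' `[0, m]`.
#'
#' @param S_m Proportion of type-m individuals; `S_m * N` must be a whole
#'   number.
#' @param params A [model_params()] with finite `N`.
#' @param config A [sim_config()]; `config$seed`, when set, seeds the run.
#' @param init Optional numeric `c(h_p0, h_m0)` initial help levels.
#'
#' @return A `type_sim_result`: the equilibrium help levels, proportions and
#'   payoffs, the recorded trajectory, a convergence flag and an outcome
#'   label (`"competitive"`, `"p-quits"`, `"m-quits"`, `"collapse"` or
#'   `"indeterminate"`).
#' @examples
#' p <- model_params(N = 1000, z = 1)
#' cfg <- sim_config(mutation_increment = 0.01, seed = 1)
#' run_fixed_proportions(0.5, p, cfg)
#' @export
run_fixed_proportions <- function(S_m, params, config = sim_config(),
                                  init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"),
            is.numeric(S_m), S_m >= 0, S_m <= 1)
  .require_finite_N(params)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- runif(2L, 0, params$m)
  .run_types_engine(params, config, S_m, init[1L], init[2L], evolve = FALSE)
}

#' Two-type simulation with payoff-driven evolving proportions
#'
#' As [run_fixed_proportions()], but after each help-mutation step a random
#' number of individuals of the lower-payoff type switches to the other type:
#' each with probability `switch_fraction_scale * |W_m - W_p|`, capped at
#' `switch_cap`.  A type that loses all members has its (now meaningless)
#' help frozen at zero and cannot re-enter.
#'
#' @param params A [model_params()] with finite `N`.
#' @param config A [sim_config()].
#' @param S_m0 Initial type-m proportion, in (0, 1); `S_m0 * N` must be a
#'   whole number.
#' @param init Optional numeric `c(h_p0, h_m0)` initial help levels
#'   (default: independent uniform draws on `[0, m]`).
#'
#' @return A `type_sim_result` (see [run_fixed_proportions()]).
#' @examples
#' p <- model_params(N = 1000, z = 0.5)
#' cfg <- sim_config(mutation_increment = 0.01, seed = 1)
#' run_evolving_proportions(p, cfg, S_m0 = 0.3, init = c(0.11, 0.11))
#' @export
run_evolving_proportions <- function(params, config = sim_config(),
                                     S_m0 = 0.3, init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"),
            is.numeric(S_m0), S_m0 > 0, S_m0 < 1)
  .require_finite_N(params)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- runif(2L, 0, params$m)
  .run_types_engine(params, config, S_m0, init[1L], init[2L], evolve = TRUE)
}

#' Basin-of-attraction map over initial help levels
#'
#' Runs the fixed-proportion simulator from a grid of initial `(h_p, h_m)`
#' pairs and labels each grid point by the equilibrium it reaches.  For
#' `z <= 1` a single label appears; for `z > 1` the competitive basin around
#' the diagonal coexists with the two quitting basins.
#'
#' @param initial_grid Either a `data.frame` with columns `h_p0` and `h_m0`,
#'   or a list with numeric vectors `h_p` and `h_m` whose Cartesian product
#'   forms the grid.
#' @param S_m Fixed proportion of type-m individuals.
#' @param params A [model_params()] with finite `N`.
#' @param config A [sim_config()]; `config$seed`, when set, seeds the whole
#'   map once (runs then consume the stream in grid order).
#'
#' @return A `data.frame` of class `basin_map` with columns
#'   `h_p0, h_m0, label, h_p, h_m, converged`.
#' @examples
#' p <- model_params(N = 100, z = 2)
#' cfg <- sim_config(mutation_increment = 0.01, max_steps = 5000, seed = 1)
#' bm <- basin_map(list(h_p = c(0.1, 0.5), h_m = c(0.1, 0.5)), 0.5, p, cfg)
#' table(bm$label)
#' @export
basin_map <- function(initial_grid, S_m, params, config = sim_config()) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  .require_finite_N(params)
  if (is.data.frame(initial_grid)) {
    stopifnot(all(c("h_p0", "h_m0") %in% names(initial_grid)))
    grid <- initial_grid[c("h_p0", "h_m0")]
  } else {
    grid <- expand.grid(h_p0 = initial_grid$h_p, h_m0 = initial_grid$h_m,
                        KEEP.OUT.ATTRS = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- .run_types_engine(params, cfg, S_m, grid$h_p0[i], grid$h_m0[i],
                           evolve = FALSE)
    data.frame(label = r$label, h_p = r$equilibrium[["h_p"]],
               h_m = r$equilibrium[["h_m"]], converged = r$converged)
  })
  out <- cbind(grid, do.call(rbind, res))
  class(out) <- c("basin_map", "data.frame")
  out
}

#' Equilibrium help and payoffs across fixed proportion splits
#'
#' Runs the fixed-proportion simulator for each value of `S_m` on a grid
#' (default 0 to 1 in steps of 0.1) and tabulates the equilibrium help
#' levels, payoffs and outcome labels.
#'
#' @param params A [model_params()] with finite `N`; `N` should be divisible
#'   by the proportion grid so that `S_m * N` counts individuals.
#' @param config A [sim_config()].
#' @param S_grid Numeric vector of `S_m` values.
#' @param init Optional fixed initial help pair used for every run; default
#'   draws fresh uniform initials per run.
#'
#' @return A `data.frame` with one row per grid value: `S_m, h_p, h_m, W_p,
#'   W_m, label, converged, steps`.
#' @examples
#' p <- model_params(N = 100, z = 1)
#' cfg <- sim_config(mutation_increment = 0.01, seed = 1)
#' proportion_sweep(p, cfg, S_grid = c(0.3, 0.5))
#' @export
proportion_sweep <- function(params, config = sim_config(),
                             S_grid = seq(0, 1, by = 0.1), init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  .require_finite_N(params)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  rows <- lapply(S_grid, function(S_m) {
    ini <- if (is.null(init)) runif(2L, 0, params$m) else init
    r <- .run_types_engine(params, cfg, S_m, ini[1L], ini[2L], evolve = FALSE)
    eq <- r$equilibrium
    data.frame(S_m = S_m, h_p = eq[["h_p"]], h_m = eq[["h_m"]],
               W_p = eq[["W_p"]], W_m = eq[["W_m"]], label = r$label,
               converged = r$converged, steps = r$steps)
  })
  do.call(rbind, rows)
}
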