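# Fully heterogeneous N-person simulator: every individual controls its own
# help level and mutates it incrementally, evaluating candidates against the
# other agents' lagged help.

#' One synchronous mutation step of the heterogeneous simulator
#'
#' Each agent draws a candidate help level one increment away (direction
#' sampled uniformly per agent unless `dirs` is supplied), evaluates its
#' expected payoff against all *other* agents' help in `prev_pop`, and adopts
#' the candidate only on strict improvement.  Help is clamped at zero and all
#' updates are simultaneous.
#'
#' @param pop Current [agent_population()].
#' @param prev_pop Lagged snapshot of the population; defaults to `pop`.
#' @param params A [model_params()] (supplies `m`, `x`, `z`; `k` is taken
#'   from the population).
#' @param config A [sim_config()] (supplies the mutation increment).
#' @param dirs Optional numeric vector of signed increments, one per agent
#'   (overrides the sampled directions; useful for deterministic tests).
#'
#' @return The updated [agent_population()].
#' @examples
#' p <- model_params(N = 5, z = 1)
#' pop <- agent_population(c(0.2, 0.3, 0.1, 0, 0.4))
#' step_agents(pop, pop, p, sim_config(mutation_increment = 0.01, seed = 1))
#' @export
step_agents <- function(pop, prev_pop = pop, params, config = sim_config(),
                        dirs = NULL) {
  stopifnot(inherits(pop, "agent_population"),
            inherits(prev_pop, "agent_population"),
            inherits(params, "model_params"), inherits(config, "sim_config"))
  n <- length(pop$h)
  stopifnot(length(prev_pop$h) == n)
  if (is.null(dirs)) {
    dirs <- ifelse(runif(n) < 0.5, 1, -1) * config$mutation_increment
  } else {
    stopifnot(is.numeric(dirs), length(dirs) == n)
  }
  h_new <- .step_agents_kernel(pop$h, prev_pop$h, pop$k, params$z, params$m,
                               params$x, dirs)
  agent_population(h_new, k = pop$k)
}

# Cluster/outcome summary of a final help distribution.  Agents providing at
# most 2 * increment are non-helpers; among the rest, the competitive cluster
# collects agents within 2 * increment of the helpers' median level.  The
# run-level outcome is "competitive" when every agent takes part in a common
# stationary positive cluster (the all-equal-help equilibrium), "collapse"
# when nobody helps, and "mixed" otherwise (a helper cluster coexisting with
# non-helpers, or no convergence).
.summarize_agents <- function(h, W, delta, converged) {
  n <- length(h)
  cut <- 2 * delta
  non <- h <= cut
  helpers <- h > cut
  if (any(helpers)) {
    level <- stats::median(h[helpers])
    cluster <- helpers & abs(h - level) <= cut
  } else {
    level <- 0
    cluster <- rep(FALSE, n)
  }
  outcome <- if (!converged) "mixed"
  else if (all(non)) "collapse"
  else if (all(cluster)) "competitive"
  else "mixed"
  list(cluster_level = level, n_competitive = sum(cluster),
       n_nonhelpers = sum(non), n_other = n - sum(cluster) - sum(non),
       mean_helper_payoff = if (any(cluster)) mean(W[cluster]) else NA_real_,
       outcome = outcome)
}

#' Heterogeneous N-person simulation
#'
#' Iterates [step_agents()] from (by default) independent uniform initial
#' help levels on `[0, m]` until no agent accepts a change for a full
#' convergence window.  The typical long-run state is bimodal: a cluster of
#' competitive helpers at a common high level and the remaining agents at
#' zero.
#'
#' @param params A [model_params()] with finite `N` (the heterogeneous study
#'   condition is `N = 200`).
#' @param config A [sim_config()]; `config$seed`, when set, seeds the run.
#' @param h0 Optional numeric vector of initial help levels (length `N`).
#'
#' @return An `agent_sim_result`: final help and payoff vectors, the cluster
#'   summary (competitive-helper count, non-helper count, cluster help level,
#'   mean helper payoff), an outcome label in
#'   `{"competitive", "mixed", "collapse"}`, and convergence diagnostics.
#' @examples
#' p <- model_params(N = 50, z = 2)
#' cfg <- sim_config(mutation_increment = 0.01, max_steps = 4000, seed = 1)
#' run_heterogeneous(p, cfg)
#' @export
run_heterogeneous <- function(params, config = sim_config(), h0 = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  .require_finite_N(params)
  n <- params$N
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(h0)) h0 <- runif(n, 0, params$m)
  stopifnot(length(h0) == n)
  delta <- config$mutation_increment
  h <- as.numeric(h0)
  h_prev <- h
  quiet <- 0L
  converged <- FALSE
  accepted <- 0L
  step <- 0L
  while (step < config$max_steps) {
    step <- step + 1L
    dirs <- ifelse(runif(n) < 0.5, 1, -1) * delta
    h_new <- .step_agents_kernel(h, h_prev, params$k, params$z, params$m,
                                 params$x, dirs)
    changed <- any(h_new != h)
    h_prev <- h
    h <- h_new
    if (changed) {
      accepted <- accepted + 1L
      quiet <- 0L
    } else {
      quiet <- quiet + 1L
    }
    if (quiet >= config$convergence_window) { converged <- TRUE; break }
  }
  if (!converged)
    warning("heterogeneous run did not converge within max_steps; ",
            "returning partial results")
  W <- .agent_payoffs_kernel(h, params$k, params$z, params$m, params$x)
  r <- help_received_agents(agent_population(h, k = params$k), z = params$z)
  summ <- .summarize_agents(h, W, delta, converged)
  structure(list(h = h, r = r, W = W, summary = summ,
                 outcome = summ$outcome, converged = converged,
                 steps = step, accepted_steps = accepted,
                 params = params, config = config),
            class = "agent_sim_result")
}

#' @export
print.agent_sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Heterogeneous simulation (N = %d)\n", length(x$h)))
  cat(sprintf("  outcome: %s; converged: %s after %d steps\n",
              x$outcome, x$converged, x$steps))
  cat(sprintf("  competitive helpers: %d at level %.4g (mean payoff %.4g)\n",
              s$n_competitive, s$cluster_level, s$mean_helper_payoff))
  cat(sprintf("  non-helpers: %d; other: %d\n", s$n_nonhelpers, s$n_other))
  invisible(x)
}

#' Passive-help sweep of the heterogeneous simulator
#'
#' Runs replicate heterogeneous simulations over a grid of passive-help and
#' degree-of-matching values and records, for each cell, how often the run
#' ends in the fully competitive equilibrium in which every individual
#' provides the same positive help.  Small amounts of passive help force
#' every individual into competition; the required amount grows slowly with
#' `z`.
#'
#' @param k_grid Numeric vector of passive-help levels (>= 0).
#' @param z_grid Numeric vector of degrees of matching.
#' @param replicates Number of replicate runs per cell (>= 1).
#' @param params A [model_params()] with finite `N`; its `k` and `z` are
#'   overridden cell by cell.
#' @param config A [sim_config()]; replicate `i` uses seed
#'   `config$seed + i` (the same seed list in every cell).
#'
#' @return A `sweep_result`: `runs` (one row per replicate: `k, z, replicate,
#'   seed, outcome, helper_count, cluster_level, helper_payoff`) and `freq`
#'   (per-cell frequency of the competitive outcome).
#' @examples
#' p <- model_params(N = 40, m = 1, x = 0.5)
#' cfg <- sim_config(mutation_increment = 0.01, max_steps = 4000, seed = 1)
#' sw <- passive_help_sweep(c(0, 0.1), 2, replicates = 2, params = p,
#'                          config = cfg)
#' sw$freq
#' @export
passive_help_sweep <- function(k_grid, z_grid, replicates = 5, params,
                               config = sim_config(seed = 1)) {
  stopifnot(is.numeric(k_grid), length(k_grid) >= 1, all(k_grid >= 0),
            is.numeric(z_grid), length(z_grid) >= 1, all(z_grid >= 0),
            replicates >= 1, inherits(params, "model_params"),
            inherits(config, "sim_config"))
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  rows <- list()
  for (z in z_grid) for (k in k_grid) for (rep_i in seq_len(replicates)) {
    pars <- model_params(N = params$N, m = params$m, x = params$x,
                         k = k, z = z)
    cfg <- config
    cfg$seed <- base_seed + rep_i
    res <- suppressWarnings(run_heterogeneous(pars, cfg))
    s <- res$summary
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, z = z, replicate = rep_i, seed = cfg$seed,
                 outcome = res$outcome, helper_count = s$n_competitive,
                 cluster_level = s$cluster_level,
                 helper_payoff = s$mean_helper_payoff)
  }
  runs <- do.call(rbind, rows)
  freq <- aggregate(competitive_freq ~ k + z,
                    data = transform(runs,
                                     competitive_freq = outcome == "competitive"),
                    FUN = mean)
  structure(list(runs = runs, freq = freq, replicates = replicates,
                 params = params, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Passive-help sweep (%d replicates per cell)\n", x$replicates))
  print(x$freq, row.names = FALSE)
  invisible(x)
}
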