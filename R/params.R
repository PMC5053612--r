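#' Model parameters for the competitive-helping market
#'
#' Bundles the fixed parameters of the market: the population size `N`, the
#' maximum fitness benefit `m`, the diminishing-returns rate `x`, the passive
#' (costless) help `k` dispensed by every individual, and the degree of
#' matching `z`.
#'
#' @param N Number of individuals in the market (>= 2).  `Inf` is accepted as
#'   the infinite-population idealization for the closed-form analysis
#'   functions; the simulators require a finite integer.
#' @param m Maximum fitness benefit from receiving help (> 0).
#' @param x Rate of diminishing marginal returns, in (0, 1].
#' @param k Passive help provided at no cost by every individual (>= 0).
#' @param z Degree of matching (>= 0): 0 means help is split equally, 1 means
#'   perfect proportional matching, large values approach winner-per-source
#'   allocation.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(N = 100, m = 1, x = 0.5, k = 0, z = 1)
#' @export
model_params <- function(N, m = 1, x = 0.5, k = 0, z = 1) {
  stopifnot(is.numeric(N), length(N) == 1L, is.numeric(m), length(m) == 1L,
            is.numeric(x), length(x) == 1L, is.numeric(k), length(k) == 1L,
            is.numeric(z), length(z) == 1L)
  if (!(is.infinite(N) || (is.finite(N) && N == round(N))))
    stop("'N' must be a whole number (or Inf)")
  if (N < 2) stop("'N' must be at least 2")
  if (!(m > 0)) stop("'m' must be positive")
  if (!(x > 0 && x <= 1)) stop("'x' must lie in (0, 1]")
  if (k < 0) stop("'k' must be nonnegative")
  if (z < 0) stop("'z' must be nonnegative")
  structure(list(N = N, m = m, x = x, k = k, z = z), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Competitive-helping market parameters\n")
  cat(sprintf("  N = %s individuals\n", format(x$N)))
  cat(sprintf("  m = %g (max benefit)   x = %g (diminishing returns)\n",
              x$m, x$x))
  cat(sprintf("  k = %g (passive help)  z = %g (degree of matching)\n",
              x$k, x$z))
  invisible(x)
}

#' Two-type population state
#'
#' Proportions and active help levels for a market split into two homogeneous
#' types, conventionally labelled p and m.  Proportions must sum to one.
#'
#' @param S_m Proportion of type-m individuals, in \[0, 1\].
#' @param h_p,h_m Active help provided by every type-p / type-m individual
#'   (>= 0).
#' @param S_p Proportion of type-p individuals; defaults to `1 - S_m`.
#'
#' @return An object of class `two_type_state`.
#' @examples
#' two_type_state(S_m = 0.5, h_p = 0.4, h_m = 0.2)
#' @export
two_type_state <- function(S_m, h_p, h_m, S_p = 1 - S_m) {
  stopifnot(is.numeric(S_m), length(S_m) == 1L, is.numeric(S_p),
            length(S_p) == 1L, is.numeric(h_p), length(h_p) == 1L,
            is.numeric(h_m), length(h_m) == 1L)
  if (S_m < 0 || S_m > 1 || S_p < 0 || S_p > 1)
    stop("proportions must lie in [0, 1]")
  if (abs(S_p + S_m - 1) > 1e-12)
    stop("'S_p' and 'S_m' must sum to 1 (within 1e-12)")
  if (h_p < 0 || h_m < 0) stop("help levels must be nonnegative")
  structure(list(S_p = S_p, S_m = S_m, h_p = h_p, h_m = h_m),
            class = "two_type_state")
}

#' @export
print.two_type_state <- function(x, ...) {
  cat(sprintf("Two-type state: S_p = %g, S_m = %g, h_p = %g, h_m = %g\n",
              x$S_p, x$S_m, x$h_p, x$h_m))
  invisible(x)
}

#' Heterogeneous agent population
#'
#' Per-individual active help levels for the N-person game, together with the
#' passive help `k` shared by all individuals.
#'
#' @param h Numeric vector of nonnegative active help levels, one per agent
#'   (length >= 2).
#' @param k Passive help common to all agents (>= 0).
#'
#' @return An object of class `agent_population`.
#' @examples
#' agent_population(c(0.4, 0.2, 0))
#' @export
agent_population <- function(h, k = 0) {
  stopifnot(is.numeric(h), is.numeric(k), length(k) == 1L)
  if (length(h) < 2L) stop("an agent population needs at least 2 individuals")
  if (any(!is.finite(h)) || any(h < 0))
    stop("help levels must be finite and nonnegative")
  if (k < 0) stop("'k' must be nonnegative")
  structure(list(h = as.numeric(h), k = k), class = "agent_population")
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("Agent population: N = %d, k = %g\n", length(x$h), x$k))
  cat(sprintf("  help: min %g, median %g, max %g\n",
              min(x$h), stats::median(x$h), max(x$h)))
  invisible(x)
}

#' Simulation configuration
#'
#' Controls for the incremental-mutation simulators.  The defaults mirror the
#' study conditions used throughout: candidate help changes of 0.001 per step,
#' one candidate direction sampled per step, and convergence declared after a
#' window of steps without any accepted change.
#'
#' @param mutation_increment Size of a candidate help change per step (> 0).
#' @param max_steps Maximum number of simulation steps.
#' @param convergence_window Number of consecutive quiescent steps (no accepted
#'   help change, and no type switching where applicable) after which the run
#'   is declared converged.
#' @param tolerance Help-level tolerance used when labelling equilibria
#'   (quitting vs competitive).  Defaults to `4 * mutation_increment`.
#' @param switch_fraction_scale In evolving-proportions runs, the expected
#'   fraction of the lower-payoff type that switches per step is
#'   `switch_fraction_scale * |W_m - W_p|`, capped at `switch_cap`.
#' @param switch_cap Per-step cap on the switching probability.
#' @param both_directions If `TRUE`, both candidate directions (+increment and
#'   -increment) are evaluated each step and the better improving one is
#'   taken; the default samples a single direction per step.
#' @param record_every Trajectory recording stride (steps).
#' @param seed Integer seed applied at the start of a run (`NULL` leaves the
#'   RNG state untouched).
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(mutation_increment = 0.001, seed = 1)
#' @export
sim_config <- function(mutation_increment = 0.001, max_steps = 50000L,
                       convergence_window = 500L, tolerance = NULL,
                       switch_fraction_scale = 1, switch_cap = 0.1,
                       both_directions = FALSE, record_every = 10L,
                       seed = NULL) {
  stopifnot(is.numeric(mutation_increment), mutation_increment > 0,
            is.numeric(max_steps), max_steps >= 1,
            is.numeric(convergence_window), convergence_window >= 1,
            is.numeric(switch_fraction_scale), switch_fraction_scale >= 0,
            is.numeric(switch_cap), switch_cap > 0, switch_cap <= 1,
            is.logical(both_directions), is.numeric(record_every),
            record_every >= 1)
  if (is.null(tolerance)) tolerance <- 4 * mutation_increment
  stopifnot(is.numeric(tolerance), tolerance > 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(mutation_increment = mutation_increment,
                 max_steps = as.integer(max_steps),
                 convergence_window = as.integer(convergence_window),
                 tolerance = tolerance,
                 switch_fraction_scale = switch_fraction_scale,
                 switch_cap = switch_cap,
                 both_directions = both_directions,
                 record_every = as.integer(record_every),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  increment %g, max %d steps, window %d, tolerance %g\n",
              x$mutation_increment, x$max_steps, x$convergence_window,
              x$tolerance))
  cat(sprintf("  switching: scale %g, cap %g; directions: %s; seed: %s\n",
              x$switch_fraction_scale, x$switch_cap,
              if (x$both_directions) "both" else "sampled",
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# internal: require a finite-N params object for simulation work
.require_finite_N <- function(params) {
  if (!is.finite(params$N))
    stop("this operation requires a finite population size N")
  invisible(params)
}
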