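# Reproducible experiment layer: validated scenarios, seeded dispatch to the
# analysis/simulation engines, CSV outputs and JSON run manifests.

.scenario_kinds <- c("replicator", "abm-types", "abm-agents", "basin", "sweep")

.default_params <- function(kind) {
  # study defaults: m = 1, x = 0.5, k = 0; aggregate two-type population of
  # 100000 individuals, heterogeneous population of 200
  N <- if (kind == "abm-agents" || kind == "sweep") 200 else 100000
  list(N = N, m = 1, x = 0.5, k = 0, z = 1)
}

.default_config <- list(mutation_increment = 0.001, max_steps = 50000,
                        convergence_window = 500, tolerance = NULL,
                        switch_fraction_scale = 1, switch_cap = 0.1,
                        both_directions = FALSE, record_every = 10,
                        seed = NULL)

.default_init <- list(S_m = 0.5, h_p = NULL, h_m = NULL,
                      horizon = 1000, evolve = FALSE,
                      grid_from = 0, grid_to = 1, grid_n = 11,
                      k_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.4),
                      z_grid = c(2, 3),
                      replicates = 5)

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown scenario key%s at '%s': %s",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", ")))
  invisible(x)
}

#' Assemble a validated experiment scenario
#'
#' A scenario names an experiment kind, the market parameters, the simulator
#' configuration, and experiment-specific settings, with unspecified values
#' filled in from the `"paper-defaults"` preset (`m = 1`, `x = 0.5`, `k = 0`,
#' mutation increment 0.001, aggregate two-type `N = 100000`, heterogeneous
#' `N = 200`).
#'
#' @param name Scenario identifier.
#' @param kind One of `"replicator"`, `"abm-types"`, `"abm-agents"`,
#'   `"basin"`, `"sweep"`.
#' @param params Named list overriding entries of the default
#'   [model_params()].
#' @param config Named list overriding entries of the default [sim_config()].
#' @param init Named list of experiment settings: `S_m`, `h_p`, `h_m`
#'   (initial state), `horizon` (replicator), `evolve` (abm-types),
#'   `grid_from`/`grid_to`/`grid_n` (basin), `k_grid`/`z_grid`/`replicates`
#'   (sweep).
#' @param seed Integer run seed.
#'
#' @return An object of class `scenario`.
#' @examples
#' scenario("demo", "abm-types", params = list(N = 1000, z = 2), seed = 1)
#' @export
scenario <- function(name, kind, params = list(), config = list(),
                     init = list(), seed = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  kind <- match.arg(kind, .scenario_kinds)
  .check_keys(params, c("N", "m", "x", "k", "z"), "params")
  .check_keys(config, names(.default_config), "config")
  .check_keys(init, names(.default_init), "init")
  p <- modifyList(.default_params(kind), params)
  cfg <- modifyList(.default_config, config,
                    keep.null = TRUE)
  ini <- modifyList(.default_init, init, keep.null = TRUE)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  params_obj <- model_params(N = p$N, m = p$m, x = p$x, k = p$k, z = p$z)
  config_obj <- do.call(sim_config, cfg)
  structure(list(name = name, kind = kind, params = params_obj,
                 config = config_obj, init = ini),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$name, x$kind))
  print(x$params)
  print(x$config)
  invisible(x)
}

#' Load a scenario from a YAML document
#'
#' Reads and validates a scenario description.  Unknown keys are rejected
#' with the offending key path; missing values fall back to the
#' `"paper-defaults"` preset (see [scenario()]).
#'
#' @param source Path to a YAML file, or a YAML string.
#'
#' @return A validated `scenario` object.
#' @examples
#' s <- load_scenario("name: demo\nkind: abm-types\nparams:\n  z: 2\nseed: 1")
#' s$params$z
#' @export
load_scenario <- function(source) {
  doc <- if (file.exists(source)) yaml::read_yaml(source)
         else yaml::yaml.load(source)
  if (is.null(doc)) doc <- list()
  .check_keys(doc, c("name", "kind", "preset", "params", "config", "init",
                     "seed"), "<top level>")
  if (!is.null(doc$preset) && !identical(doc$preset, "paper-defaults"))
    stop("unknown preset: ", doc$preset)
  if (is.null(doc$kind)) stop("scenario must declare a 'kind'")
  scenario(name = if (is.null(doc$name)) "unnamed" else doc$name,
           kind = doc$kind,
           params = if (is.null(doc$params)) list() else doc$params,
           config = if (is.null(doc$config)) list() else doc$config,
           init = if (is.null(doc$init)) list() else doc$init,
           seed = doc$seed)
}

#' Serialize a scenario to YAML
#'
#' @param s A `scenario` object.
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @examples
#' cat(save_scenario(scenario("demo", "replicator", seed = 1)))
#' @export
save_scenario <- function(s, path = NULL) {
  stopifnot(inherits(s, "scenario"))
  doc <- list(name = s$name, kind = s$kind,
              params = unclass(s$params),
              config = Filter(Negate(is.null), unclass(s$config)),
              init = Filter(Negate(is.null), s$init))
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# deterministic CSV writer (fixed column order, header row always present)
.write_result_csv <- function(df, path, columns) {
  stopifnot(all(columns %in% names(df)))
  write.csv(df[columns], path, row.names = FALSE, quote = FALSE)
  path
}

#' Read back a trajectory CSV written by [run_scenario()]
#'
#' @param path CSV path.
#' @return A `data.frame`; files whose header does not match the documented
#'   column order are rejected.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  expected <- c("step", "S_p", "S_m", "h_p", "h_m", "W_p", "W_m")
  if (!identical(names(df), expected))
    stop("unexpected trajectory header: ", paste(names(df), collapse = ", "))
  df
}

#' Run a scenario and write its results
#'
#' Dispatches a validated scenario to the matching engine, writes the result
#' tables as CSV and a JSON manifest (seed, parameter echo, package version,
#' wall time, convergence diagnostics).  Identical scenario + seed yields
#' byte-identical result CSVs.  On failure, partial outputs are removed.
#'
#' @param s A `scenario` object.
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the result object, the manifest, and the
#'   written file paths.
#' @examples
#' s <- scenario("demo", "abm-types", params = list(N = 100, z = 1),
#'               config = list(mutation_increment = 0.01, max_steps = 3000),
#'               seed = 1)
#' out <- run_scenario(s, tempfile("run"))
#' out$files
#' @export
run_scenario <- function(s, out_dir) {
  stopifnot(inherits(s, "scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  t0 <- proc.time()[["elapsed"]]
  on_fail <- function(e) {
    unlink(files)
    stop(sprintf("scenario '%s' (%s) failed: %s", s$name, s$kind,
                 conditionMessage(e)), call. = FALSE)
  }
  res <- tryCatch({
    ini <- s$init
    diag <- list()
    if (s$kind == "replicator") {
      h_p <- if (is.null(ini$h_p)) optimal_help_monomorphic(s$params)
             else ini$h_p
      h_m <- if (is.null(ini$h_m)) 0 else ini$h_m
      st <- two_type_state(S_m = ini$S_m, h_p = h_p, h_m = h_m)
      tr <- integrate_replicator(st, s$params, horizon = ini$horizon)
      df <- data.frame(step = tr$time, S_p = tr$S_p, S_m = tr$S_m,
                       h_p = tr$h_p, h_m = tr$h_m, W_p = tr$W_p,
                       W_m = tr$W_m)
      f <- file.path(out_dir, "trajectory.csv")
      files <- c(files, .write_result_csv(df, f, names(df)))
      diag <- list(converged = attr(tr, "converged"),
                   drift = attr(tr, "drift"))
      list(obj = tr, diag = diag)
    } else if (s$kind == "abm-types") {
      init <- if (is.null(ini$h_p)) NULL else c(ini$h_p, ini$h_m)
      r <- if (isTRUE(ini$evolve))
        run_evolving_proportions(s$params, s$config, S_m0 = ini$S_m,
                                 init = init)
      else run_fixed_proportions(ini$S_m, s$params, s$config, init = init)
      f <- file.path(out_dir, "trajectory.csv")
      files <- c(files, .write_result_csv(r$trajectory, f,
                  c("step", "S_p", "S_m", "h_p", "h_m", "W_p", "W_m")))
      diag <- list(converged = r$converged, steps = r$steps,
                   accepted_moves = r$accepted_moves, label = r$label)
      list(obj = r, diag = diag)
    } else if (s$kind == "basin") {
      grid <- seq(ini$grid_from, ini$grid_to, length.out = ini$grid_n)
      bm <- basin_map(list(h_p = grid, h_m = grid), ini$S_m, s$params,
                      s$config)
      f <- file.path(out_dir, "basin.csv")
      files <- c(files, .write_result_csv(bm, f,
                                           c("h_p0", "h_m0", "label")))
      diag <- list(labels = as.list(table(bm$label)))
      list(obj = bm, diag = diag)
    } else if (s$kind == "abm-agents") {
      r <- run_heterogeneous(s$params, s$config,
                             h0 = if (is.null(ini$h_p)) NULL
                                  else rep(ini$h_p, s$params$N))
      df <- data.frame(agent_id = seq_along(r$h), h = r$h, r = r$r, W = r$W)
      f <- file.path(out_dir, "agents.csv")
      files <- c(files, .write_result_csv(df, f, names(df)))
      diag <- list(converged = r$converged, steps = r$steps,
                   outcome = r$outcome, summary = r$summary)
      list(obj = r, diag = diag)
    } else if (s$kind == "sweep") {
      sw <- passive_help_sweep(ini$k_grid, ini$z_grid, ini$replicates,
                               s$params, s$config)
      f1 <- file.path(out_dir, "sweep.csv")
      files <- c(files, .write_result_csv(sw$runs, f1,
                  c("k", "z", "replicate", "seed", "outcome",
                    "helper_count", "helper_payoff")))
      f2 <- file.path(out_dir, "sweep_freq.csv")
      files <- c(files, .write_result_csv(sw$freq, f2,
                                           c("k", "z", "competitive_freq")))
      diag <- list(cells = nrow(sw$freq))
      list(obj = sw, diag = diag)
    }
  }, error = on_fail)
  manifest <- list(name = s$name, kind = s$kind,
                   seed = s$config$seed,
                   params = unclass(s$params),
                   config = Filter(Negate(is.null), unclass(s$config)),
                   init = Filter(Negate(is.null), s$init),
                   package_version = as.character(packageVersion("helpmarket")),
                   wall_time_s = proc.time()[["elapsed"]] - t0,
                   diagnostics = res$diag,
                   files = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(result = res$obj, manifest = manifest,
                 files = c(files, mf)))
}
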