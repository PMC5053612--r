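# helpmarket

Competitive helping in biological markets: closed-form analysis, replicator
dynamics, and agent-based simulation.

## The problem

In a biological market, individuals exchange a commodity — here, *help* — and
compete over the shares of it that others dispense.  Each of the `N`
individuals dispenses its active help `h` plus a common costless passive
amount `k`.  Every dispensed unit is split among the other `N − 1`
individuals in proportion to their matching weights `(h_i + k)^z`:

    r_i = Σ_{j≠i} (h_j + k) · (h_i + k)^z / Σ_{l≠j} (h_l + k)^z

The degree of matching `z` interpolates between an equal split (`z = 0`),
perfect proportional matching (`z = 1`), and near winner-per-source
allocation (large `z`).  Fitness combines a saturating benefit of help
received with the linear cost of help provided:

    W = m·r / (m·x + r) − h

where `m` is the maximum benefit and `x` sets the rate of diminishing
returns.  *Competitive helping* arises when individuals try to out-help each
other to attract a larger share of the market's help.

The package is aimed at evolutionary game theorists and behavioural
ecologists who want to study when competitive helping pays, when one
strategy quits, and how costless by-product (passive) help reshapes the
market.  Its core results:

- **Monomorphic optimum.**  With a single strategy in the market,
  `h* = (−x + √x)·m − k`, independent of `z` and `N`.
- **Symmetric optimum.**  With two equally common types at a common help
  level, `h* = m·(−x + √(x·(N−2)((z+1)N−1) / (2(N−1)²))) − k`, whose
  large-`N` limit `m·(−x + √(x(z+1)/2)) − k` no longer grows with the
  population size.  It stays below `m(1 − x)` — the level at which payoffs
  hit zero — exactly while `z < 2/x − 1`.
- **Stability.**  The replicator dynamics of the two type proportions have
  monomorphic corners whose Jacobian carries the repeated eigenvalue
  `h*(h* + mx − m)/(h* + mx)` (multiplicity 2, extinct type at zero help),
  negative for all admissible `m, x`; the symmetric interior state is
  neutral along the equal-help line and stable transversally only while
  `z < 2/x − 1`.
- **Invasion.**  In a market of non-helpers with `k = 0`, a lone helper earns
  `−H`: providing no help is an ESS, and helping needs at least **two**
  simultaneous helpers to pay.
- **Runaway competition.**  Incremental-mutation agent dynamics reproduce
  the equilibrium structure: a single competitive equilibrium at `z ≤ 1`,
  coexisting competitive and quitting outcomes at `z > 1` (with escalating
  help and eventually negative payoffs), and full competition forced by
  modest passive help.

## Worked example

```r
library(helpmarket)
p <- model_params(N = 1000, m = 1, x = 0.5, k = 0, z = 2)
optimal_help_symmetric(p)    # 0.3658806
optimal_help_monomorphic(p)  # 0.2071068

res <- run_fixed_proportions(S_m = 0.5, p,
                             sim_config(mutation_increment = 0.005, seed = 1))
res
#> Two-type simulation (fixed proportions)
#>   equilibrium: h_p = 0.365509, h_m = 0.367124, S_p = 0.5, S_m = 0.5
#>   payoffs: W_p = 0.05626, W_m = 0.05679
#>   label: competitive; converged: TRUE after 543 steps (26 accepted moves)
```

Both types climb to the symmetric optimum 0.366 (within two mutation
increments) and earn the same positive payoff — at `z = 2` competition still
pays; beyond `z = 2/x − 1 = 3` the same equilibrium yields negative payoffs.

```r
hs <- optimal_help_monomorphic(p)
jacobian_stability(two_type_state(S_m = 0, h_p = hs, h_m = 0), p)
#> Replicator equilibrium report
#>   location: S_p = 1, S_m = 0, h_p = 0.207107, h_m = 0
#>   eigenvalues (2-D): -0.0857864, -0.0857864
#>   constrained derivative: -0.0857864
#>   transverse help eigenvalue: -0.0857864
#>   classification: stable

invasion_analysis(H = 0.1, model_params(N = 100, z = 1))
#> Invasion analysis (k = 0)
#>   E(0,[0]) = 0; E(H,[0]) = -0.1 at H = 0.1
#>   minimum simultaneous helpers for positive payoff: 2
#>   no-help strategy is an ESS: TRUE
```

The corner eigenvalue −0.0858 equals `h*(h* + mx − m)/(h* + mx)` with
multiplicity 2: a market fixed on the optimal-help strategy is
asymptotically stable, yet that same strategy cannot invade a market of
non-helpers without a partner.

Other entry points: `run_evolving_proportions()` (payoff-driven type
switching), `basin_map()` (basins of attraction over initial help),
`run_heterogeneous()` (every individual sets its own help),
`passive_help_sweep()` (frequency of the fully competitive outcome over a
`(k, z)` grid), and `run_scenario()`/`load_scenario()` for seeded,
manifest-backed experiment runs.  A thin command-line front end lives at
`exec/helpmarket`.

## Package layout

- `R/model_core.R` — matching-law allocation and payoff primitives
- `R/replicator.R` — replicator dynamics, closed-form optima, stability
- `R/abm_types.R` — two-type incremental-mutation simulator
- `R/abm_agents.R` + `src/agents.cpp` — heterogeneous N-person simulator
- `R/experiments.R` — scenarios, seeded runs, CSV/JSON export
- `vignettes/competitive-helping.Rmd` — model assumptions, design and
  numerical choices
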