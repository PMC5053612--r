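---
title: "Competitive helping in biological markets: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive helping in biological markets: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helpmarket)
```

## The model

A market of `N` individuals exchanges help.  Individual `i` chooses an
active help level `h_i >= 0` and, in addition, automatically dispenses a
costless passive amount `k` common to everyone.  Help is allocated by a
matching-law rule: each dispensed unit from source `j` is split among the
other `N - 1` individuals in proportion to their matching weights
`(h_i + k)^z`,

$$ r_i \;=\; \sum_{j \ne i} (h_j + k)\,
   \frac{(h_i + k)^z}{\sum_{l \ne j} (h_l + k)^z}. $$

The degree of matching `z` spans equal division (`z = 0`, weights all one),
perfect proportionality (`z = 1`) and, as `z` grows, an allocation in which
each source gives essentially everything to its top-ranked recipient.  Note
that even in the `z -> Inf` limit the single most generous individual does
*not* literally take all: it cannot receive its own contribution, which goes
to the runner-up.

Fitness is a saturating benefit of help received minus a linear cost of help
provided,

$$ W_i = \frac{m\,r_i}{m x + r_i} - h_i, $$

with maximum benefit `m > 0` and diminishing-returns rate `x` in `(0, 1]`.
Two population structures are analyzed: a *two-type* market in which every
individual of a type provides the same help (proportions `S_p + S_m = 1`),
and a fully *heterogeneous* market in which each of the `N` agents controls
its own help level.

### Parameters

| symbol | meaning | default |
|---|---|---|
| `N` | market size | 100000 (two-type), 200 (heterogeneous) |
| `m` | maximum fitness benefit | 1 |
| `x` | diminishing-returns rate | 0.5 |
| `k` | passive (costless) help | 0 |
| `z` | degree of matching | varied, 1 = proportional |
| increment | candidate help change per step | 0.001 |

The defaults are the study conditions used throughout the test-suite and the
acceptance script: `m` only rescales help levels, `x = 0.5` puts the
zero-payoff threshold at `z = 2/x - 1 = 3`, and the mutation increment 0.001
makes simulated trajectories effectively gradual.

## Closed-form optima

When one type occupies the whole market, every dispensed unit returns to the
type itself, so `r = h + k` identically and maximizing `W` gives

$$ h^* = (-x + \sqrt{x})\,m - k, $$

independent of both `z` and `N` (`optimal_help_monomorphic()`).  When two
equally common types share the market at a common help level, differentiating
a type's payoff with respect to its own help (the whole type moving together)
and solving the stationarity condition gives

$$ h^* = m\left(-x + \sqrt{x\,\tfrac{(N-2)\,((z+1)N-1)}{2\,(N-1)^2}}\right) - k, $$

(`optimal_help_symmetric()`), clamped at zero.  Its large-`N` limit,
`m(-x + sqrt(x (z+1)/2)) - k`, stops depending on the population size, and
it equals the monomorphic form at `z = 1` in that limit — two anchors that
pin the radicand; both forms are verified in the tests against numeric
best-response maximization through the allocation engine, not against
themselves.  Because the payoff at a common help level `h` is
`W = m(h+k)/(mx+h+k) - h`, payoffs at the symmetric optimum turn negative
exactly when `h*` exceeds `m(1 - x)`, i.e. when `z > 2/x - 1`.

A second family of equal-payoff states exists on the boundary: if one type
provides no active help (`k = 0`), the other type's equal-payoff level is
`m - m x`, where benefits exactly cover costs and *both* types earn zero.
Direct computation through the allocation engine shows this holds for every
`z > 0`: a non-helping type has zero matching weight, receives nothing, and
pays nothing, while the helping type's dispensed help recirculates within
itself so `r = h`.  At `z = 0` the non-helpers receive equal shares and the
boundary value no longer applies — the package evaluates the condition at
the `z` it is given rather than assuming one regime
(`boundary_solutions()`).

## Replicator dynamics and stability

With help levels fixed, the type proportions evolve by

$$ \dot S_i = S_i\,(W_i - (S_p W_p + S_m W_m)), $$

which on the simplex factorizes as
`dS_m/dt = S_m (1 - S_m)(W_m - W_p)`.  Equilibria are the two monomorphic
corners and any state with equal payoffs.  Because equal help levels give
equal payoffs *for every split*, the set `{h_p = h_m}` is a neutral set of
the proportion flow; the package treats it as such rather than as a line in
the `(S_p, S_m)` plane (which would conflict with `S_p + S_m = 1`).

`jacobian_stability()` reports three things:

1. the 2x2 Jacobian with `(S_p, S_m)` treated as free coordinates, computed
   symbolically (via `deriv()`) with a finite-difference cross-check in the
   tests;
2. the constrained one-dimensional derivative along the simplex;
3. a transverse "help eigenvalue" `-W(resident)`: the growth rate of a rare
   quit-invader (zero help) against the resident strategy.

At a monomorphic corner with the extinct type carrying no help and `k = 0`,
the 2x2 Jacobian is diagonal with the repeated eigenvalue
`h*(h* + mx - m)/(h* + mx)` (multiplicity 2), negative for all `m, x` since
`h* = (-x + sqrt(x))m < m(1 - x)` always.  The multiplicity is sensitive to
what help the extinct type is assigned: if the absent type is instead carried
at the resident's `h*`, its hypothetical payoff ties with the resident's and
one eigenvalue collapses to zero.  The package takes the extinct-type help
from the supplied state, so both conventions are computable; the zero-help
convention is the natural one — in simulations with evolving proportions,
extinction of a type coincides with that type's help reaching zero — and is
what the acceptance script uses.

The symmetric interior state is neutral in the proportion direction
(zero eigenvalue), so its classification is decided transversally: the
quit-invader grows at rate `-W(h*)`, negative exactly while `z < 2/x - 1`.
The same flip is visible under plain numerical integration: a rare
non-helping type dies out against residents at the symmetric optimum for
`z = 2.5` and takes over for `z = 3.5`.

Integration uses `deSolve::ode()` (lsoda, `rtol = 1e-10`, `atol = 1e-12`)
with terminal renormalization onto the simplex; the recorded drift is
required to stay below `1e-9`.  A state counts as an equilibrium when the
right-hand side's max-norm is at most `1e-8` (the model gives no tolerance,
so one had to be fixed; the flow near the equilibria of interest is well
above this scale).

## Invasion analysis

With `k = 0`, a market of non-helpers dispenses nothing, so a lone helper
providing `H` earns exactly `-H` while everyone else earns 0: providing no
help is an ESS.  Two simultaneous helpers, however, exchange their full help
(non-helpers have zero matching weight), each earning `mH/(mx + H) - H > 0`
for moderate `H` — the minimum invading coalition has size two
(`invasion_analysis()`).  Because the simulators give agents only *lagged*
information about others' help, this coalition cannot assemble spontaneously,
which is why the all-zero market is an absorbing state of the heterogeneous
simulator.

## The agent-based simulators

**Update rule (both engines).**  At each step every decision-maker draws a
candidate help level one increment away (direction sampled uniformly;
evaluating both directions is available as a configuration flag), computes
the *expected* payoff of adopting it against the other parties' help from the
previous step, and adopts the candidate only on strict improvement.  Updates
are synchronous and help is clamped at zero.  The stated "mutation rate" of
0.001 is interpreted as the increment size of these candidate changes: an
incremental step is the only reading that produces the gradual trajectories
the model's equilibrium maps are built from, and it is exposed as
`sim_config(mutation_increment = )` so the alternative interpretation is one
knob away.

**Two-type engine** (`run_fixed_proportions()`, `basin_map()`,
`proportion_sweep()`).  Types are homogeneous, so a candidate is evaluated
as if all members of the type adopt it simultaneously; the expected payoff
is then a closed-form evaluation of the two-type allocation, which makes the
engine's cost independent of `N` (the aggregate default of 100000
individuals costs no more than 100).  Convergence is declared after 500
consecutive steps with no accepted change (unspecified in the model; long
enough that the chance of a profitable move being missed by direction
sampling for the whole window is negligible, `2^-500`).

**Evolving proportions** (`run_evolving_proportions()`).  After each help
step, each member of the lower-payoff type switches with probability
`switch_fraction_scale * |W_m - W_p|`, capped at 10% of the type per step
(the switching propensity is stated only as "proportional to the payoff
difference"; the cap keeps trajectories comparable across parameter
settings).  The number of switchers is binomial, so proportions move in
whole individuals and `S_i N` stays integral.  A type that loses all members
has its help frozen at zero and cannot re-enter — which is also why the
quitting-type equilibria coincide with extinctions.  Which type survives a
high-`z` race depends on transient payoffs, not only on the initial help
gap: an over-helping type can bleed members early and go extinct even though
its help level was the larger one.

**Heterogeneous engine** (`run_heterogeneous()`, `step_agents()`).  Every
agent evaluates its own candidate against all other agents' lagged help; the
inner O(N^2) payoff evaluation is compiled (Rcpp), with a pure-R oracle in
the test-suite verifying the kernel step for step.  Initial help defaults to
independent uniform draws on `[0, m]`, which exposes all basins.  The
long-run state is typically bimodal: a cluster of competitive helpers at a
common high level with the rest at zero.

**Outcome labels.**  Two-type runs are labelled `competitive` (both types
helping at a common level, within the labelling tolerance of 4 increments),
`p-quits`/`m-quits` (one type at zero), `collapse` (nobody helps; this
occurs, e.g., at `z = 0` with even proportions) or `indeterminate`.
Heterogeneous runs are labelled `competitive` only when *every* agent joins
a common stationary positive cluster, `collapse` when nobody provides active
help, and `mixed` otherwise.  The all-agents reading is deliberate: the
fully competitive equilibrium is the heterogeneous counterpart of the
two-type equal-help state, and it is the outcome whose frequency responds to
passive help — a cluster-of-some criterion (e.g. "at least two helpers")
would be satisfied by virtually every run at `z > 1` and could not register
the passive-help transition at all.

**Passive help** (`passive_help_sweep()`).  With `k = 0` and `z > 1`, runs
from uniform initial help stratify: agents below the emerging cluster ratchet
down to zero and, once there, cannot profitably re-enter.  Passive help
changes this: every individual retains matching weight `k^z > 0`, so staying
at zero stops being safe, and above a `z`-dependent threshold every run ends
with the whole population competing.  Observed thresholds at the defaults are
roughly `k ~ 0.2` at `z = 2`, `~ 0.4` at `z = 3` and `~ 0.65` at `z = 5` —
nondecreasing in `z`, because a zero-helper's re-entry gradient scales like
`z k^(z-1)`, which shrinks with `z` for small `k`.  The default sweep grid
(`k` from 0 to 0.4, `z` in {2, 3}) brackets the first two thresholds while
staying below the saturation regime `k > m(sqrt(x(z+1)/2) - x)` in which
passive help alone maxes out the benefit and active help is clamped to zero
(at `z = 2`, `x = 0.5` that happens near `k = 0.5`, and the fully
competitive outcome gives way to universal free-riding).  Replicate `i` of
every cell runs with seed `base + i`, recorded in the output, so cells share
common random numbers.

## Numerical choices

- **Degenerate allocation pools.**  When a source's recipients all have zero
  matching weight (possible with `k = 0`, `z > 0`), the source's help is
  split equally.  This preserves conservation (`sum(r) = sum(h + k)`
  exactly), and continuity with `z = 0`.
- **`0^0 = 1`.**  Matching weights at `z = 0` are identically one, so
  `z = 0` always means an equal split, including for individuals with
  `h + k = 0`.
- **Leave-one-out sums.**  The vectorized allocation computes each source's
  recipient pool as a direct leave-one-out sum rather than `sum(w) - w_j`:
  with a dominant weight (large `z`) the subtraction cancels catastrophically
  and dispensed shares stop summing to one at the `1e-9` conservation
  tolerance.
- **Individual counting.**  The two-type allocation counts individuals, so
  `S_i * N` must be whole (validated); proportion sweeps choose `N`
  divisible by the grid.  The replicator layer, which differentiates through
  the allocation, treats proportions as continuous instead.
- **Types with no members** report `r = 0` and `W = 0` — those quantities
  describe nobody.

## Problem sizes

The test-suite runs the two-type engine at aggregate sizes 100–1000 with
increments 0.005–0.01 and the heterogeneous engine at `N = 200–400` with
the default increment — sizes at which every qualitative conclusion above is
already size-stable (doubling `N` moves the competitive-cluster level by
less than two increments, which is itself one of the checks).  The
acceptance script uses an aggregate population of 1000 for the
evolving-proportions run and averages its terminal split over five seeds.

## What the simulations do and do not show

The simulators implement the model faithfully but remain a stylized market:
there is no spatial or network structure, no kin structure, no memory or
reputation, no demography (fixed `N`), a single common `k` for everyone, and
payoff-monotone incremental adjustment rather than explicit
birth–death selection.  Passing tests therefore certify the internal logic
of the matching-law market — not that real helping markets obey matching-law
allocation or saturating benefits.  Within the model, conclusions at very
large `z` also deserve caution: the winner-per-source limit is approached
but never attained, and the "winner takes all" intuition fails for the top
helper's own contribution.
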