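---
title: "The CHASE migration model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CHASE migration model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chase)
```

## The model and its assumptions

`chase` treats migration as a discrete-time Markov chain over `L` cities
on a plane. Individuals carry a permanent origin label (the city they
started in), the total population is constant — no births, deaths, or
aging — and everyone of the same origin in the same city is
exchangeable, so the full state is the `L × L` matrix `n[j, x]` of
origin-`x` people living in city `j`.

One step of the chain moves an origin-`k` individual from city `j` to
city `i` with probability

$$
w^{(k)}_{ij,t} =
\begin{cases}
1-\delta+\delta\left(\frac{e}{\beta_t}\right)^{\beta_t}
  \left(\frac{N_j}{K_j}\right)^{\beta_t} e^{-N_j/K_j} & i = j,\\[4pt]
C \,\frac{\left(\sum_{x\neq k} n_i^{(x)} + \gamma n_i^{(k)}\right)^{\beta_t}}
  {d_{ij}^{\alpha}}\, e^{-N_i/K_i} & i \neq j,
\end{cases}
$$

with $N_j=\sum_x n_j^{(x)}$ and $C$ chosen per source column so each
column sums to one (people are conserved by construction). The four
drivers:

* **Environment.** $e^{-N/K}$ is Ricker-type density dependence: `K` is
  the characteristic population a city can support, and crowding beyond
  it suppresses both the willingness to stay and the attraction to
  move in.
* **Agglomeration.** The destination population enters with exponent
  $\beta_t$; bigger places mean more opportunity, but only insofar as
  migrants care ($\beta_t$).
* **Social ties.** Same-origin residents at a destination are weighted
  by `γ` in the agglomeration numerator; `γ = 1` makes the numerator the
  plain total population (neutral), `γ > 1` models ethnic-enclave pull.
* **Changing mindset.** $\beta_t = 1 - e^{-t/\tau_\beta}$: early in a
  migration episode people move on distance and safety alone
  ($\beta \approx 0$, the kernel degenerates to
  $C\, d_{ij}^{-\alpha} e^{-N_i/K_i}$), later they fully weigh
  opportunities and ties ($\beta \to 1$).

The $(e/\beta)^{\beta}$ factor in the staying branch rescales
$(N/K)^{\beta} e^{-N/K}$ so its maximum over $N$ is exactly 1 (attained
at $N = \beta K$), which pins the staying probability inside
$[1-\delta,\,1]$ and keeps the numerics stable.

## Parameters

| parameter  | meaning                                   | units   | default |
|------------|-------------------------------------------|---------|---------|
| `delta`    | max emigrating fraction per step          | —       | 0.2     |
| `alpha`    | distance-deterrence exponent              | —       | 1       |
| `gamma`    | social-tie weight (1 = neutral)           | —       | 50      |
| `tau_beta` | mindset timescale (0 ⇒ β ≡ 1)             | steps   | 120     |
| `steps`    | simulation length `T`                     | steps   | 5000    |
| `n0`       | natives per city at `t = 0`               | persons | 3000    |
| `K`        | characteristic city size (on the map)     | persons | 5000    |
| `epsilon`  | extinction threshold at the final step    | persons | 1       |

The defaults are the baseline configuration of the package's
experiments: 10 cities × 3,000 natives = 30,000 people, run for 5,000
steps. `alpha` stays at 1 everywhere (the classical gravity exponent);
`gamma`, `tau_beta`, and `K` are the dials the experiments sweep.

## Conventions and numerical choices

Several limits need a convention, and each is chosen so the β = 0 kernel
is the exact continuous limit of the general one:

* `tau_beta = 0` is *defined* as $\beta_t \equiv 1$ for all `t`
  (the $e^{-t/0}$ form is otherwise undefined).
* $0^0 := 1$, so at β = 0 the population factor is identically 1 even
  for empty destinations, while for β > 0 an empty destination has
  exactly zero attraction.
* $(e/\beta)^\beta \to 1$ as β → 0, taken as its limit.
* **Degenerate columns.** If every off-diagonal raw weight out of city
  `j` is zero (e.g. all other cities are empty and β > 0), the would-be
  emigrants have no admissible destination; the staying probability is
  forced to 1 so probability mass is conserved. Column sums are
  verified to 1 within 1e−12 in the test suite.
* The kernel for the step from `t` to `t+1` uses $\beta_t$ (the first
  step uses $\beta_0$), the same $\beta_t$ in both branches.
* No flooring of small populations during a run: extinction is a
  *measurement* applied at the final step (`total > epsilon`), not a
  dynamic rule, which keeps the dynamics exactly Markovian. One whole
  person is the natural operational cutoff for "population greater
  than 0" under real-valued flows; stochastic runs can use
  `epsilon = 0`.
* Quartiles in `boxplot_stats()` use linear interpolation between order
  statistics (`quantile()` type 7) with 1.5 × IQR whiskers; the
  outlier flags depend on that rule, so it is fixed and documented.

### Update modes

The default update is **deterministic expected flow**: populations are
real-valued and each origin's distribution is propagated by its kernel,
`n'[, k] = w_k %*% n[, k]`. Single-map trajectories are then smooth and
bit-reproducible, and all ensemble variability comes from the random
maps — which is also why the ensemble experiments resample maps, not
paths. A **stochastic mode** (multinomial draws per city and origin,
integer agents, exactly conserved totals, seed-reproducible) is provided
for agent-level realism; its single-step mean matches the deterministic
flow, which the tests verify by Monte Carlo. The update is synchronous:
all kernels for step `t` are computed from the state at `t` before
anyone moves.

## Synthetic maps

Every experiment runs on maps from `generate_map()`: `L` points uniform
on the unit square, redrawn until all pairwise distances exceed `d_min`
(0.05 by default — `d^{-α}` diverges for coincident cities), with one
shared `K` for all cities. Because the off-diagonal normalization `C`
absorbs any global distance scale, the kernel is invariant under uniform
rescaling of coordinates (tested to 1e−12), so the unit square is a
normalization, not an assumption; only the *shape* of the point pattern
matters. What the generator does **not** emulate: clustered or
corridor-like city systems, heterogeneous or time-varying `K`,
real geographic distances, or demographic change. Passing tests
therefore show that the mechanisms behave as specified on homogeneous
random geographies — not that the model is calibrated to any real
migration system.

## Experiments

* `legacy_effect()` runs the *same* map under several `tau_beta` values
  and reports the final per-city populations and the pairwise maximum
  absolute per-city difference between final states. A difference above
  10 persons is treated as "different final state" — the legacy claim is
  qualitative, and a threshold makes it testable.
* `k_sweep()` averages the surviving-city count over fresh random maps
  for each `K`. The counterintuitive headline: raising every city's
  capacity `K` *lowers* the number of surviving cities, because cheap
  capacity releases the benefit of agglomeration.
* `gamma_diversity()` pools the inverse Simpson indices of surviving
  cities across runs and `K` values into (γ, surviving-count) cells,
  summarized as boxplot statistics. Grouping by surviving count matters:
  with a single survivor everyone is in one city and `S = L` exactly,
  regardless of γ. Realizations are counted per (γ, `K`) combination,
  and cells are pooled across the whole `K` list.

Per-run seeds are drawn up front from a master seed (`sample.int()`
under `set.seed(master)`), so ensemble statistics do not depend on
execution order and any individual run can be replayed from its recorded
seed. The specific γ list behind capacity sweeps is exposed as an
argument (defaults `{1, 10, 50}`: neutral, moderate, strong).

## Problem sizes

The package's default ensembles use 100 maps per parameter cell for
capacity sweeps and 25 realizations per (γ, `K`) cell for the diversity
analysis — large enough that the directional results (Spearman trends,
group medians) are stable across master seeds at full run length
(5,000 steps), while keeping a complete desk-scale replication in the
minutes range. Larger ensembles (e.g. 1,000 maps per cell) are a single
argument change (`n_maps`, `n_realizations`).

## Known limitations

* `K` is homogeneous across cities and constant in time; dynamic or
  heterogeneous capacity (droughts, conflict shocks, growing
  infrastructure) is deliberately out of scope.
* No births, deaths, or multi-generation dynamics; origin labels never
  dilute.
* Deterministic flows leave arbitrarily small sub-person populations in
  "extinct" cities; these are reported as-is and only thresholded at
  measurement time.
* The distance kernel is fixed to `d^{-α}`; exponential-decay or
  radiation-style kernels are not implemented.
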