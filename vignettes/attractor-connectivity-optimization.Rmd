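---
title: "Optimizing which synapses exist: methods behind synaptopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing which synapses exist: methods behind synaptopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(synaptopt)
```

## The model

`synaptopt` simulates an autoassociative (Hopfield-type) network of `N`
binary neurons with states $s_i \in \{-1, +1\}$. The network stores `p`
random patterns $\xi^\mu \in \{-1,+1\}^N$ through the integer Hebbian rule

$$W_{ij} = \sum_{\mu=1}^{p} \xi_i^\mu \xi_j^\mu,$$

and — the distinctive ingredient — a *binary connectivity matrix* $C$ with
$C_{ij} = 1$ when neuron $j$ feeds neuron $i$. Weights are never modified
after learning; all optimization acts on which connections exist. Every
neuron has in-degree $c$ (offline mode; the online algorithm lets in-degrees
vary), the diagonal is zero, and retrieval runs synchronous threshold
dynamics on the local field

$$h_i = \frac{1}{c} \sum_j W_{ij} C_{ij} s_j, \qquad
  s_i \leftarrow \mathrm{sgn}(h_i),$$

with the tie $\mathrm{sgn}(0) := +1$. A pattern counts as *retrieved* when,
started from it (optionally with a fraction of flipped neurons), the
dynamics end with overlap $m = \frac{1}{N}\sum_i s_i \xi_i$ strictly above
0.7. The dynamics stop when the overlap is unchanged between consecutive
synchronous steps (compared exactly, on the integer dot product) or after
100 steps.

The *storage capacity* $p_c$ is the largest `p` for which **all** stored
patterns are retrieved from error-free initialization, and
$\alpha_c = p_c / c$ normalizes it per connection. All retrieval arithmetic
is exact: patterns, weights and fields are integers well below $2^{53}$, so
no floating-point tolerance enters the retrieval criterion.

```{r capacity-small}
cap <- storage_capacity(random_network_builder(N = 120, c = 119), c = 119,
                        seeds = 1:3, max_p = 40)
cap
```

A fully connected random network stores about $0.138\,c$ patterns; diluted
random networks ($c \ll N$ but $c \gtrsim \ln N$) stay below $2/\pi \approx
0.64$ patterns per connection. Structural optimization moves far beyond both.

## The row cost functions

Writing the aligned local field at pattern $\nu$ as $1 + R_i^\nu$ (signal
plus crosstalk), the package optimizes each neuron's presynaptic row
independently through the integer quantity

$$A_i^\nu = c\,R_i^\nu = \sum_{j:\,C_{ij}=1}\bigl(\xi_i^\nu \xi_j^\nu W_{ij} - 1\bigr),
\qquad
E_i = \sum_{\nu=1}^{p} \bigl(A_i^\nu - \varepsilon\bigr)^2 .$$

Two targets matter:

* **Noise reduction**, $\varepsilon = 0$: make the crosstalk vanish so every
  stored pattern sits close to a noiseless fixed point.
* **Signal reinforcement**, $\varepsilon > 0$ (the offline convention is
  $\varepsilon = p$): make the crosstalk *positive*, so interference actively
  stabilizes the patterns and deepens their basins.

`row_cost()`, `row_noise()` and `delta_cost_swap()` expose these quantities;
the swap delta is computed incrementally in $O(p)$ per proposal and is tested
against brute-force recomputation.

```{r rowcost}
xs <- generate_patterns(p = 6, N = 40, seed = 2)
cn <- random_connectivity(N = 40, c = 8, seed = 3)
row_cost(1, cn$C[1, ], xs, epsilon = 0)
```

## Simulated annealing per row

Because the cost couples only entries of one row, the network optimization
is `N` independent combinatorial problems: choose `c` of the `N - 1` allowed
inputs. `anneal_row()` runs simulated annealing over *swap moves* (drop one
existing input, add one absent input), which conserve the in-degree and the
empty diagonal by construction:

* geometric cooling with factor 0.99 down to $T_{\text{final}} = 10^{-4}$;
* initial temperature from 50 probe moves, set so the mean uphill move is
  accepted with probability 0.8 (`estimate_initial_temperature()`);
* if no probe is uphill the schedule would be empty, so the annealer falls
  back to a zero-temperature greedy quench with the same proposal budget;
* the best row ever visited is returned, and its cost is re-verified against
  a full recomputation.

The default `moves_per_t = 1` proposes one swap per temperature (about 925
proposals per row over the full schedule). For the quantitative capacity
reproductions the package uses `moves_per_t = 5`: a convergence diagnostic
run before freezing any reference values showed retrieval quality plateaus
between 5 and 20 proposals per temperature while 1 is visibly short of the
plateau. This is a deliberate package choice, documented here rather than
hidden in defaults.

```{r anneal}
cfg <- anneal_config(epsilon = 0, moves_per_t = 5)
opt <- optimize_network(cn, xs, cfg, seed = 4)
c(total_cost_before = sum(opt$e_init), total_cost_after = sum(opt$e_final))
```

Capacity comparisons pair the optimized network against the *same* initial
random network (`annealed_network_builder()` shares the seed lineage of
`random_network_builder()`), and pattern sets are nested in `p` at fixed
seed, so the capacity search is a well-defined monotone scan per seed
(coarse steps plus bisection, identical to a unit-step scan).

## Online structural plasticity

`online_run()` models learning during development: patterns arrive in
batches of 10 while connections are continually added and pruned. The rule
is the zero-temperature counterpart of the annealer with *toggle moves* —
a uniformly drawn potential input is added if absent or pruned if present,
kept only when the row cost strictly decreases — so in-degrees vary freely.
Key conventions:

* the crosstalk target is held at the fixed value $\varepsilon = N/2$
  (the load changes constantly, so a `p`-dependent target is not available);
* each neuron's field is normalized by its *own current in-degree*;
* a new batch is loaded only once the network again retrieves more than
  90% of its stored patterns ($p_{\text{eff}} > 0.9\,p$);
* the run starts at the measured capacity of the initial random network and
  stops after 50 consecutive sweeps without an accepted toggle (or at
  explicit sweep/pattern guards, which are flagged, not errors).

The equilibrium mean in-degree `c_est` is independent of the initial
in-degree `c0`: sparse starts grow, dense starts prune, and runs started
from below characteristically *overshoot* the equilibrium before pruning
back — a connectivity trajectory reminiscent of developmental synaptic
overproduction followed by elimination.

```{r online}
run <- online_run(N = 80, online_config(c0 = 10, batch = 5,
                                        max_outer_iterations = 150,
                                        stop_after_unchanged = 25),
                  master_seed = 3)
run
head(run$trajectory)
```

## Structural and field analyses

Two read-outs characterize *how* optimization rewires the network:

* `conditional_connection_probability()` histograms
  $P(C_{ij} = 1 \mid W_{ij}/W^M)$ over 21 bins (robust for 11–41 bins; empty
  extreme bins are reported as `NA`, never interpolated). Random networks
  are flat at $c/(N-1)$; signal reinforcement concentrates connections on
  large-$|W|$ pairs, while noise reduction avoids them.
* `aligned_field_stats()` and `field_statistics_sweep()` trace the mean and
  spread of the aligned local field across loads: noise reduction shrinks
  the spread at the cost of the mean, signal reinforcement pushes the mean
  well above 1.

```{r fields}
aligned_field_stats(xs, hebbian_weights(xs), opt$C, norm = 8)[c("mean", "sd")]
```

## Problem sizes and reproduction scale

The scientific regimes of interest are large ($N = 2000$, $c = 20$ for the
high-dilution capacities; dense-connectivity sweeps at $N = 2000$ take
hours). The package's test suite and examples instead use sizes chosen to
finish in seconds-to-minutes on one CPU while preserving every qualitative
regime: $N = 300$ fully connected for the classic capacity, $N = 500$ for
the connectivity sweep shape, $N = 200$ for online equilibration. These
sizes are package choices made for desk-scale verification; `scripts/acceptance.R`
in the source tree reruns the headline $N = 2000$ quantities directly.

## Scope and limitations

* All data are synthetic: unbiased i.i.d. ±1 patterns. Correlated or sparse
  patterns change capacities and are out of scope.
* Dynamics are synchronous and deterministic (zero temperature); retrieval
  under stochastic dynamics is not modeled.
* The annealer treats rows independently, which is exact for the cost
  functions used but means no cooperative rewiring across neurons.
* Capacity values at small `c` are coarse by nature (`p_c` granularity is
  one pattern), so improvement ratios at very low in-degree are unstable;
  comparisons should use $c \gtrsim 20$.
* Stochastic reproductions are medians over seeds with finite-size effects
  of a few percent; they are not thermodynamic-limit values.
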