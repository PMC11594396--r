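---
title: "Methods: cooperation, partner choice and invasion resilience on evolving networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperation, partner choice and invasion resilience on evolving networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcoop)
```

## The model

netcoop simulates a fixed-size population playing the prisoner's dilemma on
an undirected simple graph that is rewired only by turnover: at every step a
newcomer joins and one incumbent leaves, a birth–death scheme of Moran type.
The quantity of interest is not the graph per se but the population's
resilience: after the network has settled, one individual is forced to
defect, and we ask whether cooperation recovers or the cheater's strategy
takes over — and how that depends on the *public ranking* newcomers consult
when picking partners.

Payoffs are additive over edges. A cooperator with $K$ cooperating and $J$
defecting neighbours earns $P_i = K(b-c) - Jc$; a defector earns $P_i = Kb$.
With the default $b = 9$, $c = 8$ mutual cooperation is worth $b - c = 1$ per
edge while a single defecting neighbour costs a cooperator $-8$ — cooperation
is productive but easily exploited. Payoffs are *stateless*: they are
recomputed from the current graph whenever needed and never accumulate across
steps, because each step's interaction structure fully determines them.

Fitness is $f_i = (1+\delta)^{P_i}$ with weak selection $\delta = 0.01$. The
exponential map matters: exploited cooperators have negative payoffs, and the
roulette-wheel role-model selection $\Pr(i) = f_i / \sum_j f_j$ needs strictly
positive weights. At $\delta = 0$ the map degenerates to neutral drift.

### One simulation step

1. A role model is drawn fitness-proportionally; the newcomer copies its
   strategy.
2. The candidate set is the role model's closed neighbourhood, visited in
   increasing node order.
3. Each candidate gets an independent *private* perception draw —
   $N(\mu_c, \sigma^2)$ if it cooperates, $N(\mu_d, \sigma^2)$ if it defects
   ($\mu_c = -0.5$, $\mu_d = +0.5$, $\sigma^2 = 0.5$) — endorsed when the
   threshold $\tau$ strictly exceeds the draw. The acceptance probability is
   $\Phi((\tau - \mu_s)/\sigma)$, so cooperators are always endorsed more
   often, and raising $\tau$ makes private information more permissive for
   both strategies.
4. *Public* information endorses a candidate whose centrality (degree,
   betweenness or eigenvector) strictly exceeds (`*_HI`) or falls strictly
   below (`*_LO`) the network average; the `RANDOM` method endorses with
   probability $r_c = 0.8$. Rankings are recomputed once per step, at the end
   of the previous step; the newcomer has no score and is never a candidate.
5. The decision rule: both endorsements $\to$ connect; neither $\to$ reject;
   public-only $\to$ connect with probability $p$; private-only $\to$ with
   probability $q$.
6. The newcomer joins with its accepted edges, then one incumbent is removed
   uniformly at random (role model included, newcomer excluded — the Moran
   default, since nothing more specific is implied by the protocol). An
   accepted edge to the removed incumbent is simply lost.

### The perturbation protocol

A trial initialises an Erdős–Rényi graph on $N = 100$ all-cooperator nodes
with 30% of the $\binom{N}{2}$ possible edges, runs a burn-in of 10,000 steps
so the ranking-specific structure emerges, records the pre-invasion
prosperity metrics (mean payoff, mean degree, and mean payoff ratio — payoff
normalised by $(N-1)(b-c)$, the maximum a fully connected cooperator among
cooperators could earn), then flips one uniformly chosen node to defection.
Stepping continues until one strategy is extinct: all-cooperator absorption
is a *recovery*, all-defector an *invasion*. Absorption is permanent because
strategy copying cannot resurrect an extinct strategy. A cap (`max_steps`,
default $10^6$) bounds unresolved trials, which are reported as censored and
excluded from the recovery-ratio denominator, never silently dropped.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $b$, $c$ | 9, 8 | payoff | benefit/cost per edge; requires $b > c > 0$ |
| $\delta$ | 0.01 | — | selection strength in $f = (1+\delta)^P$ |
| $\mu_c$, $\mu_d$, $\sigma^2$ | $-0.5$, $0.5$, $0.5$ | perception scale | the two perception Gaussians, peaks one apart |
| $\tau$ | swept, $[-2, 2]$ step $0.2$ | perception scale | private-information permissiveness |
| $p$, $q$ | 0.25 | probability | weight of public-only / private-only endorsements |
| $r_c$ | 0.8 | probability | endorsement rate of the RANDOM ranking |
| $N$ | 100 | nodes | population size, constant throughout |
| `init_density` | 0.30 | fraction | expected share of possible edges at start |
| `burn_in` | 10,000 | steps | settling time before the forced mutation |

## Design choices

**Exponential fitness.** The payoff-to-fitness map is read as
$(1+\delta)^{P}$ rather than the product $(1+\delta)P$: the product is
negative for exploited cooperators, which would break roulette selection; the
exponential is the standard weak-selection mapping and is monotone and
positive over the whole reachable payoff range
$[-(N-1)c,\,(N-1)b]$.

**All-cooperator start.** The protocol mutates an individual *to* defection
after the burn-in; that experiment is only coherent if the burn-in is
cooperator-monomorphic, so initial strategies are all-cooperator.

**$G(n,p)$ initialisation.** "30% of all possible edges" is read as the
expected fraction: each possible edge is included independently with
probability 0.3. An exact-count $G(n,M)$ variant is available via
`er_exact = TRUE` since the wording admits both.

**Strict comparisons.** Public signals use strict inequalities against the
network average; a score exactly equal to the average endorses under neither
`HI` nor `LO`. This matters on regular graphs (the complete graph at
`init_density = 1`, cycles, and other transient states), where all public
signals are negative. Private signals are strict too; perception ties have
probability zero.

**RNG discipline.** A single seeded stream drives, in fixed order per step:
the role-model roulette, then the per-candidate perception draws (candidates
sorted by node id), then the per-candidate decision draws (a uniform is
consumed only in the probabilistic cases), then the replacement choice.
Trials are therefore bit-reproducible from their seed, and batch trial $i$
uses `seed + i − 1` so any trial can be reproduced in isolation. Sweep cells
get disjoint seed blocks, making cell order immaterial.

## Numerical choices

**Betweenness** is computed by Brandes' dependency accumulation (in C++,
`src/centrality.cpp`) over unordered pairs — identical to exhaustive
shortest-path enumeration, which the test suite verifies on random graphs of
up to 8 nodes at tolerance $10^{-6}$. Centralities are recomputed from
scratch after every step; at $N = 100$ this costs roughly a millisecond, and
no incremental update is attempted.

**Eigenvector centrality** is computed by power iteration on $A + I$, run
*per connected component*. The identity shift makes the iteration matrix
primitive on each component, so bipartite structure cannot cause
oscillation; iterating per component keeps the convergence rate governed by
the *within*-component spectral gap — iterating on the whole graph instead
would mix at the ratio of the top spectral radii of *different* components,
which is arbitrarily close to 1 when two components are near-tied, a routine
occurrence in the sparse fragmented graphs the `EIG_LO` regime produces. The
component with the largest spectral radius carries the scores (exact ties
broken by lowest node index); all other nodes, including isolated ones,
score 0, and the vector is normalised to unit Euclidean length. Convergence
is declared at entrywise change below $10^{-8}$ with a 200,000-iteration
cap; a component that still has not met the tolerance is accepted only if
its eigen-residual is below $10^{-6}\lambda$ — i.e. the iterate is an
eigenvector at the precision any score-versus-average comparison could
resolve — and is a hard error otherwise. Since signals only compare scores
with their average, all centrality conventions (raw degree, pair-fraction
betweenness, unit-norm eigenvector) are behaviour-preserving choices fixed
for reproducible logs.

## What the generator emulates — and what it does not

All inputs are synthetic by construction: the simulator *is* the data
generator, and its defaults are the study conditions above. The
Erdős–Rényi start gives a statistically homogeneous, unclustered substrate;
real social networks start from heavy-tailed, clustered topologies, so
passing tests say nothing about ring or scale-free substrates (explicitly
out of scope). Perception noise is Gaussian, symmetric and memoryless;
there is no learning, no strategy mutation beyond the single forced flip,
no rewiring of existing edges, and no repeated-game memory. Conclusions
from this package are about the model, not about any empirical network.

## Problem sizes used by the tests

The full study conditions (burn-in 10,000, 1000 trials per cell, the
588-cell sweep) are what `sweep_rankings()` defaults target, but the test
suite exercises the machinery at reduced scale chosen as a deliberate
trade-off between statistical resolution and a test run of a few minutes:
structural invariants on one full $N = 100$ trial with burn-in 2,000 under a
betweenness ranking; the connectivity/resilience direction checks at
$\tau = 1.6$, $p = q = 0.25$ with burn-in 500 and 30 trials per ranking; and
the $q$-effect on connectivity with burn-in 400 and 12 burn-in-only trials
per method. Stochastic assertions use three-standard-error tolerances
against analytic values where one exists (normal-CDF acceptance curves,
binomial signal rates) and direction-only comparisons where the reference
figures are qualitative.

## Known limitations

- Recovery/invasion times are step counts; no physical time scale is implied.
- Censored trials (cap hit) are rare under the default cap but are possible
  in principle; they are reported, and the recovery ratio is conditional on
  resolution.
- Near-degenerate eigenvector spectra are resolved to $10^{-6}$, not
  exactly; a component tie makes the dominant eigenvector genuinely
  non-unique and the winner is a deterministic convention.
- The betweenness recomputation dominates runtime at full scale; a
  10,000-step burn-in under `BET_*` takes a few seconds per trial, so the
  full 588-cell, 1000-trial sweep is a compute-cluster job, not an
  interactive one.
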