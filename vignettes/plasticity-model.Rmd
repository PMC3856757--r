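---
title: "The plastisim model: reaction-norm evolution under spatial and temporal heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The plastisim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastisim)
```

## The question the model addresses

Organisms can adapt to a heterogeneous environment along two routes:
*genetic differentiation*, where local populations fix different trait
values, or *phenotypic plasticity*, where a single genotype expresses
different phenotypes depending on the environment it develops in. Which
route selection favors depends on **cue reliability** — how well the
environment at the time the phenotype is determined predicts the
environment in which selection later acts. plastisim is a forward-time,
individual-based simulator built to explore that question across
combinations of spatial structure, temporal fluctuation, life-history
order, and movement pattern.

## Model structure

### Space and genotype

The metapopulation is a linear array of $D$ demes (default 50). The locally
optimal phenotype $\theta_i$ increases linearly along the array with slope
0.4 trait units per deme, from $-9.8$ to $+9.8$ under the defaults, centred
on the midpoint $(D+1)/2$.

Each diploid individual carries 5 *nonplastic* and 5 *plastic* loci with
continuous allelic values. The phenotype, fixed once at development in deme
$i$, is

$$T = \sum_k N_k + E_i \sum_k P_k,$$

where $E_i$ is the environment-dependent expression multiplier, a second
linear function of position with slope 0.04 per deme,
$E_i = 0.04\,(i - 25.5)$ under the defaults. There is no random component
of phenotypic variation. $\sum N$ is the reaction-norm intercept at the
gradient midpoint; $E_i \sum P$ its slope contribution. Because
$E_i = \theta_i / 10$ exactly, a genotype with $\sum N = 0$ and
$\sum P = 10$ expresses the locally optimal phenotype in *every* deme —
the "pure plasticity" solution. A genotype with $\sum P = 0$ has a flat
reaction norm; a set of demes fixing different $\sum N$ values is the
"pure differentiation" solution.

### Life cycle

Each generation executes, in order:

1. **temporal environment update** (see below),
2. **development** — phenotypes fixed from the development environment of
   the natal deme,
3. either **dispersal then selection** (`move_first`) or **selection then
   dispersal** (`select_first`),
4. **reproduction** under soft selection.

Survival is Gaussian in the deviation from the local selection optimum,
$W = \exp\!\left(-(T-\theta)^2 / (2\sigma^2)\right)$ with $\sigma = 2$ by
default; each individual draws a uniform number and dies if $W$ falls
below it. (Whether the published denominator was $2\sigma^2$ or $\sigma^2$
is not recoverable from our sources; the form used is stated here so any
comparison can rescale $\sigma$.) Reproduction pairs survivors within a
deme uniformly at random *with replacement* — self-pairing included, so a
single survivor refills its deme — each pair leaving one offspring, until
the deme again holds its carrying capacity (100; 1000 for single-deme
runs). Offspring inherit one allele per locus from each parent with free
recombination, and every allele mutates with probability 0.1 by a
Normal(0, 0.1) step (an infinite-alleles model). Extinction is
metapopulation-level: a run ends early only if *no* individual anywhere
survives to reproduce; empty demes are otherwise recolonizable by later
dispersal.

### Temporal heterogeneity

Deviations from the gradient follow a stationary AR(1) process on the
trait scale,

$$d_t = \rho\, d_{t-1} + \tau \sqrt{1-\rho^2}\; z_t, \qquad z_t \sim
\mathcal N(0, 1),$$

so the marginal standard deviation is exactly $\tau$ at every
autocorrelation $\rho$ (the reason this parameterization was chosen: it
makes "$\tau$ = the SD of environmental variation" literally true). $\tau$
is specified as a percentage of the gradient's optimum span (19.6 trait
units under the defaults). Three timing patterns are available:

| pattern | before development | before selection | within-generation correlation |
|---|---|---|---|
| `p1` | fixed | varies | — |
| `p2` | varies | fixed | — |
| `p3` | varies | varies | $c \in [-1, 1]$ |

Under `p3` the two stage innovations are bivariate standard normal with
correlation $c$; $c = 1$ is a single change carried through the whole life
cycle, and $c = -1$ makes the development cue point exactly away from the
selection optimum. A deviation applied to the development stage is divided
by the fixed ratio optimum-slope/expression-slope (10) when it enters the
expression multiplier, so one environmental displacement moves the cue and
the optimum consistently. With `synchronized = TRUE` one innovation per
stage drives all demes at once (a "warm year everywhere" scenario);
otherwise demes fluctuate independently.

### Dispersal

*Stepping-stone*: displacement is the nearest integer of a
Normal(0, $s$) draw, clamped at the terminal demes, which couples the
probability of moving and the distance moved through one parameter. The
headline dispersal rate $r$ is converted to $s$ by the exact inverse
$s = 0.5/\Phi^{-1}(1 - r/2)$, so the realized move fraction equals $r$
(this also means $r = 1$ is unsupported for stepping-stone). The
nearest-integer discretization is a declared choice — the alternative
truncation conventions would break the exact rate correspondence.
*Island*: move with probability $r$; destination uniform over the other
$D-1$ demes. Both kernels are lossless (no mortality in transit).

### Outcome statistic

Mean plasticity is the average of $\sum P$ over residents within each
deme, then averaged (unweighted) across occupied demes, every generation.
It is standardized by the optimum-matching plastic sum
(optimum-slope/expression-slope = 10): **relative plasticity** is 1 for
the pure-plasticity outcome, 0 for flat norms, above 1 for
*hyperplasticity* (a bet-hedging slope steeper than optimal) and negative
for countergradient-style norms. Reported end states average the final 100
generations rather than the last generation alone, to reduce sampling
noise; per-generation values remain available in the trajectory.

## Replicates, equilibrium and extinction accounting

A parameter combination is replicated (default 20 times) with
counter-derived child seeds, re-running until the target number of
non-extinct replicates is reached or 60 attempts are exhausted. Averages
use successful replicates only; the extinction probability is the extinct
fraction of attempts. Runs default to 10,000 generations; equilibration is
checked by `equilibrium_check()`, a linear fit over a trailing window
whose fitted total drift must not exceed a stated tolerance (the original
"no further directional trend" criterion has no published tolerance, so
ours — 0.5 trajectory units across a 500-generation window by default —
is explicit and adjustable).

## What the simulator emulates, and what it does not

The generator *is* the model: there is no external data. Its defaults are
the stated world — 50 demes, slope 0.4, $\sigma = 2$, capacity 100, 10%
mutation at SD 0.1, discrete founder alleles in $\{-2,\dots,2\}$. What it
deliberately does not contain: hard selection (capacity is refilled
regardless of how many survived), fecundity selection, dominance,
epistasis, linkage, overlapping generations, costs of plasticity or of
dispersal, nonlinear or two-dimensional gradients, and continuously labile
traits. A green qualitative test therefore establishes that *this* model
reproduces the direction and rough magnitude of the published surfaces at
reduced scale (2,000 generations, 5 replicates), not that any of the
excluded mechanisms would leave those surfaces unchanged.

## Numerical and design choices

* **Single-deme $\tau$ base.** Temporal-only (one-deme) runs convert
  $\tau$ percentages with the same 19.6-unit base as the default gradient,
  for comparability between the two experiment families. An observed
  consequence: with uncorrelated within-generation change, single-deme
  populations face a real extinction risk once $\tau$ reaches roughly
  10–15% of that base (the optimum leaps away from everyone
  simultaneously), so the replicate protocol matters there.
* **Order of stochastic events** is fixed (environment, development,
  movement/selection, reproduction), and all randomness flows through the
  R RNG, so a run is bit-reproducible from its seed, including the C++
  reproduction kernel.
* **Self-pairing** is allowed when drawing parents with replacement; it is
  what guarantees a lone survivor can refill a deme. With 100 survivors
  the probability of selfing is 1%, which is negligible for the reported
  statistics.
* **Tie-breaks and degenerate inputs**: a single-deme gradient is flat
  (optimum 0, multiplier 0); empty demes are excluded from deme averages,
  not imputed; an extinct run has no end state and is excluded from
  outcome averages but counted in extinction probability.

## Known limitations

Relative plasticity summarizes the *mean* reaction norm; the package does
not decompose within-deme genetic variance or norm curvature. The
stepping-stone/island pair brackets, but does not fill, the continuum of
spatially autocorrelated dispersal patterns. Transient dynamics (the
approach to equilibrium) are recorded in the trajectories but are not an
analysis target.
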