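---
title: "Induced versus constitutive defense in the Imd pathway: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Induced versus constitutive defense in the Imd pathway: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdsim)
```

## The scientific question

Hosts can defend themselves with *induced* responses, switched on by
signaling when a threat is detected, or *constitutive* defenses that are
always on. Induction saves the cost of standing defense but pays a delay;
constitutive defense is immediate but always costly. `imdsim` implements a
mechanistic model of this trade-off built on the *Drosophila melanogaster*
Imd (immune deficiency) pathway — the NF-κB cascade that senses
Gram-negative peptidoglycan and drives antimicrobial peptide (AMP)
production — and asks in which bacterial environments each strategy wins.

## The induced model

Nine coupled ODEs track bacteria in the gut (B), free peptidoglycan (G),
free receptors (R), the receptor–PG complex (C), active Relish (N), the
scavenger PGRP-LB (L), Pirk (P), the repressosome complex (S), and AMP
(A):

$$
\begin{aligned}
\dot B &= f(t) + k_0 B - A B &
\dot G &= \alpha k_0 B - LG - RG + PC + \lambda_3 C - \lambda_1 G \\
\dot R &= R_0 + \beta_1 \tfrac{N}{N+Z_n} - PR - RG + \lambda_3 C - \lambda_2 R &
\dot C &= RG - PC - \lambda_3 C \\
\dot N &= \beta_2 C - \lambda_2 N &
\dot L &= \beta_3 \tfrac{N}{N+Z_n} - \lambda_2 L \\
\dot P &= \beta_4 \tfrac{N}{N+Z_n} - \lambda_2 P &
\dot S &= \beta_5 \tfrac{N}{N+Z_n} - \lambda_2 S \\
\dot A &= \beta_6 \tfrac{N}{N + Z_n + Z_n S / Z_s} - \lambda_2 A & &
\end{aligned}
$$

The external influx $f(t)$ is the only forcing. Three negative feedback
loops shape the response: PGRP-LB scavenges the input signal, Pirk removes
receptors and complexes, and the repressosome competes with Relish at AMP
promoters (the competitive occupancy term in $\dot A$ — binding energies
$Z_n$, $Z_s$ are inversely proportional to binding probability, so a
*small* $Z_s$ means *strong* repression). The occupancy terms are
first-order saturation functions; we read the binding-energy symbols as
scalar constants, not Hill exponents, and fix the Hill coefficient at 1 —
the equations as written contain no exponentiation and nothing in the
model's behavior requires cooperativity.

The constitutive strategy keeps $A$ fixed, so only $\dot B = f + k_0 B -
AB$ remains.

**Initial conditions.** All nine variables start at 0 (a naive host with
no prior exposure). This makes the silent pathway analytically checkable:
with $f \equiv 0$ only receptors move, relaxing to $R_0/\lambda_2$, which
the tests exploit as a closed-form oracle.

**Degradation rates.** R, N, L, P, S and A share $\lambda_2$. The
per-species generalization is a straightforward extension but all shipped
defaults and experiments use the shared rate.

## Numerical integration

Both models are integrated with a fixed-step kernel (Euler, default $h =
0.01$ time units; classical RK4 available). A fixed step — rather than an
adaptive library solver — is a deliberate choice: the random-walk influx
is piecewise constant with jump discontinuities at every step boundary,
which defeats adaptive error control, and a fixed step makes stochastic
runs exactly reproducible. On smooth sinusoidal forcing, Euler at $h =
0.01$ stays within 1% of RK4 at $h = 0.001$ on all nine components, and
the RK4 solution agrees with an adaptive reference (`deSolve::lsoda`) to
about $10^{-5}$ relative — both are asserted in the test suite.

Euler steps can undershoot zero; concentrations are physical, so every
component is floored at 0 after each step (`clip_negative`, on by
default) and the number of clipped values is reported on the trajectory.

One exception to the fixed-step rule: when the constitutive model's AMP
grid is scanned under a walk (200 levels × many walks), the package uses
the *exact* solution of the linear equation on each constant-influx
interval, $B(t{+}\Delta) = Be^{r\Delta} + f\,(e^{r\Delta}-1)/r$ with $r =
k_0 - A$, accumulating the exact interval integrals for the time average.
This is both faster than sub-stepping and error-free; the tests confirm
it agrees with the Euler route on the optimum it selects.

## Fitness

After a sojourn, fitness decreases exponentially with the summed
time-averaged burden:

$$F_\text{induced} = e^{-(\bar B + \bar N + \bar L + \bar P + \bar S + \bar A)},
\qquad
F_\text{constitutive} = e^{-(\bar B + A)} .$$

Free peptidoglycan, free receptors and the complex carry no cost — they
are not synthesized effectors — and the constitutive cost charges the
standing level $A$ itself. An alternative mode (`fitness_weights(mode =
"amp_only")`) charges only $\bar A$ and $\bar B$, with weights that let
either immunopathology or bacterial load count double. Across a set of
walks the strategy fitness is the **arithmetic mean of per-walk fitness**,
never the fitness of mean components; the exponential is nonlinear and the
order matters (a test demonstrates the difference on a heterogeneous walk
set). The strategy comparison is $\Delta F = F_\text{constitutive} -
F_\text{induced}$: negative favors induction.

## Environments and encounters

Environments are square lattices (default 100×100) seeded with $d$
colonies grouped into $p$ clusters — a discrete Thomas-style cluster
process. Cluster centers are uniform; colonies scatter around their
center with an isotropic Gaussian offset (default `cluster_sd = 3` cells,
chosen to give visually tight, well-separated clumps on a 100-cell
lattice) and are rounded to cells with toroidal wrap. $p = 1$ is maximal
heterogeneity (one blob); $p = d$ recovers uniform placement. Collisions
are kept as per-cell multiplicities so colony number is conserved
exactly. The toroidal boundary (for placement, distances and walks)
avoids edge artifacts in long sojourns. The mean nearest-neighbor
distance under the toroidal metric (`patchiness_statistic()`) verifies
the knob's direction: clustered environments score several-fold lower
than uniform ones.

The fly's sojourn is a simple random walk: uniform start, one move per
step to a uniformly chosen von Neumann neighbor (the lattice is regular,
so the walk's stationary distribution is uniform — asserted by a
Monte-Carlo occupancy test). While the fly occupies a cell with colonies
it ingests at rate `dose × colony count` (default dose 1); colonies are
not depleted, which keeps the coupling Markovian and avoids inventing an
unparameterized regrowth mechanism. Each walk step spans 1 time unit,
integrated with 100 Euler substeps.

What the generator does *not* emulate: colony growth or decay within an
environment, chemotaxis or biased movement, fly mortality, and
continuous-space colony positions. Passing tests therefore speak to the
lattice abstraction, not to quantitative properties of real foraging
flies.

## Optimization

The induced strategy has 11 free host parameters ($\lambda_2, \lambda_3,
R_0, \beta_1..\beta_6, Z_n, Z_s$); the bacterial attributes ($\alpha,
k_0, \lambda_1$) describe the environment and stay fixed. Optimization is
a stochastic hill climb under deterministic sinusoidal forcing $f(t) =
\omega \sin^2(t\Phi)$ (stochastic-input optimization would be
prohibitively expensive, and a predictable fluctuation is the regime in
which plastic responses can evolve): each proposal multiplies one
uniformly chosen parameter by $e^u$, $u \sim U(-0.5, 0.5)$, and is
accepted only on strict improvement. Defaults: 3 restarts from
log-uniform draws in $[0.01, 10]$, 2000 proposals each, bounds
$[10^{-4}, 10^2]$ enforced by rejection, $\omega = 1$. The evaluation
horizon is $t_\text{end} = \min(10\pi/\Phi, 1000)$ — at least five
forcing periods so the time average is representative, capped so a
single evaluation stays cheap. Proposals whose integration blows up are
rejected and never enter the acceptance trace. On a reduced
two-parameter landscape the climb reaches within 5% of an exhaustive
dense-grid oracle (asserted in the tests).

The constitutive strategy is optimized by exhaustive scan of $A \in
\{0.01, 0.02, \ldots, 2\}$, with ties broken toward the smaller (cheaper)
level. Against stochastic environments the scan optimizes the mean
per-walk fitness; across multiple environments a *single* $A$ must serve
all of them, so the scan maximizes the (probability-weighted) mean of the
per-environment fitness curves — this shared-level constraint is exactly
what multi-environment fluctuation exploits.

## Experiments

* `run_fitness_grid()` — the heat-map experiment: one environment per
  (density, patchiness) cell, both strategies facing the *same* walks
  (paired comparison), constitutive re-optimized per cell.
* `compute_piw()` — proportion of induced wins; strict inequality, ties
  count as constitutive wins (conservative toward the null; ties are
  measure-zero in floating point except in degenerate constructions).
* `environment_pool()` / `sample_multi_environment()` — fluctuation
  across environments: pools are restricted to cells where the
  constitutive optimum wins in isolation, then $j$ environments are drawn
  without replacement (or two with weights $q$, $1-q$), induced fitness
  is the mean across them, and the constitutive side takes the best
  single $A$ for the whole draw.
* `gamma_scan()` / `delta_scan()` — negative-regulator perturbations:
  $\gamma$ rescales the PGRP-LB/Pirk production rates
  ($\beta_3, \beta_4$), $\delta$ rescales the repressosome binding energy
  ($Z_s$); all scan variants share environments and walks so differences
  are attributable to the perturbation alone. With $\beta_5 = 0$ the
  repressosome is never produced and fitness is exactly invariant in
  $\delta$ — a plumbing check the tests assert bitwise.

Seeds: every driver takes one seed and derives independent child seeds
per component (environment, each walk, each resampling stage) with a
documented integer hash (`child_seed()`), so enlarging one part of an
experiment never perturbs another.

## Problem sizes and defaults

The shipped defaults are desk-scale: 100 walks of 5,000 steps per
environment and 500–10,000 resampling repeats, which resolve the
qualitative contrasts (the sign structure of $\Delta F$ over the grid,
the rise of PIW with $j$) with comfortable margins. The full-scale
settings (1,000 walks of 100,000 steps, 10,000 repeats) are plain
configuration changes: `walk_config(n_steps = 1e5, n_walks = 1000)`.

## Known limitations

* The model is deterministic given $f(t)$; there is no intrinsic noise in
  the kinetics (no chemical-master-equation regime) and no delay terms.
* One environment realization per grid cell per seed; a config flag
  regenerating environments per walk is a natural extension but the
  shipped experiments hold the environment fixed within a cell.
* The optimizer is a local stochastic search; restarts mitigate but do
  not eliminate multi-modality, and optimized parameter values are
  seed-dependent even when the achieved fitness is stable. Conclusions
  are therefore drawn from fitness and PIW contrasts, not from
  individual optimized parameter values.
* Cross-generational evolution of the network is out of scope; the
  package compares the performance of fixed strategies.
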