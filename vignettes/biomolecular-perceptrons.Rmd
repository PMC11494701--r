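---
title: "Sequestration-based biomolecular perceptrons under shared resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequestration-based biomolecular perceptrons under shared resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnnsim)
```

## The model

A node of a biomolecular neural network (BNN) is one sigma factor $S_i$
paired with its antisigma protein $A_i$. Weighted sources produce the two
species: a positive-signed weight $w$ on a source of concentration $y$
contributes a flux $w\,y$ to the sigma, a negative-signed weight to the
antisigma; biases act on a virtual input held at 1 µM. All concentrations
are in µM and times in hours. The reactions per node are

* production: $\varnothing \xrightarrow{u_i} S_i$,
  $\varnothing \xrightarrow{v_i} A_i$, with $u_i,v_i$ the signed weighted
  source fluxes;
* sequestration: $S_i + A_i \xrightarrow{\gamma_1} \varnothing$
  (irreversible, the stoichiometric annihilation that implements
  subtraction);
* degradation: $S_i \xrightarrow{\delta} \varnothing$,
  $A_i \xrightarrow{\delta} \varnothing$;
* polymerase binding: $S_i + C \xrightarrow{\gamma_2} C_i$, where $C$ is
  core RNA polymerase drawn from one finite shared pool with total
  concentration $c^{tot}$;
* complex turnover: $C_i \xrightarrow{\delta} S_i + C$.

The turnover convention deserves a comment, because the steady state of the
whole package hinges on it. Turnover must return the polymerase (otherwise a
finite pool with nonzero throughput has no steady state), and we release the
sigma together with it. With this convention the polymerase-binding flux
cancels out of the free-sigma balance at steady state, which reduces every
node to the isolated sequestration pair

$$\gamma_1 \bar s^2 + \Bigl(\delta - \gamma_1\frac{u - v}{\delta}\Bigr)\bar s - u = 0,
\qquad \bar a = \bar s - \frac{u - v}{\delta},$$

and makes the *normalized* complex output exactly independent of the pool
size (see below) — a property the published analysis states outright and
that several package invariants test. Degrading the sigma inside the
complex instead couples $\bar s$ to the free polymerase and destroys that
independence; we verified numerically that normalized single-node maps then
drift by order 0.1 between pool sizes, so that variant is not implemented.

The complex balance closes the pool self-consistently:
$\bar c_i = c^{tot}_{free}\,\gamma_2 \bar s_i/\delta$ with
$c_{free} + \sum_i \bar c_i = c^{tot}$. For a single node this gives the
saturating activation
$$\bar c_1^{\,n} \;=\; \frac{\bar c_1}{c^{tot}} \;=\;
  \frac{\gamma_2 \bar s_1}{\delta + \gamma_2 \bar s_1},$$
independent of $c^{tot}$ because $\bar s_1$ is. With several nodes the
denominator gains every competitor's $\gamma_2 \bar s_j$, which is the
resource-competition coupling: node $j$'s saturation ceiling is
$c^{tot} - \sum_{i\neq j} \bar c_i$.

## Activation functions and regimes

Two dimensionless groups organize the behavior ([regime_indicators()]):

* $\xi = \delta^2 / (\gamma_1 \max_k \mathrm{flux}_k)$, the
  sequestration-speed indicator: the reciprocal sequestration-strength
  group obtained by nondimensionalizing concentration by
  $\mathrm{flux}/\delta$ and time by $1/\delta$. For $\xi \ll 1$ the pair
  steady state converges to the **AReLU** limit
  $\bar s = \max(0, (u-v)/\delta)$ — sharp thresholding. For $\xi \gg 1$
  thresholding is lost and $\bar s \to u/\delta$.
* $r = \gamma_2/\gamma_1$, the competitive binding ratio. For $r \ll 1$
  (fast competitive binding) the saturating output $\bar c_1^{\,n}$
  inherits the AReLU threshold and becomes the **ASReLU**: rectified,
  linear above threshold, saturating at 1 (or at the competitor-depleted
  ceiling). For $r \gtrsim 1$, $\gamma_2$ amplifies the soft
  sub-threshold tail of $\bar s$ and the clean boundary is lost.

## Multilayer networks

The output of a node is its complex $C_i$ — the transcriptionally active
species — and downstream production is linear in its concentration with
unit gain (µM of complex drives its weight in µM/h of flux). All layers
draw on the same pool. We considered driving downstream nodes by the
occupancy fraction $\bar c_i/c^{tot}$ instead, which would make the
normalized multilayer map exactly pool-invariant; it was rejected because
it rescales the published layer-2 weights by $1/c^{tot}$ and demonstrably
breaks the two classifier designs (the band-stop's silent center band
fills in). Consequence: multilayer patterns are only *approximately*
pool-invariant — layer-1 normalized maps are exactly invariant, but the
output region's edge shifts slightly with $c^{tot}$ because the layer-2
input flux scales with the pool while the layer-1 sub-threshold tails do
not rescale relative to the bias. Single-layer normalized maps are exact.

The `coupled` input–output mode models inputs transcribed by a
housekeeping sigma factor rather than an orthogonal polymerase: two
housekeeping complexes $C_S, C_A$ form at $\gamma_2 s_c c_{free}$ from a
fixed housekeeping sigma concentration $s_c$ (default 1 µM; treated as a
buffered parameter, not a dynamic species), occupy the same pool, and gate
all external-input
and bias production. This suppresses the response amplitude while leaving
the onset boundary (the $w_1 x_1 = w_2 x_2$ line) in place, since both
production fluxes scale by the same occupancy.

The ideal reference ([ideal_relu_network()]) is the same wiring evaluated
as a resource-free ReLU network; [deviation_from_ideal()] compares a
mechanistic map against it.

## Decision-boundary and overlap conventions

The source figures draw boundaries graphically, so the extraction rules are
package conventions:

* [extract_decision_boundary()]: region = cells at or above
  $\theta \cdot \max$ (default $\theta = 0.5$, ties in), components
  4-connected.
* [deviation_from_ideal()]: the *ideal* region is the ideal map's support —
  a ReLU is "on" exactly where it is positive, and its support contour is
  the dashed design boundary of the figures. The saturating mechanistic
  unit switches on over a narrow band, so its $\theta$-level set tracks the
  same onset line; comparing half-max regions of both maps instead mostly
  measures that one of them saturates and the other does not.
* [overlap_metric()]: Jaccard index of the two maps' $\varepsilon$-supports
  (each normalized by its own maximum, default $\varepsilon = 0.1$), so
  identical maps score 1 and disjoint ones 0.

## Solvers and numerical choices

Two independent routes compute every steady state:

* **Algebraic** ([solve_resource_fixed_point()]): given $c_{free}$, each
  node reduces to the sequestration quadratic (solved in layer order with
  a cancellation-free root form), and the pool closes through a
  one-dimensional root problem for $c_{free}$ on $[0, c^{tot}]$. The
  endpoints always bracket, so a bracketed root finder cannot fail; a few
  Newton polish steps follow because with fast binding the conservation
  residual is steep in $c_{free}$ and bracketing precision alone leaves an
  $O(\gamma_2 \bar s)$ right-hand-side error. (A damped fixed-point
  iteration over the pool would also work; the bracketed root is
  preferred because its convergence does not depend on a damping
  constant.)
* **Integration** ([integrate_to_steady_state()]): `deSolve::ode` (lsoda,
  `rtol` 1e-10, `atol` 1e-12) from the all-zero state over a logarithmic
  time mesh, stopping when $\|f\|_\infty < 10^{-9}$ µM/h (default
  `t_max` $10^4$ h; non-convergence is flagged, not raised).

The test suite cross-checks the two on 100 seeded random networks (up to 4
nodes, binding rates log-uniform in 0.1–1000 µM⁻¹h⁻¹, degradation
0.1–10 h⁻¹) at a mixed relative tolerance of $10^{-6}$ with scale floor 1
µM — concentrations below the floor are compared absolutely, since
sub-threshold species are meaningfully "zero" at any solver tolerance.
Pool conservation is an algebraic identity of the assembled right-hand
side and is asserted to $10^{-12}$ at random states and $10^{-8}$ along
trajectories.

Degenerate inputs: $c^{tot} = 0$ encodes the pure sequestration motif (no
pool; the free sigma is the output); zero production gives the exact zero
state; a zero map yields an empty boundary with an explicit flag rather
than a region.

## Presets and the fixture generator

The nine presets transcribe the published parameter sets: $\delta = 1$/h
and $\gamma_2 = 10$ µM⁻¹h⁻¹ throughout, inputs on $[0,1]$ µM.
$\gamma_1$ is the regime dial: required explicitly for the bare-motif
presets (the published sweeps vary it), defaulting to 100 ($r = 0.1$) for the
single-perceptron presets and 1000 ($r = 0.01$) for the classifier
networks, the regime in which they track their ideal design. Pool sizes
not tabulated per panel default to 0.5 µM (single perceptron) and 0.2 µM
(classifiers, the value printed for the band-stop figure). The two-node
interference preset is wired so node 1 peaks at $(1,0)$ and node 2 at
$(1,1)$: each node then loses output exactly where the other consumes the
pool, which is the effect that preset exists to exhibit.

[generate_random_network()] draws small random valid feed-forward networks
(seeded, RNG-state-clean) for property tests. It emulates the *structure*
of the study's networks — sizes, signed weights, rate ranges — not real
data: there is no measurement noise, no cell-to-cell variability, no
crosstalk, and binding is irreversible by construction. Passing tests
therefore certify the solvers and the stated model, not the behavior of a
wet implementation.

## Problem sizes

Tests use 15–51 point grids per axis and 100 random networks; the shipped
analyses run in about a minute total. Response maps default to 51×51,
matching the resolution at which the published boundaries are resolved;
results are insensitive to refinement because the algebraic solver is
exact per point.

## Known limitations

* Reversible binding is not modeled (the steady state is unchanged by
  reversibility; transients with reversible binding are out of scope).
* No transcription/translation stages, delays, dilution by growth, or
  stochasticity; production is a single lumped flux.
* The housekeeping sigma in coupled mode is a fixed parameter, not a
  dynamic species.
* Networks are feed-forward and weights are fixed: these circuits do not
  learn; weight selection is the designer's task.
* Multilayer pattern invariance to $c^{tot}$ is approximate (see above);
  claims of exact invariance hold only within a single layer.
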