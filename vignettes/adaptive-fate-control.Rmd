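---
title: "Adaptive fate control: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive fate control: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatecontrol)
```

This vignette is the package's account of the science it implements: the
models, the controller and its approximation, the numerical machinery, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The endogenous networks

All models are two-gene regulatory motifs with Hill-type production and
first-order decay, built by mass action from an explicit chemical reaction
network. Concentrations are in µM, time in hours. The motifs are:

* **toggle switch** — mutual repression,
  $\dot y_1 = \alpha_1 K^m/(K^m + y_2^m) - \delta y_1$ and symmetrically
  for $y_2$. At the nominal parameters ($\alpha = 2.2$, $K = 1$, $m = 3$,
  $\delta = 1$) it is bistable: two mirrored stable states
  ($\approx (2.18, 0.19)$) and a saddle on the diagonal
  ($y + y^4 = \alpha$, $y \approx 1.04$).
* **mutual activation** — both Hill functions activating; stable states
  are "both high" ($y^3 - 2.2y^2 + 1 = 0$, largest root
  $\approx 1.93$) and the origin, separated by an unstable diagonal point.
* **toggle with self-activation** — adds an activating self-loop of
  strength $\alpha_3$ to one or both species. With the dedicated nominal
  set ($\alpha_{1,2,3} = 1.2$, $K = 0.5$, $m = 4$) the double variant is
  tristable: on the diagonal the repressing and activating Hill terms sum
  to one, so $(\alpha/\delta, \alpha/\delta) = (1.2, 1.2)$ is an exact
  intermediate fixed point, flanked by two asymmetric stable states and
  two saddles.

The throughline of "Km" in the rate laws is $K^m$ (the Hill constant
raised to the cooperativity): $K$ carries µM units and $m$ is listed as a
separate dimensionless parameter, so no other parse is dimensionally
consistent.

## The adaptive controller

The controller is an incoherent feedforward loop closed by sequestration.
Its drive is a Hill function $p$ of the sensed endogenous species; $p$
produces the intermediate $X$ (rate $\theta$) and the sequestering species
$U_2$ (rate $\xi$); $X$ produces the output $U_1$ (rate $k$); $U_1 + U_2
\to \varnothing$ at rate $\gamma$; all controller species decay at
$\delta$. The output actuates a target species either additively
($+\beta u$) or through saturated degradation
($-\beta u \, y/(y + K_{deg})$).

Two dimensionless design quantities govern behaviour:

* the **adaptive metric** $r = \xi\delta/(k\theta)$. At $r = 1$ the two
  IFFL arms cancel at steady state, so the controller output vanishes for
  any input that settles — the actuation is transient and the equilibrium
  landscape is asymptotically unperturbed;
* the **sequestration rate** $\gamma$, whose large-$\gamma$ limit makes
  the cancellation fast. At a controlled equilibrium the residual output
  scales as $\gamma^{-1/2}$ (the positive root of
  $\gamma u^2 + (\delta - \gamma d) u - k\theta p/\delta = 0$ with
  $d = p(k\theta - \xi\delta)/\delta^2$), which the test suite verifies
  as a log–log slope of $-0.5$ on the equilibrium alteration.

In the fast-sequestration limit the input–output map is
$[k\theta - \xi(s+\delta)]/(s+\delta)^2$ followed by clipping at zero.
`approx_output()` realizes it in the time domain as a two-stage low-pass
cascade $\dot z_1 = -\delta z_1 + y$, $\dot z_2 = -\delta z_2 + z_1$ with
output $\max\{0, k\theta z_2 - \xi z_1\}$; the equivalence with the
transfer function is a *test* (Simpson-rule convolution against the
kernels $t e^{-\delta t}$ and $e^{-\delta t}$), not an implementation
path. One transient subtlety is worth recording: with repressing sensing
— the wiring used in the toggle — the drive *falls* when the target
rises, and it is the falling drive that produces a positive derivative
response. Fed directly with a *rising* ramp at $r = 1$, the linear
response settles at $-k\theta/\delta^3 < 0$ and the clip holds the output
at zero; a falling ramp of slope $-s$ yields the steady output
$\xi s/\delta^2$. The tests assert both.

### Feedback architecture labels

A controller that senses the species it actuates is labelled *negative
feedback* (its own action feeds back into its drive); sensing the opposing
species is *positive feedback*. This architectural convention covers both
actuation modes: the additive toggle controller sensing its target, and
the degradation-based mutual-activation controller sensing its target,
are both negative-feedback designs.

## Equilibrium analysis

Controlled models have 5 or 8 species, but every auxiliary species is
driven only by $(y_1, y_2)$, so at a fixed point the controller sits
exactly at its quasi-steady state (QSS) given the endogenous pair. All
equilibrium work therefore happens on the reduced 2-D map with
`controller_qss()` eliminated states; solutions are lifted back to the
full state (the lift is exact at equilibria) and classified from the
full-system Jacobian (central differences, relative step $10^{-6}$).
Nullclines of controlled systems use the same QSS elimination, the
standard convention for phase-plane plots of such circuits.

`find_equilibria()` seeds a damped Newton iteration from two sources:
local minima of the reduced-map residual on a $60\times 60$ lattice, and
sign changes of $\dot y_1$ along the bracketed branches of the
$\dot y_2 = 0$ nullcline (400 columns). The second source matters: close
to a saddle-node bifurcation a stable/saddle pair sits a fraction of a
lattice cell apart and lattice seeding alone merges it. The unbalanced
toggle at production ratio 1.9 (varying $\alpha_2$) is exactly such a
case — a genuine stable pair separated by $\approx 0.17$ µM that a
coarse scan misses; exact counting keeps the network bistable out to
ratio 1.9 on the 0.1 grid (and to 1.3 when the ratio is realised through
$\alpha_1$). Roots are polished to a residual below $10^{-9}$,
deduplicated at $10^{-4}$ µM, and labelled stable / saddle / unstable
with an eigenvalue real-part threshold of $10^{-6}$ (closer to zero is
reported as "marginal" and excluded from stability counts). The search
box is $[0, 1.5 \cdot \max(\text{production})/\delta]^2$, which bounds
every nullcline with room for the additive control terms. An independent
brute-force oracle (connected components of lattice cells where both
reduced components change sign, $400 \times 400$) checks the census in
the test suite.

### Equilibrium alteration conventions

Two measures of how far the controller (or a parameter change) moves a
matched stable equilibrium are reported side by side:

* **dominant-species alteration** — $100\,|y^{new}_d - y^{ref}_d| /
  y^{ref}_d$ on the species that is high at that equilibrium; the natural
  per-branch reading of equilibrium-value plots;
* **point alteration** — $100\,\lVert y^{new} - y^{ref}\rVert /
  \lVert y^{ref}\rVert$, the relative Euclidean shift of the whole
  equilibrium point.

They differ materially when the *low* species moves: over the
adaptive-metric band $r \in [0.9, 1.1]$ (gain 1, $\gamma = 100$) the
dominant-species measure peaks near 4% while the point measure peaks
near 9% at the $r = 0.9$ edge, because the low-$y_1$ branch gains
absolute $y_1$. The scan summaries expose both
(`summary$max_dominant_alteration`, `summary$max_point_alteration`); the
acceptance script reports the point convention for the metric scan.

## Stochastic simulation and the fate assay

`reactions()` maps every rate term to one reaction; the summed drift
(stoichiometry × propensity) reproduces the ODE right-hand side
identically, which is asserted to $10^{-12}$ on random states. SSA is
Gillespie's direct method in C++ over these tables, using R's RNG so a
seed pins the trajectory bit-for-bit. Counts convert to concentrations
through the system size $\Omega$ (molecules per µM): zeroth-order
propensities scale by $\Omega$, second-order ones by $1/\Omega$, and
Hill/Michaelis terms evaluate at $x/\Omega$.

The fate protocol is the study protocol: ensembles start at the zero
state, run to a fixed horizon $t = 200$ h, and each terminal state is
assigned to the nearest stable attractor (Euclidean distance on the
endogenous species, terminal counts rescaled by $1/\Omega$ first). If the
two nearest attractors are within 5% relative distance of each other the
run is reported as *unresolved* rather than force-assigned. Endpoint
histograms use 8 equal bins on $[0, \max]$; the range is a package choice
(only the bin count is prescribed by the protocol).

### What the generator emulates — and what it does not

The SSA ensembles emulate *intrinsic* molecular noise: finite-copy-number
fluctuations of the very reactions in the model, the mechanism by which a
cell at a symmetric unstable state commits to a fate. They do not emulate
extrinsic parameter variability between cells, transcriptional bursting,
cell growth and division, or spatial effects — so passing tests show the
controller biases intrinsic-noise-driven decisions, not that it would
dominate all noise sources in a real population.

One consequence deserves emphasis, because the study protocol leaves the
system size unstated: **the fate bias depends strongly on $\Omega$.** At
$\Omega = 1$ (concentrations read directly as molecule counts — the
package default, and the plainest reading of the protocol) the nominal
negative-feedback ensemble reaches a Y1-high fraction of only ~55%:
single-molecule noise largely drowns the deterministic bias. The
acceptance suite runs at this prescribed $\Omega = 1$ and reports what it
measures. At $\Omega = 5$–$10$ the same design yields ~75–90%,
bracketing the 80/20 rule of thumb for this architecture; the bias is a
deterministic property that noise masks, not creates. For the same
reason two property checks run at $\Omega = 10$, where they are
statistically resolvable at affordable ensemble sizes: the ordering of
fate bias across sequestration rates, and the <5% unresolved-rate check
for the *uncontrolled* toggle (at $\Omega = 1$ its terminal distribution
leaves ~10% of runs on discrete diagonal states such as $(1,1)$, which
the tie rule rightly refuses to classify). The gain-monotonicity of the
bias and the controlled-toggle unresolved rate are asserted at
$\Omega = 1$.

## Problem sizes and tolerances

ODE integration is `deSolve::ode` (lsoda) at `rtol = 1e-8`,
`atol = 1e-10` — tight because bistable basin boundaries amplify
integration error — with 2000-point output grids (reduced in tests where
only terminal states matter). The test suite uses ensembles of 200–1000
runs and 60-point lattices; the acceptance script uses the full study
protocol (1000 trajectories, $t = 200$ h, ratio grids at step 0.1, metric
grid at step 0.01) and completes in about two minutes on one CPU.
Ensemble seeds derive per-run from the master seed by integer hashing, so
any subset of an ensemble is reproducible in isolation.

## Design decisions

* $K_{deg}$, the Michaelis constant of the degradation actuation,
  defaults to the Hill constant $K$ but is an independent field — the
  rate laws do not force the two to coincide.
* Double controllers mirror the first controller's wiring onto the other
  species and share all production/sequestration rates; only the gains
  $\beta, \beta'$ differ, and scans tie $\beta' = \beta$ unless set
  explicitly.
* The adaptive metric is swept through $\xi$ alone: $\delta$ also enters
  the endogenous network, and $k, \theta$ rescale the output magnitude,
  so $\xi$ isolates the IFFL imbalance.
* The tristable network's mixed design keeps each controller's native
  sensing: the additive controller on $Y_1$ senses through the repressing
  Hill (as in the controlled toggle), the degrading controller on $Y_2$
  senses its target through the activating Hill (as in the controlled
  mutual activation).
* Species order is fixed at $(Y_1, Y_2, X, U_1, U_2, X', U_1', U_2')$
  with absent species omitted; $m = 0$ is rejected rather than
  reinterpreted.
* Exogenous-input production terms (the isolated controller's drive) have
  no exact SSA realization and `reactions()` refuses them rather than
  discretising a time-varying propensity.

## Known limitations

No tau-leaping or hybrid acceleration (exact SSA only); no SBML/Antimony
exchange; no pseudo-arclength continuation — saddle-node bifurcations
appear as count changes on parameter grids, which is sufficient for the
0.1-step reporting resolution but does not locate folds to higher
precision. Nullclines of controlled systems are defined under controller
QSS; away from equilibria the full dynamics can cross these curves.
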