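---
title: "Screening gene-network designs for robust bistable switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene-network designs for robust bistable switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchgrade)
```

## The problem

A bistable switch turns its output on when an input signal rises past one
threshold and off only when the signal falls below a lower one.  This
memory-like behaviour — hysteresis — underlies most synthetic toggle
circuits, and a central design question is which small network topologies
produce it over *large* regions of kinetic-parameter space rather than at a
carefully tuned point.  `switchgrade` answers that question combinatorially:
it decomposes the parameter space of a small regulatory network into
finitely many regions, computes the exact qualitative dynamics on each, and
scores designs by the fraction of input sweeps that run through an
off / bistable / on sequence.

## The switching model

A network is a signed digraph on nodes $x_0, \dots, x_{N-1}$ (by convention
$x_0$ receives the external signal $s$ and $x_2$ reports the output).  Each
node decays at rate $\gamma_n$, and each edge $m \to n$ carries a low
production rate $\ell_{n,m}$, an increment $\delta_{n,m}$ (high rate
$\ell_{n,m}+\delta_{n,m}$), and a threshold $\theta_{n,m}$ on $x_m$.  The
interaction algebra is fixed: activating inputs are summed, and each
repressing input multiplies the sum by its own switching factor.  A node
with no in-edges produces a constant $\beta_n$.  Away from thresholds,
$\dot x_n = -\gamma_n x_n + \Lambda_n(x)$ with $\Lambda_n$ piecewise
constant, so all qualitative behaviour is decided by finitely many
comparisons between *production values* (one per input state) and *scaled
thresholds* $\gamma_n\theta_{k,n}$.

## Factor graphs and realizability

For one node, a parameter region is described by

* a **threshold order** — which of the node's out-thresholds is smallest,
  next, and so on (one *class* per permutation), and
* a **binarization chain** $B_1 \supseteq B_2 \supseteq \dots \supseteq B_k$
  — for each ordered threshold, the set of input states whose production
  value exceeds it.

Chains must be nested and each $B_i$ upward-closed in the polarity-adjusted
order on input states (raising an activator input never decreases
production; raising a repressor input never increases it).  Not every such
chain is *realizable* by strictly positive parameters, so each candidate is
submitted to a feasibility decision:

* **pure-sum nodes** (all activators): the constraints are linear in the
  base rate, the increments and the scaled thresholds.  We maximize the
  minimum slack subject to unit box constraints (the system is homogeneous,
  so the box only fixes scale) and accept when the optimum exceeds the
  strictness margin `eps` (default `1e-6`).  The solve uses a dual-method
  quadratic program with a tiny ridge (`1e-6`), which is numerically robust
  and distorts the linear optimum by far less than the acceptance margin.
* **pure-product nodes** (all repressors): the same construction after a
  log transform, where products become sums.
* **mixed nodes**: the sum-times-product structure is not linearizable, so
  the minimum slack is maximized numerically (Nelder–Mead in log
  coordinates, 20 seeded starts, early exit once the slack is comfortable).
  A candidate that never reaches the margin is reported **undecided** and
  excluded (and counted in `n_undecided`); `include_undecided = TRUE` keeps
  such regions, without witnesses, for sensitivity checks.  Certified
  infeasibility is not available in the mixed case, which is why the count
  is reported rather than silently dropped.

Every accepted region stores a numeric **witness**, rescaled so that its
largest scaled threshold sits at $3.0$ — a convenient scale commensurate
with input signals of order one to four.  Witness correctness is asserted
by round-trip classification, and the enumeration is validated by a
partition oracle: random positive parameter draws must always classify onto
an enumerated region.

Adjacent regions differ in exactly one inequality: either one input state
moves across one threshold, or two neighbouring thresholds transpose while
carrying identical state sets.  The per-class factor sizes this enumeration
produces (3 for one-in/one-out, 6 monotone sets for two summed inputs, 707
chains for a three-input sum node with three thresholds, 756 for the mixed
two-activator/one-repressor shape) are what the screen's parameter-region
counts and maxima are built from.

## The parameter graph, essential regions, and signal paths

The full parameter graph is the Cartesian product of the per-node factor
graphs.  A node's region is **essential** when every threshold is crossed
by some input state and every in-edge moves some state across some
threshold — i.e. when every edge of the topology actually shapes the
dynamics.  Screening restricts the non-input nodes to their essential
combinations; the **perturbed** variant enlarges that set to its closed
one-edge neighborhood, modelling a single weakened interaction.  A node
with no in-edges has constant production, which can never cross a
threshold both ways, so such nodes admit no essential region and designs
relying on them are reported non-switching under the essential convention.

Rising input traces a monotone path through the input node's factor graph.
We order regions by **increasing production**: the minimal vertex has every
production value below every threshold (low input), the maximal vertex the
reverse.  This orientation is forced by the dynamics — an ascending sweep
must start where the output can rest low — and it makes the bundled
continuation example's parameter point (whose node-0 values all sit below
its thresholds at $s=0$) classify onto the minimal vertex, as it should.
Paths must change dynamics at least twice, hence contain at least three
vertices; **full** paths run minimal-to-maximal.  Scoring fixes one
threshold-order class (default: thresholds ordered as the out-targets are
listed); classes are symmetric for the worked designs, and cross-class
transposition edges are order-incomparable, so monotone paths cannot use
them.

## Combinatorial dynamics

Thresholds slice phase space $(0,\infty)^N$ into rectangular top cells.  On
the wall between two cells the sign of $-\gamma_n\theta + \Lambda_n$
decides, for each side, whether the wall **absorbs** (flow exits through
it) or **repels**; these labels induce the state transition graph, and a
cell all of whose walls repel it is a stable state, labeled
$\mathrm{FP}(i_0,\dots,i_{N-1})$ by how many thresholds each coordinate
exceeds.  Outer boundaries (at $0$ and at infinity) always repel — decay
and positivity push inward.  The Morse graph condenses the STG to its
recurrent components ordered by reachability; its minimal nodes are the
attractors, and single-cell minimal nodes are exactly the FP cells.

Two extensions keep every topology in scope.  A node with no out-edges
receives a placeholder threshold (reported as `t[.][n]`) so the complex
stays well-formed; it influences nothing downstream.  A **repressing
self-edge** can make a wall absorbing from both sides, so its threshold is
doubled into two walls with a thin cell between them: the outer wall sides
are labeled classically, each inner side takes the opposite label, and
walls between thin cells inherit labels from their classical neighbours
(consistent by construction).  For reporting, the thin cell counts as lying
*below* its threshold — the self-repression equilibrium of a one-node
circuit is reported as $\mathrm{FP}(0)$, its coordinate having crossed no
threshold completely — and forgetting the doubled index collapses the
refined complex cell-by-cell onto the unrefined one.

## Hysteresis scores

A path with fixed non-input coordinates $(v_1, v_2)$ exhibits **ascending
hysteresis** when its first vertex has a stable state with output
coordinate $0$, its last vertex one with output coordinate $> 0$, and some
strictly interior vertex has both at once.  The `strict_ends` variant
additionally demands monostable endpoints, as switch schematics usually
draw them; both variants agree on all the worked designs.  Descending
hysteresis mirrors the endpoint conditions.  The **hysteresis score** is
the percentage of (path, parameter-vertex) pairs satisfying the predicate;
the **perturbed score** replaces the essential set by its one-edge
neighborhood, and **robustness** is their ratio, with designs at or below
$0.5$ called fragile.  Path counts explode combinatorially, so scores are
computed exactly by dynamic programming over the class's cover DAG with
endpoint flags and an inclusion–exclusion step for the bistable-interior
condition; enumeration is only used below a configurable cap, and the DP is
tested against brute-force enumeration on small graphs.

## Hill-model validation

Replacing each step by a Hill function with shared exponent $n$
(increasing $\ell + \delta x^n/(\theta^n + x^n)$, decreasing
$\ell + \delta \theta^n/(\theta^n + x^n)$) gives a smooth ODE whose
behaviour approaches the combinatorial model as $n$ grows.  A sampled
parameter point is declared hysteretic by the continuation procedure: draw
ten initial guesses in the sub-threshold box (output above the top
threshold for descending mode), solve for equilibria at $s = 0$, keep those
whose output lies in the required band, and continue each in $s$ by
pseudo-arclength to $s = 4$.  Saddle-node folds are flagged by sign changes
of $\det J$ and refined by bisection to $|\Delta s| < 10^{-8}$; a curve
counts as hysteretic when it reaches the end of the range with an even
number of folds, at least two, all jumping the output in the mode's
direction.  We require *at least two* folds because a fold-free monotone
branch satisfies the even-count condition vacuously while exhibiting no
switching.  Continuation defaults: initial step $0.01$, adaptive in
$[10^{-5}, 0.1]$, Newton corrector tolerance $10^{-10}$, $10^5$-step
budget; incomplete curves are never hysteretic.  Hill evaluations go
through the logistic of $n(\log x - \log\theta)$, so exponents in the
hundreds neither overflow nor lose the derivative.

Numeric parameters for a region are drawn by jittering its witness
log-normally (scale $0.25$) and rejecting draws that leave the region
(membership is re-checked against the exact inequalities, capped at
$10^4$ rejections), with $\gamma_n = 1$.  This guarantees membership but
deliberately makes no uniformity claim over the unbounded regions — no
sampling scheme on an unbounded open cone is canonical.  Consequently
Monte-Carlo Hill percentages are *sampler-dependent*: the package
reproduces their ordering (frequencies fall as the exponent drops from 30
to 4, and the combinatorially top-ranked design stays ahead), not any
particular percentage.  The stiff-limit check is sharper: at
$n = 100$, multi-start Newton recovers the Morse-graph attractor counts
(1 / 2 / 1 along the three-cycle's path) in at least 90% of sampled
essential-region points.

## What the built-in fixtures do and do not show

All test inputs are generated programmatically: the fixture networks are
reconstructed from their defining algebra, and parameter sets are sampled
from enumerated regions.  The generator emulates the study conditions —
essential-region operation, unit decay rates, thresholds of order one —
and not features of any laboratory system: no measurement noise, no
stochastic gene expression, no unmodelled intermediate species.  Passing
tests therefore certify the combinatorial claims exactly and the ODE-level
claims for the stated Hill family and sampler, and nothing beyond that.

## Numerical and scale choices

* Feasibility margin `eps = 1e-6` (relative); QP ridge `1e-6` with
  fallbacks `1e-4`, `1e-2`; mixed-case slack threshold `1e-5`, 20 seeded
  starts.
* Witnesses normalized to a maximum scaled threshold of $3.0$; signal range
  $[0, 4]$.
* Test problem sizes are the package's own validation choices: $10^4$
  partition-oracle draws per node shape, all 27 parameter vertices of the
  three-cycle plus $10^3$ seeded samples for each larger fixture's Morse
  checks, 50 stiff-limit agreement points, and 200 Monte-Carlo samples per
  Hill exponent.
* All randomness is seed-controlled; sampling and Monte-Carlo runs are
  bitwise reproducible for a fixed seed.

## Known limitations

* Factor graphs are enumerated for nodes with at most four in- and four
  out-edges — ample for three-node screens, not for large networks.
* Mixed-logic regions can come back *undecided*; they are excluded by
  default and surfaced in `n_undecided` rather than resolved exactly.
* Partial-path percentages depend on conventions (which vertices of the
  non-input nodes count as essential, and how short paths are counted)
  that differ between implementations; full-path scores and the
  worked small-network scores are convention-free and are the ones this
  package asserts.
* Morse nodes beyond fixed points (cyclic attractors) are detected but not
  classified further, and the Hill layer detects folds only — no Hopf
  analysis.
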