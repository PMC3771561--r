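---
title: "Circuit-breaking analysis of regulatory-network fixed points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit-breaking analysis of regulatory-network fixed points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbnet)
```

## The model class

`cbnet` analyses autonomous ODE systems $\dot x = f(x)$, $x \in
\mathbb{R}^n_{\ge 0}$, $f \in C^1$, of the kind used for gene-regulatory
and small metabolic networks: every rate is an arithmetic expression in
the state variables and parameters (operators `+ - * / ^`, `exp`), which
covers mass action, Michaelis–Menten and Hill kinetics. Two assumptions
matter:

* **Bounded trajectories.** Every variable declares a closed interval
  $[lo_i, hi_i]$, $lo_i \ge 0$, interpreted as a trapping region: a box
  trajectories eventually enter. Biologically this is the statement that
  synthesis saturates and degradation is at least linear; mathematically
  it guarantees at least one fixed point and gives every root search a
  finite domain. All fixed points *inside the box* are found; the package
  makes no claims outside it. For models in decay form
  ($f_i = r_i(x_{-i}) - d_i x_i$ with constant $d_i > 0$),
  `propose_bounds()` iterates $hi_i \leftarrow \max r_i / d_i$ to a
  positively invariant box.
* **Differentiability.** All Jacobians are symbolic (`stats::D` on the
  expression tree); a central finite-difference route (`jacobian_fd`) is
  kept as an independent cross-check and agrees to $10^{-4}$ relative on
  all built-ins.

## From equations to graph

The interaction graph has an edge $j \to i$ whenever $\partial f_i /
\partial x_j$ is not identically zero. Presence and sign are decided by
evaluating the symbolic partials on a Halton sample of the box (64 points
by default, start offset = seed, hence reproducible); an edge is signed
`+`/`-` only if the sampled partial never changes sign. The numeric route
rather than a purely structural one makes the graph parameter-aware: a
synthesis term with a zero prefactor contributes no edge, which is exactly
what the downstream theory needs.

**Self-edge convention.** Linear decay gives every variable a negative
self-derivative that generates no feedback, so the strict reading
"self-edge iff the self-partial is positive somewhere" is available as
`self_edges = "strict"`. It is not the default, because nonlinear
*negative* self-regulation (the tryptophan variable combines enzyme
inhibition with saturable uptake) genuinely creates a length-1 feedback
circuit that the circuit cover must break. The default therefore adds a
self-edge whenever the self-derivative is state-dependent (or a positive
constant); with it, the circuit sets of all three case-study models come
out with the expected members, including the `{x4}` self-circuit of the
tryptophan network. Both conventions are exposed on the command line
(`--self-edge-mode`).

## The algorithm

1. **SCC condensation** (igraph). Components are numbered along a
   deterministic topological order of the condensation (Kahn's algorithm,
   ties by smallest member vertex). Fixed points are assembled SCC by SCC;
   upstream coordinates enter as constant input $u$, and multiple upstream
   fixed points multiply out as a Cartesian product.
2. **Elementary circuits** per SCC (Johnson's algorithm, implemented here;
   self-loops are length-1 circuits), capped at 10,000 with a `truncated`
   flag.
3. **Minimal circuit cover** $\tilde V$: an exact branch-and-bound hitting
   set when at most 20 candidate vertices are involved (biological SCCs
   are small), greedy max-coverage beyond, flagged non-exact. Among equal
   minima the vertex occurring in the most circuits is preferred, then the
   smallest index. When several minimal covers exist (the repressilator is
   fully symmetric) the choice moves the $\kappa$ axis but not the zero
   *set*, which is all that downstream results depend on.
4. **Break and solve.** Clamping $\tilde V = \kappa$ leaves an acyclic
   subgraph; its variables are solved in topological order as scalar root
   problems. Decay-form variables are solved in closed form
   ($x_p = r_p/d_p$, one expression evaluation, vectorizable over a whole
   $\kappa$ grid); all others by dense sign-change bracketing (200
   subintervals of the variable's bound interval) refined by Brent's
   method. Multiple roots spawn solution branches (capped at 16).
5. **Close circuits.** Cover vertices are released innermost-first; each
   release solves the partial characteristic $f_i(x_i, \kappa, F(\kappa)) =
   0$ by the same bracketing scheme, with the deeper releases re-solved at
   every trial point. The final scalar function $c(\kappa_1)$ is tabulated
   on a grid of the leading variable's interval (601 points by default)
   and also kept as a closure for pointwise re-evaluation.
6. **Zeros, back-substitution, polish.** Sign changes are bisected to the
   $\kappa$ resolution ($10^{-13}$ relative) — deliberately not stopped on
   a $|c|$ threshold, because characteristics can span many orders of
   magnitude across the grid. Assembled full states are polished by damped
   Newton on $f(x) = 0$ with the analytic Jacobian, validated against the
   bounds and a residual tolerance of $10^{-8}$, and deduplicated at
   $10^{-6}$ relative.

Grid cells where some variable has no root in its bounds become `NA` holes
in a branch rather than being interpolated; branches across grid points
are matched by nearest-neighbour continuation of the downstream state.

### Degenerate and awkward cases

* A single circuit-free vertex has no circuit to break; its
  "characteristic" is defined as $f_1$ restricted to the line, which keeps
  the zero/fixed-point correspondence trivially intact.
* A rate may still *textually* contain a variable whose edge vanished
  (e.g. a zero prefactor). Unset upstream slots are filled with box
  midpoints for evaluation only — sound because a variable without an edge
  into the expression is constant in it over the box.
* Tangencies: a sign-preserving local minimum of $|c|$ below
  $10^{-4}\cdot\max(1, \max|c|)$ is reported as a tangency candidate with
  zero slope — the saddle-node signature.

## Stability from the characteristic

The slope of the characteristic at a point of its graph equals
$\det J_f(x) \cdot \det^{-1} J_f^{V\setminus\{v_1\}}(x)$ — verified in the
test suite on randomized fully connected 3-vertex and structured 4-vertex
fixtures (both need two closing steps) at $10^{-5}$ relative against
central differences of the numerically constructed characteristic, and at
every zero of the built-in models.

For a **leading vertex graph** — one vertex on every circuit — the
subnetwork without $v_1$ is acyclic, its Jacobian determinant is the
product of the (negative) diagonal entries, so its sign is fixed at
$(-1)^{n-1}$; a positive characteristic slope at a zero then forces an
eigenvalue into the right half plane. `lvg_instability_test` returns
`unstable_by_slope` only in that certified situation, `not_applicable`
for non-LVG covers, and `inconclusive` for non-positive slopes. A
negative slope must never be read as stability: the tryptophan model at
$\mu = 0.1$ has a strictly decreasing characteristic and an unstable fixed
point, and the repressilator's characteristic is independent of the
time-scale parameter $\beta$ although its spectrum is not. Marginal
spectra ($|\mathrm{Re}\,\lambda| \le 10^{-8}\|J\|$) are classified
`marginal`, never stable or unstable.

A note on the repressilator at the parameter set used throughout
($\alpha = 290$, $\alpha_0 = 10$, $n = 2$): the repression slope at the
symmetric point $m_i = p_i = 12$ has magnitude $|r'(12)| = 0.331 < 1$, and
the characteristic polynomial $(1+\lambda)^3(\beta+\lambda)^3 =
\beta^3 r'^3$ then keeps the whole spectrum in the left half plane for
*every* $\beta$ (the leading real part tends to $0^-$ as $\beta \to 0$).
The package's eigenvalue continuation consequently reports no stability
change over a $\beta$ sweep at these values; destabilising the ring
requires stronger repression cooperativity. The instructive content —
a $\beta$-blind characteristic with a $\beta$-dependent spectrum — is
unaffected and is what the test suite asserts.

## Bifurcation scans

`sweep_parameter` reruns the full pipeline over a parameter grid, with
optional linkages (`"eN=eM"`) evaluated as expressions of the swept
parameter, and matches fixed points into branches by nearest relative
distance (jump threshold 0.25). Fold candidates are bracketed by changes
in the fixed-point *count* and bisected to $10^{-4}$ relative (depth cap
40); the tangent state is read off the characteristic on the bracket side
where it still only touches the axis, falling back to the flattest zero
just past the fold, where the new pair may be closer together than the
grid resolution. Hopf candidates are sign changes of the leading
eigenvalue real part with nonzero imaginary part, refined by bisection
with Newton continuation of the fixed point; across a Hopf point the
number of characteristic zeros never changes, which is why eigenvalues —
not the characteristic — must be consulted.

## Synthetic model generators

Two generators make every stage testable without external data:

* `methods_fixture()` builds the two reference topologies used to verify
  the slope identity (fully connected 3-vertex; 4-vertex with dependence
  structure `f1(x1,x3), f2(x1,x2,x4), f3(x1,x3,x4), f4(x2,x4)`). The
  identity must hold for *any* smooth rates, so the rates are randomized
  sums of activating/inhibiting Hill terms (coefficients in [0.5, 2],
  thresholds in [0.3, 1.5], Hill exponent 2) minus linear decay (rate in
  [0.8, 1.5]), fixed by seed.
* `random_lvg_model()` emits strongly connected models in which vertex 1
  provably lies on every circuit (disjoint directed paths, each closed
  through vertex 1), with the same Hill-term vocabulary. Same seed, same
  model file, byte for byte.

What these generators emulate is the *structure* relevant to the theory —
feedback topology, saturating kinetics, linear decay, a bounded box. What
they do not emulate: stochasticity, delays, conservation laws,
non-hyperbolic degeneracies, or rate laws outside the Hill/decay
vocabulary. Tests passing on them demonstrate correctness of the graph
reduction and the analytical identities, not fidelity to any particular
biological data set.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_scan` | 200 | bracketing subintervals per scalar root search |
| `tol_root` | 1e-12 | absolute refinement tolerance of inner roots |
| `tol_zero` | 1e-8 | acceptance residual for characteristic zeros |
| `tol_tangent` | 1e-4 | relative $|c|$ threshold for tangency candidates |
| `tol_fp` | 1e-8 | max residual of a reported fixed point |
| `tol_dedup` | 1e-6 | relative distance below which points merge |
| `max_branches` | 16 | cap on simultaneous solution branches |
| `n_grid` | 601 | characteristic grid points per leading variable |
| `eps_edge` | 1e-9 | sampled-partial threshold for edge presence |
| `tol_slope` | 1e-6 | slope below which no instability verdict is issued |

All are dimensionless except where they scale with the state (noted
above). The default problem sizes — 601-point characteristic grids,
7–21-point parameter sweeps before bisection, 100–200 Newton multistarts
in the cross-check oracles — were chosen so that each case study is a
sub-second to few-second computation at full accuracy; they are
user-overridable through `cba_control()`.

## Known limitations

* The instability certificate applies only to leading vertex graphs; for
  covers with $m \ge 2$ the package deliberately returns
  `not_applicable` rather than extrapolating.
* Characteristic branches are tracked by nearest-neighbour continuation;
  pathological branch crossings within a single grid cell can be
  mis-associated (tighten the grid in that case).
* Fixed points outside the declared bounds are out of scope by design, as
  are limit cycles, basins of attraction, and symbolic solution of the
  implicit closing equations.
* Fold refinement is based on the fixed-point count and assumes the pair
  birth/death is resolvable by the sweep; folds of branches that never
  enter the box are invisible.
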