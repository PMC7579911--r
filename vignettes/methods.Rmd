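---
title: "Methods: multi-objective optimal control of enzyme activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective optimal control of enzyme activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem class

dynenz computes time-varying enzyme-activation strategies for kinetic models
of metabolic pathways. The mathematical object is a nonlinear optimal control
problem (OCP): a state vector $x(t)$ of metabolite (and possibly enzyme)
concentrations obeys $\dot x = f(x, u, p, t)$ from $x(t_0) = x_0$, the
controls $u(t)$ are enzyme concentrations or synthesis rates bounded by
$u^L \le u(t) \le u^U$, and the biology enters through inequality path
constraints $g(x, u, p) \le 0$ enforced over the whole horizon (total enzyme
capacity, critical metabolite levels for survival) and point constraints at
single times (e.g. a product target at the final time $t_f$, which may itself
be free and optimized). Each objective functional has a Mayer (endpoint) and/
or Lagrange (integral) term,
$J_i = \Phi_M^i[x(t_f), p] + \int_{t_0}^{t_f} \Phi_L^i[x, u, p]\,dt$,
with a per-objective min/max sense. With several conflicting objectives
(e.g. fast pathway transition vs. low intermediate burden; long survival vs.
low protein investment) the solution concept is the Pareto set of
non-dominated trade-offs.

## Canonical form

Every solver in the package works on a canonical reduction produced by
`prepare_problem()` (exposed as `augment_lagrange()` + `normalize_time()`):

* **Lagrange reduction.** Each integral term becomes a quadrature state
  $\dot q = \Phi_L$, $q(t_0) = 0$, and the objective becomes pure Mayer on
  $q(t_f)$. Objective values are identical for any trajectory; this is an
  exact reformulation, not an approximation.
* **Free final time.** A free $t_f$ is removed by rescaling time onto
  $\tau \in [0, 1]$: the vector field becomes $t_f \cdot f$ and $t_f$ joins
  the decision vector as a static parameter bounded by the user-supplied
  `tf_bounds`. An objective that is literally $t_f$ maps to that parameter.
  All free-time handling goes through this normalization; there is no
  variable-horizon shooting, so both transcriptions below stay uniform.
* **Senses.** Internally every scalarized solve is a minimization; maximize
  objectives are negated on entry and reported raw on exit.

Model expressions (right-hand sides, integrands, constraints) are strings in
a small arithmetic grammar (`+ - * / ^`, parentheses, `exp log sqrt sin cos
tan`, symbol references). They are parsed once, validated against the symbol
table, and differentiated symbolically with `stats::D()` — the same
expressions drive the simulator, the analytic Jacobians and the Hessian of
the Lagrangian, so there is no drift between what is integrated and what is
differentiated.

## Phase 1: control vector parameterization with hybrid global search

The sequential transcription (`transcribe_cvp()`) divides the horizon into
$\rho$ elements and approximates each control inside element $i$ by a
Lagrange polynomial of order $M_j \in \{1, 2\}$ (piecewise constant or
piecewise linear) in the normalized element time. The decision vector is the
coefficient vector $w$, optionally the element widths (variable-length
elements, useful when optimal switching times must be located precisely),
and the free parameters such as $t_f$. Each evaluation of the reduced NLP
performs exactly one IVP solve (deSolve's `lsoda`, stiff-capable, adaptive;
default `rtol = atol = 1e-7`); the cost and all constraints share that
solve. Path constraints are sampled at element boundaries and midpoints; a
denser post-hoc check is available through `check_constraints()` on the
reported 201-point trajectory. Integration failures at absurd decision
vectors are converted into a large penalized cost so the stochastic search
can continue; a failure rate above 50% aborts with a diagnostic.

**Event-horizon reformulation.** Two free-final-time problem families admit
an exact reformulation that removes both the final-time variable and the
endpoint equality from the reduced NLP (`transcribe_cvp_event()`, selected
automatically when the structure fits): *transition-time* problems, where a
monotone endpoint expression must reach a target (the realized $t_f$ is the
first crossing, located by integrating with root detection via `lsodar`, and
any Mayer objective is evaluated there), and *survival-time* problems, where
$t_f$ is the first violation of a state path constraint and the objective is
to maximize $t_f$ itself. Controls are parameterized in real time with free
element widths; the target/survival constraints hold on the realized horizon
by construction. This matters in practice: on minimum-transition-time
pathway problems the generic transcription's landscape (a penalized endpoint
equality coupled to the $t_f$ variable) scattered the global phase across
local basins several percent apart, while the event form converges to the
same basin from every seed.

The reduced NLP is optimized by `scatter_search()`, a scatter-search
metaheuristic: a seeded space-filling diverse set enriched with corner
samples and — when the parameterization exposes its control-element
structure — with one-active-control-per-element sparse corners (enumerated
outright when there are at most 300 patterns). These sparse corners are the
extreme points of shared-capacity feasible sets and correspond exactly to
the sequential bang-bang "wave" policies of capacity-limited pathways; the
interior-sampling search locates them very slowly on its own. A small
reference set is maintained by quality and diversity, recombined pairwise
by line recombination beyond the parents' segment with a go-beyond
intensification step, and periodically polished by the package's
augmented-Lagrangian solver (forward-difference gradients in this phase,
step `1e-4`: the step must clear the ~`1e-7` relative integration noise of
the embedded IVP solve, and smaller steps produce half-noise gradients that
stall the line search). Constraint handling is feasibility-first: a feasible
point always beats an infeasible one, and infeasible points are ranked by a
quadratic penalty. All randomness flows from one generator seeded per call,
so a seed plus settings reproduces a run exactly.

The optimization feasibility tolerance in this phase is `1e-5`, two orders
of magnitude looser than the integration tolerance: tighter demands make the
optimizer chase integration noise, which manifests as non-smoothness of the
embedded cost. The augmented-Lagrangian polish starts from a gentle penalty
(`rho0 = 2`) on cold starts — a heavy initial penalty turns the
all-controls-off stationary point of the endpoint-shortfall penalty into an
attractor (a dead pathway has zero target gradient) — and from a stiff one
(`rho0 = 200`) on warm-started continuation solves, which are already near
their constraint boundary and need penalty curvature to ride it.

## Phase 2: trapezoidal collocation with analytic derivatives

The simultaneous transcription (`transcribe_trapezoidal()`) discretizes both
states and controls on a mesh: decision variables are all node states, all
node controls and the free parameters; the ODE becomes the trapezoidal
defect constraints
$x_{i+1} - x_i - \tfrac{h_i}{2}(f_i + f_{i+1}) = 0$
(the two-stage Runge–Kutta scheme with weights $\beta = (\frac12,
\frac12)$); path constraints are imposed at every node and controls
interpolate linearly between nodes, consistent with the transcription order.
`assemble_derivatives()` generates the exact cost gradient, the sparse
constraint Jacobian with a precomputed sparsity pattern, and the sparse
Hessian of the Lagrangian, all from the symbolic partials of the model
expressions. Analytic derivatives are not an optimization nicety here: the
defect constraints couple thousands of variables, and finite differences at
that scale are both slow and noisy.

The NLP is solved in two stages by `solve_collocation()`:

1. a bound-constrained **augmented Lagrangian** (`local_solve()`): the
   classical first-order multiplier updates with L-BFGS-B inner solves,
   using the analytic gradient of the Lagrangian assembled without forming
   sparse matrices (a precomputed scatter pattern turns $J^\top w$ into
   cumulative sums);
2. a **Newton active-set refinement** (`kkt_refine()`): with the active
   inequalities and bounds pinned, each step solves the sparse SQP system
   $\begin{pmatrix} H & J^\top \\ J & 0\end{pmatrix}
   \begin{pmatrix}\Delta y \\ \lambda^+\end{pmatrix} =
   \begin{pmatrix}-\nabla F \\ -c\end{pmatrix}$
   built from the analytic Hessian; working-set members whose multipliers
   come out with the wrong sign are released. Near a regular solution this
   sharpens both the iterate and the multipliers to near machine precision —
   on the linear-quadratic fixture the refined solution and its multipliers
   are exact to ~1e-14.

Because the collocation constraints are exact algebra (no embedded
integration), the phase-2 feasibility tolerance defaults to `1e-8`, far
tighter than phase 1. Warm starting (`warm_start_from()`) interpolates the
phase-1 trajectory onto the mesh; in the two-phase strategy the augmented
Lagrangian is started with a large initial penalty (`rho0 = 1e4`) so the
refinement stays glued to the warm-started basin instead of tunnelling
through infeasible space to a different local solution — min-time problems
of this class have many KKT points and phase 2 is meant to refine, not to
re-explore.

## Adjoint (costate) estimates and constraint sensitivities

Under the Lagrangian convention $F + \nu^\top c$ with the defect sign above,
the defect multipliers of the converged NLP estimate $-\lambda(t)$ of the
Hamiltonian convention $H = L + \lambda^\top f$; `extract_adjoints()`
averages the two interval multipliers adjacent to each node and flips the
sign, which on the linear-quadratic oracle ($\lambda^* \equiv -2$) is exact
at any mesh. Path-constraint node multipliers scale to the continuous
multiplier density $\mu(t)$ by the trapezoidal quadrature weights
($h_1/2$, $(h_{i-1}+h_i)/2$, $h_\rho/2$); their raw sum approximates
$\int \mu\,dt$ and is reported by `sensitivity_report()` as a per-constraint
scalar sensitivity — the optimal-control analogue of a shadow price:
the first-order change of the optimal cost per unit of constraint
relaxation. The report ranks path constraints by that integral, point
constraints by their scalar multiplier, and control bounds by the summed
bound multipliers recovered from the stationarity residual.

## The Pareto driver

`epsilon_constraint_sweep()` traces bi-objective fronts by the
epsilon-constraint method: the two single-objective anchors are solved
first; then, for a uniform grid of $\varepsilon$ values spanning the
secondary objective between its two anchor values, the primary objective is
minimized subject to the secondary being at least as good as $\varepsilon$
(direction follows the declared sense). Because the canonical form makes
every objective an endpoint expression, the $\varepsilon$ constraint is just
one more point constraint at $t_f$. Each subproblem is warm-started from its
$\varepsilon$-neighbor by default (`warm_start = FALSE` forces independent
cold starts, which is what a multiplicity study wants). Infeasible
subproblems are dropped with a warning rather than aborting the sweep.
Fronts are dominance-filtered (`filter_dominated()`, stable order, weak
dominance) and sorted; `knee_point()` returns the point of maximal
perpendicular distance to the anchor chord after min–max normalization of
both objectives, which is invariant to objective rescaling.

The default grid has 11 points anchors included; the sweep grid is uniform
in the secondary objective because the reference studies do not report their
grids, and a uniform grid makes the monotonicity properties of the front
easy to audit. The sweep runs from the secondary anchor outward, relaxing
$\varepsilon$ step by step: every warm start is then feasible for its
subproblem and each solve is a descent to the new constraint boundary
(restoring feasibility from the violated side is much harder for the local
phase). The neighbor's augmented-Lagrangian multipliers are carried along as
warm starts — the shadow price of the $\varepsilon$ constraint changes
slowly along the front. With the two-phase strategy the deterministic
phase-1 sweep can be reused (`phase1_front`): each stored phase-1 point is
refined by the collocation phase directly instead of recomputing an
identical CVP sweep.

## Benchmarks and their documented defaults

Three pathway case studies ship as factories, parameter-complete and
serializable to YAML/JSON (`write_ocp()` / `load_ocp()`):

* **`build_lpn3b()`** — three-step linear pathway, mass-action kinetics
  $v_i = k_i S_i e_i$ with the substrate held constant, capacity
  $\sum e_i \le E_T = 1$, product target $S_4(t_f) = 0.9$, objectives
  $[t_f, \int (S_2 + S_3)\,dt]$, both minimized, free $t_f$.
  `build_linear_pathway(n)` generalizes the same structure to $n$ steps
  ($n = 3$ reproduces the benchmark field-by-field; $n = 1$ has the
  closed-form minimum time $t_f = 0.9$ used in tests).
* **`build_sc()`** — yeast central carbon metabolism during diauxic shift:
  8 states, 6 enzyme controls, uncontrolled drains $u_7 = 3\,ATP$ and
  $u_8 = 0.1\,NADH$, capacity $E_T = 11.5$, survival constraints
  $NADH \ge NADH_c$, $ATP \ge ATP_c$, objectives (both maximized)
  $[t_f, -\int \sum e_i\,dt]$. NADH+NAD and ATP+ADP are conserved moieties
  (paired stoichiometric rows sum to zero), which the tests assert under
  random admissible controls. The critical values default to
  $ATP_c = 0.3$, $NADH_c = 0.1$ — **placeholders**: the source model states
  the constraints but not the values, so every result involving them is
  conditional on these inputs. With these placeholders the cell can survive
  indefinitely on its large ethanol pool, so the survival anchor is limited
  by the $t_f$ search interval (default $[0.2, 8]$ h) rather than by
  substrate exhaustion; the cost/benefit front in the protein-investment
  direction is unaffected by that truncation.
* **`build_bsub()`** — B. subtilis central carbon metabolism under a
  substrate shift (scenarios G-M and M-G): 22 states including 13 enzymes
  with synthesis controls $a_i \in [0.0025, 0.125]$ and first-order decay
  $\beta = 0.25$, enzyme capacity $\sum_{i} E_i \le 6.5$, objectives
  $[-\int ATP\,dt, \int \sum E_i\,dt]$, fixed horizon. The final time
  defaults to $t_f = 30$ time units — a documented **placeholder**, since
  the source formulation does not print one. The printed initial state at
  the substrate shift is used verbatim; the pre-shift steady-state phase is
  out of scope.
* **`build_lq_toy()`** — the analytic linear-quadratic oracle
  ($\min \int u^2$, $\dot x = u$, $x(1) = 1$; $u^* = 1$, $J^* = 1$,
  $\lambda^* = -2$) used to validate the transcription, the solver and the
  adjoint extraction end to end.

Control bounds for the enzyme-concentration models default to $[0, E_T]$:
the sources bound only the total, but concentrations are non-negative and no
single enzyme can exceed the shared capacity. Free-time search intervals
(`tf_bounds`) are likewise documented package defaults, chosen wide enough
to contain the optimum without dominating the search space.

## Numerical choices, in one place

* Integration: `lsoda`, `rtol = atol = 1e-7`; reported trajectories on a
  uniform 201-point grid (plus element boundaries); `tcrit` caps the
  integrator at the final time.
* CVP phase: default 5 elements, piecewise-linear controls. The event
  transcription always carries free element widths (minimum width `1e-3` of
  the horizon; switching times are what it exists to locate); the generic
  transcription defaults to fixed elements so no width-sum equality burdens
  the search, with `variable_length = TRUE` available as an option. Initial
  coefficients at mid-bounds when no warm start is given. Feasibility
  tolerance `1e-5`.
* Collocation phase: default 100 uniform intervals; feasibility `1e-8`;
  augmented-Lagrangian start `rho0 = 100` cold / `1e4` warm-started;
  Newton refinement up to 12 steps, working-set release at multiplier sign
  violations beyond `1e-8`.
* Scatter search: reference set ~10, diverse set `min(10 n, 100)`, line
  recombination factor in $[-0.3, 1.3]$, penalty weight `1e4`, stagnation
  refresh of the worst half of the reference set.
* Degenerate inputs: element widths that do not sum to the horizon are
  rescaled for control construction (the equality constraint restores the
  sum at the solution); collocation guesses outside bounds are clipped with
  a warning; a colinear front returns its first interior point flagged
  "flat".
* Multiplicity ensembles compare members on normalized time $\tau \in
  [0,1]$ on a common 200-point grid, because free-$t_f$ members have
  different absolute horizons; the membership threshold (default 0.5%)
  applies to the scalarized cost of the solve that produced each member.

## What the tests do and do not show

The test suite validates every operation against independent oracles:
closed-form ODE solutions, hand-evaluated stoichiometry, brute-force
dominance filtering, finite-difference derivative checks, KKT systems solved
directly, and the linear-quadratic adjoint. Solver-level tests run at
deliberately reduced sizes (element counts around 5, meshes of 15–100
intervals, search budgets of a few thousand evaluations, fronts of 5–11
points) — sizes at which the pipeline's behavior is already representative
while a complete run of the suite stays comfortably within a desk session.
Passing them demonstrates correctness of the machinery and reproducibility
of the two-phase pipeline on the benchmark models at those sizes; it does
not certify global optimality on the nonconvex cases (min-time problems of
this class have many KKT points, and the package's own multiplicity tools
exist precisely to map that structure), and all quantitative SC results are
conditional on the placeholder critical values discussed above.

## Study sizes used by the package's own checks

The end-to-end checks in the test suite run the benchmarks at deliberately
compact sizes, chosen once as representative desk-scale conditions: the
three-step pathway anchor uses a 5-element phase-1 search refined to 10
elements and a 100-interval collocation mesh; its 11-point fronts use 4
piecewise-constant elements per control with warm-started interior points
(search budget 100 evaluations each, anchors 300); the yeast model runs with
4 elements, a search budget of 550 and a 60-interval mesh; the B. subtilis
scenarios with 2 elements and a budget of 300; toy-model collocation checks
use 15–100 intervals. Deterministic seeds make every one of these runs
exactly reproducible.

## Known limitations

* Dynamics must be ODEs in the documented expression grammar: no DAEs,
  delays, events or stochasticity, and no table lookups inside rhs
  expressions.
* Only piecewise-constant and piecewise-linear CVP controls ($M_j \le 2$),
  and only the trapezoidal collocation scheme — no Hermite–Simpson or
  pseudospectral transcription, and no multiple shooting.
* The epsilon-constraint driver supports two objectives; dominance
  filtering itself is dimension-agnostic.
* The local NLP solver is a first-order augmented Lagrangian plus Newton
  refinement; on strongly nonconvex transcriptions it refines the basin it
  is started in, which is exactly why the hybrid global phase exists, and
  why anchors on hard problems deserve generous search budgets and several
  seeds (`multiplicity_ensemble()` automates that audit).
* Singular arcs are not regularized; they surface as control-envelope
  spread in the multiplicity ensemble rather than being detected
  symbolically.
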