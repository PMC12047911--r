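---
title: "Energy layer optimization: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy layer optimization: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elopt)
```

## The planning model

A pencil-beam-scanning proton plan is a nonnegative intensity per spot. The
dose-influence matrix `D` maps intensities to voxel dose and decomposes by
energy layer, `D = [D1 ... DN]`; a layer is *active* when its spots carry
intensity. Two constraints make the problem hard:

* the **minimum monitor unit (MMU)**: each delivered intensity must be 0 or
  at least a machine threshold `G_min` — a nonconvex, disconnected set;
* the **layer budget**: exactly `NE` of the `N` layers may be active,
  encoded by binaries `s` with `sum(s) = NE`.

The objective is the standard weighted quadratic DVH form: for each term,
the mean squared deviation between dose and its prescribed/limit level over
an *active voxel set*. L2 terms are always active on the whole structure.
DVH-max terms (at most a fraction `v` of the structure above level `t`)
and DVH-min terms (at least `v` above `t`) are nonconvex; we handle them by
iterative convex relaxation (ICR): at the current dose, a DVH-max term's
active set is the violating voxels minus the `floor(v * |structure|)`
highest-dose violators (the fraction that is allowed to exceed the level);
DVH-min mirrors this on underdosed voxels with allowance
`floor((1 - v) * |structure|)`. Floor rounding and index-order tie-breaking
make the map deterministic and idempotent at fixed dose, which the test
suite checks against exhaustive evaluation of the rule on small structures.
Whether a clinical system would round rather than floor the allowance is a
genuine convention choice; floor is conservative (never excuses an extra
voxel) and is fixed throughout.

All doses are carried internally as percent of prescription, so
prescription levels read naturally (100 = prescribed dose) and absolute
fraction schemes only affect reporting labels.

## The solver

With active sets frozen, the objective is a least-squares misfit
`||A x - b||^2` where each term contributes its active rows scaled by
`sqrt(weight / |active|)` (and by the square root of the scenario weight in
robust mode). One outer ICR iteration refreshes the active sets; inner ADMM
sweeps then alternate:

1. **x-step** — conjugate gradient on
   `(A'A + mu1 I) x = A'b + mu1 (z - lambda1)` with layer columns scaled by
   the current `s`. The operator is applied as two sparse matrix-vector
   products; the system is positive definite for any `mu1 > 0`. Default
   relative tolerance `1e-6`, warm-started across sweeps.
2. **s-step** — at fixed `x`, layer choice is the QUBO
   `||B s - b||^2 + mu2 (1's - NE + lambda2)^2`, where column `i` of `B` is
   layer `i`'s dose contribution `A_i x_i` (see below for solvers).
3. **z-step** — the exact Euclidean projection of `x + lambda1` onto
   `{0} U [G_min, Inf)`: 0 below `G_min / 2`, `G_min` between `G_min / 2`
   and `G_min`, identity above. The tie at exactly `G_min / 2` is resolved
   to `G_min`: the two candidates are equidistant, and keeping the spot
   deliverable is the physically useful choice.
4. **duals** — `lambda1 <- lambda1 + x - z` and the scalar
   `lambda2 <- lambda2 + sum(s) - NE` (the layer-count constraint is a
   single scalar equation, so its dual is a scalar).

The update order x → s → z → duals means the x-step sees the previous
sweep's selection.

**Shadow intensities.** When the s-step drops a layer, its intensities are
*not* zeroed during the sweeps. Zeroing them would collapse that layer's
column of `B` to zero at the next binary step, so a dropped layer could
never look attractive again and the selection would freeze after one or two
sweeps — particularly harmful when layers are nearly redundant, which is
precisely the regime layer reduction exploits. Keeping the intensities as
shadow values lets every binary step price all `N` layers fairly. The
delivered plan is made consistent at termination: deselected intensities
are zeroed, and the chosen selection is re-fit.

**Termination.** The cardinality penalty does not guarantee
`sum(s) = NE` at every sweep, so at termination the selection is repaired
greedily (add or remove the layer with the smallest marginal change of
`||Bs - b||^2`) and the resulting *restricted convex problem* — the plan
with `s` frozen — is solved cleanly by a second pass of the same ICR + ADMM
engine. The reported objective is therefore always the objective of a plan
that satisfies both the MMU constraint (the last operation is the
projection) and the layer budget exactly. The all-layers baseline
`run_impt()` is this same engine with `s` frozen at all ones.

**Penalty weights.** `mu1` defaults to `0.05` times a power-iteration
estimate of `||A||^2`, which makes the x-step regularization scale with the
problem instead of with arbitrary units; `mu2` defaults to the mean squared
column norm of `B` at the first binary step, putting the cardinality
penalty on the same scale as the data misfit. Both are exposed in
`admm_config()`. Iteration counts (default 15 outer x 6 inner) are
configuration: the underlying mixed-integer heuristic has no natural
stopping rule, and the objective histories recorded in every plan let the
user judge convergence.

## QUBO solvers

The binary subproblem is stored as minimize `s'Qs - 2c's` with symmetric
`Q = B'B + mu2 11'`, `c = B'b + mu2 (NE - lambda2) 1`, and a tracked
constant `||b||^2 + mu2 (NE - lambda2)^2` so that energy plus constant
reproduces the least-squares objective exactly at every binary vector (an
identity the tests verify at random configurations). Off-diagonal couplings
are counted once through the bilinear form.

* `solve_qubo_exact()` enumerates all `2^N` states in chunks (bound N ≤ 24),
  breaking ties toward the lexicographically smallest configuration. It is
  the ground-truth oracle for everything else.
* `solve_qubo_annealing()` is best-of-restarts single-flip Metropolis with
  a geometric temperature schedule scaled to the typical single-flip energy
  change of the instance, followed by zero-temperature descent; the
  all-zeros and all-ones states are always scored, so the result never
  loses to either. Fully seeded.
* `solve_qubo_vqa()` is a QAOA-style variational routine: the QUBO maps to
  a diagonal Ising cost Hamiltonian via `s = (1 - sigma) / 2`
  (`qubo_to_ising()` documents the exact coupling/field/offset
  correspondence), `depth` alternating layers of cost-phase and
  transverse-field mixer unitaries act on the uniform superposition, and
  the `2 * depth` angles are optimized by seeded multi-start Nelder-Mead on
  the expected energy (energies are rescaled to unit magnitude for
  optimizer conditioning). The default backend is an exact statevector, so
  the answer is the lowest-energy state among the most probable basis
  states; an optional `n_shots` switches to multinomial measurement
  sampling. The statevector bound is 16 qubits; `solve_qubo()` reroutes
  larger instances — including clinical layer counts of 50-80 — to
  annealing, mirroring the fact that variational-quantum solves at this
  scale are themselves simulations. Circuit depth, restarts, and shot
  counts have no canonical values for this problem; the defaults (depth 3,
  5 restarts) are validated against the exact oracle in the test suite.

## Choosing the number of layers

`select_ne()` implements the practical workflow: starting from the number
of layers the baseline actually uses (layers that received intensity, not
the total available), halve with ceiling rounding until the relative
objective error `|f_QC - f_IMPT| / f_IMPT` first exceeds the threshold
`epsilon` (default 0.1); ascend from that lower bound in steps of 5 until a
count passes; then scan the bracketing interval upward in unit steps and
return the smallest passing count. Each candidate count is evaluated at
most once (cached), each evaluation runs under a fixed seed, and the full
trace is returned for plotting. Two conventions were open and are fixed
here: halving uses ceiling (so the sequence always terminates at 1), and
the error is the absolute value — a reduced plan that happens to *beat* the
baseline by more than `epsilon` would be flagged rather than silently
accepted, which keeps the acceptance region an interval around the
baseline. On analytic error functions the workflow provably returns the
smallest passing count in the scanned interval, and the tests compare it
against brute force.

## Delivery time

The per-fraction delivery time is the sum of three terms:

* **ELST** — energy switching: 0.7 s per downward and 5.5 s per upward
  energy transition, summed over consecutive delivered layers including
  across beam boundaries (a conservative convention; machines that switch
  during gantry motion would hide part of it).
* **SSPT** — spot spill: delivered charge over the beam current,
  `||x||_1 / gamma` with `gamma = 2.6e11` protons/min, converted to
  seconds. A configurable factor converts intensity units to protons.
* **SSWT** — spot switching: per same-layer transition, the speed-limited
  lateral travel `max(|dx|/v_x, |dy|/v_y)` plus a 1 ms magnetic
  preparation. The published fits for this term are machine-specific, so
  the scan speeds are explicit configuration and only the structural
  properties (additivity, geometry dependence) are asserted in tests.

Delivery order is not dictated by the optimization: the package delivers
beams in index order and, within a beam, active layers in descending energy
— the standard practice that avoids slow upward switches — with spots in
serpentine row order. Under this convention removing a layer can never
increase ELST, which is the monotonicity the whole method relies on.

## The synthetic phantom generator

`generate_case()` builds fully synthetic cases: a spherical target and
cuboid organ-at-risk on a 3 mm isotropic grid, beams at configurable
gantry angles, spots on a 3 mm lateral grid covering the target footprint,
and energy layers every 5 mm of depth across the target extent. Each
spot's dose is an analytic Bragg-like curve — a slowly rising entrance
plateau, a Gaussian peak at the layer's nominal range, a sharper Gaussian
distal falloff — with Gaussian lateral spread and a small seeded lognormal
amplitude jitter. Setup uncertainty shifts the phantom relative to a fixed
entry plane (so shifts along the beam axis change depth, as they should);
range uncertainty scales the nominal ranges; the standard 5 mm / 3.5%
setting yields the usual nine scenarios (nominal, six cardinal shifts, two
range scalings) with uniform weights by default. How per-scenario objectives
should be composited is left open by the robust-planning literature this
follows; the package uses the scenario-weighted sum (stacking
`sqrt(weight)`-scaled rows), with active sets refreshed per scenario from
that scenario's dose, and exposes the weights so expected-value or
worst-case-leaning composites can be emulated.

A `layer_repeat` option duplicates every nominal range, building cases with
deliberate layer redundancy — the property layer reduction exploits — which
the tests use for parameter-recovery experiments (the workflow should keep
roughly one layer per distinct range).

What the phantom does *not* emulate: tissue heterogeneity, scattering tails,
range straggling beyond the analytic widths, realistic beam models, or
patient anatomy. Passing tests on these phantoms validates the optimization
machinery — the convex steps against oracles, the binary steps against
enumeration, the workflow against brute force — not clinical dosimetry; on
real dose-influence matrices the algorithm applies unchanged but the
numbers would be machine- and patient-specific.

## Numerical conventions and problem sizes

* CG tolerance `1e-6` (relative residual), cap 100 iterations, warm starts.
* MMU threshold default `G_min = 1` intensity unit, about a few percent of
  a typical optimized spot weight on the bundled phantoms.
* Active-set allowances use `floor(. + 1e-9)` so that exact fractions of
  structure sizes are not lost to floating-point representation.
* All stochastic components (case jitter, annealing, variational restarts,
  inner QUBO seeds) derive from explicit integer seeds; re-running any
  pipeline with the same seed reproduces the same report byte for byte,
  and case files round-trip bit-exactly (matrix entries are written with
  17 significant digits).
* The tests and the acceptance script run phantoms of 2,744-4,096 voxels,
  8-20 layers, and 400-1,100 spots with 8-10 outer x 4-5 inner iterations —
  sizes chosen so a full pipeline solves in seconds while still exhibiting
  layer redundancy; the engine itself is dimension-free and its per-sweep
  cost is dominated by sparse matrix-vector products.

## Known limitations

* The mixed-integer heuristic is not monotone in `NE`: an unlucky selection
  at a larger budget can end worse than a smaller one (the restricted
  re-fit reports such plans honestly rather than masking them). The
  selection workflow's caching keeps the best plan per count.
* Worst-case (minimax) robust composites are not implemented.
* The exact QUBO solver is exponential by design; above 24 variables only
  the heuristic backends apply, and the variational backend above 16 qubits
  falls back to annealing.
* No DICOM-RT or Monte Carlo dose interfaces; cases enter either from the
  generator or from the Matrix Market case directory format.
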