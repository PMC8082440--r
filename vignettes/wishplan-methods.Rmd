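---
title: "wishplan: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wishplan: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`wishplan` implements a desk-scale automated-planning pipeline for
mediastinal lymphoma radiotherapy and the population study built on top of
it: for each (synthetic) patient it generates 24 treatment plans — CP_x and
NCP_x (x = 5..15 computer-selected coplanar/non-coplanar IMRT beams) plus
the VMAT (21 equiangular coplanar beams) and Butterfly-VMAT (20 beams in
three 60° arcs) class solutions — evaluates clinical dose-volume metrics,
applies the coverage-based patient exclusion rule, and aggregates
population statistics with two-sided Wilcoxon signed-rank tests.

The pipeline has five layers, each usable on its own: phantom generation
(`generate_patient`, `generate_cohort`), beam geometry (`beam_direction`,
candidate enumeration, class solutions), an analytic dose-influence engine
(`compute_influence`), prioritized wish-list optimization
(`solve_wishlist`) with greedy beam-angle optimization (`greedy_select`),
and plan evaluation / study orchestration (`compute_metrics`, `run_study`).

# The optimization model

## Wish-list (lexicographic epsilon-constraint) optimization

A wish-list is an ordered set of hard constraints (maximum or mean dose per
structure) and prioritized convex objectives with goal values. Planning
proceeds one priority at a time. Stage $i$ solves

$$\min_{x \ge 0} \; f_i(d), \quad d = D x, \quad
  \text{s.t. hard constraints and } f_j(d) \le b_j \; (j < i),$$

where $x$ is the beamlet fluence vector and $D$ the dose-influence matrix.
After stage $i$, its bound is recorded as

* $b_i = \text{goal}_i$ when the goal was attained (with a numerical
  attainment margin, below), or
* $b_i = \text{achieved}_i \cdot (1 + \delta)$ otherwise, with
  `slack_delta` $\delta = 0.03$ by default.

The slack is what lets lower priorities make progress; it is recorded in
every plan. Supported objective types are mean dose, mean underdose below a
threshold, mean overdose above a threshold (all exactly LP-representable)
and gEUD(a). gEUD is evaluated exactly post hoc for any $a > 0$; inside the
staged solver only $a = 1$ (identical to mean dose) is accepted, because a
general-$a$ gEUD stage is no longer an LP and no suitable NLP layer is
available in the target environment. The default wish-list does not use
gEUD.

Volume metrics (V5Gy, V20Gy, V95%) are non-convex counting quantities; they
are steered through convex surrogates (the mean over/underdose objectives)
and *evaluated* exactly after planning, which mirrors standard practice.

## The default wish-list

The published clinical wish-list itself is not available; the default is a
reconstruction from the printed protocol: prescription 30 Gy in 15
fractions; hard dose ceiling 110% (33 Gy) on PTV and patient; priorities
(1) PTV mean underdose below 28.5 Gy (95% of prescription), goal 0;
(2) heart mean dose, goal 10 Gy; (3) lungs mean dose, goal 13.5 Gy;
(4)/(5) left/right breast mean dose, goal 2 Gy; (6) lungs mean overdose
above 5 Gy, goal 1.5 Gy (a tuned convex surrogate for lungs V5Gy); (7)
patient mean dose, goal 0 (conformality). Goals use the protocol's
*preferred* thresholds; the *required* thresholds (breast 5 Gy, heart
26 Gy, lungs 15 Gy, lungs V5Gy 55%, V20Gy 30%) are evaluated by
`check_goals`. The two printed breast goals ("each") are represented as two
consecutive priorities because priorities must be unique.

## Solver

Each stage is solved with a diagonally preconditioned primal-dual
first-order method (Chambolle–Pock with Pock–Chambolle diagonal step
sizes), implemented in C++ over a sparse influence matrix. Hinge-sum
epsilon-constraints are enforced by exact Euclidean projection (bisection
on the proximal multiplier); per-voxel bounds and halfspaces by direct
projection. For small problems — all contract and oracle tests — the
first-order solution is refined by a proximal-point sequence of quadprog
solves; the proximal-point method on a linear program converges finitely,
so the refined solution is the exact stage optimum (verified against an
independent `scipy.optimize.linprog` oracle to ~1e-7 relative).

Numerical choices that matter:

* **Epsilon-constraint margins.** Bounds are posed internally tightened by
  a relative margin (`eps_margin_rel`, 2e-4 in the accurate profile) and
  solved to a feasibility tolerance of 0.4 of that margin. Consequently the
  *recorded* bounds hold for the returned fluence with room to spare — the
  package asserts `objective_values <= bounds + 1e-6` after every solve.
  A goal counts as attained only when achieved clears it by the margin;
  goal-0 underdose objectives that reach (numerical) zero are subsequently
  enforced as per-voxel minimum-dose constraints at a threshold tightened
  by the margin, which makes the recorded bound of exactly 0 hold exactly.
* **Solver profiles.** `control_accurate()` (first-order + polish,
  errors on non-convergence) for tiny fixtures and contract tests;
  `control_fast()` / `control_score()` (bounded iterations, no polish) for
  study runs, where plan *quality* is judged by the evaluated metrics, not
  by optimality certificates. The coverage stage gets its own iteration
  budget (`stage1_max_iter`) because PTV coverage is the one requirement
  treated as hard.
* **Determinism.** No randomized initialization anywhere; identical inputs
  give identical plans.

## Greedy beam-angle optimization

Beams are selected one at a time from the candidate set. Each unselected
candidate is scored by optimizing only the candidate's beamlets on top of
the frozen incumbent dose (`incremental` mode, the default) or by a full
re-solve (`full` mode); the lexicographically best candidate is added (ties
broken by couch, then gantry, ascending — the candidate ordering), and the
incumbent fluence is fully re-optimized. Because greedy selection is
nested, one run to x = 15 yields every CP_x/NCP_x plan as a prefix; this is
how `run_study` generates all 22 BAO plans from two greedy runs per
patient.

Two scoring shortcuts keep desk-scale runtimes: scoring uses only the
leading priorities (`score_depth`, default 3; the re-optimization always
uses the full wish-list), and scoring runs with a higher iteration budget
while the incumbent's coverage objective is still positive, because that is
the regime where beam choice matters most. Greedy selection with
approximate scoring carries no optimality guarantee; the package measures
its gap against exhaustive subset search on small instances instead of
assuming it away, and the superset advantage of non-coplanar candidates is
asserted at the level of exhaustive subsets (where it is a theorem) and
tested empirically at the level of greedy population means.

# The dose engine

The Monte Carlo engine of a clinical system is out of scope; `wishplan`
substitutes a transparent analytic pencil-beam kernel and says so. For
voxel $v$ and beamlet $j$:

$$D_{vj} = \text{OF} \cdot e^{-\mu\, d_\text{rad}(v)} \cdot
           e^{-r(v,j)^2 / 2\sigma^2},$$

with $d_\text{rad}$ the density-weighted depth from the patient surface
along the beam axis (ray marching, nearest-neighbour density lookup,
half-voxel steps), $r$ the lateral distance from the beamlet ray, and
entries below `trunc_rel` (1e-4) of the beamlet maximum truncated to zero
(sparse storage). Geometry is parallel (non-divergent): source-axis
distance bookkeeping changes nothing about the beam-direction comparisons
the study makes. Defaults $\mu = 0.005$/mm and $\sigma = 4$ mm give a
6-MV-like depth falloff; there is no build-up region and no scatter beyond
the lateral Gaussian. Lung tissue has relative density 0.25, everything
else 1.0, so radiological depth genuinely differs between lung and soft
tissue paths.

With a pure Gaussian lateral kernel, beamlet spacing must stay below about
$2.5\sigma$ or the lattice cannot form flat fields; the reduced study
profile therefore pairs 20 mm beamlets with $\sigma = 10$ mm. This is a
stated resolution reduction, not a physics claim.

# The synthetic cohort

Each phantom is built from geometric primitives on an isotropic grid
(default 4 mm over a 320 x 220 x 280 mm field; the reduced study profile
uses 14 mm, the volume-distribution checks 10 mm): elliptic-cylinder torso
(mildly jittered semi-axes around 145 x 92 mm), two ellipsoidal lungs at
density 0.25, an ellipsoidal heart (anterior-inferior, slightly left),
anterior hemispherical breasts (always present — the emulated cohort is
all female), and a mediastinal PTV tube with optional supraclavicular and
axillary lobes and a bulky-disease variant. OAR masks are made pairwise
disjoint by construction (heart takes precedence over lungs, thoracic
organs over breast); the PTV may overlap OARs, as real mediastinal targets
do.

PTV volumes are drawn log-normally with median 605 cc and log-sd 0.5,
clipped to [97, 1654] cc (clipping affects ~2% of draws; only the median
and range are published, the spread is a modelling choice). The realized
mask is calibrated by bisection on the lateral scale to within ~2% of the
draw (contract: 10%); cranio-caudal extents are drawn uniformly with a
minimum length tied to the volume so the required cross-section stays
anatomically plausible. Flag prevalences (supraclavicular 0.3/side,
axillary 0.2/side, bulky 0.25) are configurable defaults — the source
cohort's prevalences are not published, so these are choices, not
inferences.

What the generator does *not* emulate: CT texture and Hounsfield units,
deformable/asymmetric organ shapes, shoulder/neck anatomy, couch and
immobilization hardware. A green population test therefore establishes that
the *pipeline* reproduces the protocol's structure and trends on plausible
geometry, not that it reproduces any clinical cohort's absolute dosimetry
— which is also why the study's absolute Table-style values are reported
but not asserted.

# The study protocol

`run_study` attempts exactly 24 plans per patient. Any patient with any
plan failing the coverage requirement (PTV V95% >= 95%, the ">=" reading)
is excluded from every population analysis — the "patient 0" rule. Plans
are renormalized (fluence scaling) so full-grid coverage reaches the
prescription isodose where the 110% ceiling allows; prescription
renormalization is standard planning practice and is applied uniformly to
all 24 configurations. Population summaries are means and ranges per
configuration per metric over evaluable patients; per-patient orderings
follow descending NCP_15 heart mean dose. Wilcoxon signed-rank tests are
two-sided, exact (dynamic programming over doubled midranks) up to n = 25,
normal-approximated with tie correction beyond, and reported unadjusted at
alpha = 0.05 (no multiple-testing correction, deliberately). Directional
per-OAR comparisons between configurations are emitted as data, not
asserted as tests: they depend on anatomy realism beyond the generator's
warrant.

# What the population trend tests establish

The trend assertions (priority-1 population mean non-increasing in the
beam count x; non-coplanar never worse than coplanar at equal x) are
evaluated on the re-optimized coverage objective at x in {5, 8, 11, 15}.
On the default synthetic cohort the coverage objective typically reaches
zero by 4–6 beams — the idealized kernel makes coverage easier than on
real anatomy — so at the tested beam counts both assertions often hold at
0 = 0. They bind in the regime where coverage is genuinely hard (large
targets wrapped around the heart at few coplanar beams, visible in the
greedy traces at x < 5), and the same machinery exposes the paper-like
phenomenon of coverage failure at low coplanar beam counts for difficult
anatomies. The absolute OAR trade-off trends across configurations are
reported as data (population summaries, Wilcoxon tests), not asserted.

# Known limitations

* Hard maximum-dose constraints act on the sampled optimization voxels;
  unsampled normal-tissue voxels can exceed the ceiling (the PTV itself is
  always fully sampled, so coverage and PTV overdose are controlled
  exactly). Reported patient metrics are computed on the full grid and
  show whatever spill occurs.
* The first-order solver certifies feasibility and bound satisfaction, not
  global optimality, in the fast profiles; exactness is established on
  small instances via the quadprog polish and the scipy LP oracle.
* Parallel beams and the absence of build-up make absolute dose values
  stylized; only comparative structure is meaningful.
* The 194-direction candidate set of a real linac cannot be reproduced
  (machine-specific collision geometry); the default collision mask
  reproduces its shape (couch-0 always deliverable, posterior couch-rotated
  directions excluded) and yields an order-200 set at 10 degrees.
* `greedy_select` with incremental scoring is an approximation of
  integrated beam-angle optimization; its gap is measured, not bounded.
* Monotonicity comparisons between two independent fresh solves are
  asserted at the solver's relative objective tolerance (1e-4), not at
  machine precision; the epsilon-constraint bound contract, by contrast,
  is enforced through the margin scheme and asserted at 1e-6.
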