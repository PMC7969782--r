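---
title: "Staged constrained constructive optimisation of arterial trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged constrained constructive optimisation of arterial trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

## The model

`vasctree` generates synthetic arterial trees in a perfusion domain
$\Omega$ (2D or 3D) by constrained constructive optimisation: the network
is built one terminal at a time, and each new bifurcation is placed where a
cost functional is minimal among all admissible candidates. A tree is a set
of straight cylindrical segments $v_i = (r_i, x^p_i, x^d_i)$ rooted at one
or more inlets with fixed root radius $r_1$ and inflow $Q$.

Three groups of assumptions define the model:

**Hemodynamics.** Steady Poiseuille flow in every segment,
$\Delta p_i = R_i q_i$ with $R_i = 8\eta(r_i)\,l_i/(\pi r_i^4)$, and a
radius-dependent apparent viscosity (in cP, radii in mm)
$$\eta(r) = 1.125\left(\kappa + \kappa^2\big(6e^{-170 r} -
  2.44 e^{-8.09\,r^{0.64}} + 2.2\big)\right),\qquad
  \kappa = \left(\frac{r}{r - 5.5\times 10^{-4}}\right)^2,$$
which captures the reduction of apparent viscosity in narrow tubes. All
free terminals deliver the same outflow $q_f$; designated distal arteries
(constrained outlets) instead carry a prescribed fraction of the total
inflow, and $q_f$ is the remaining flow divided by the number of free
terminals. Viscosity is converted to Pa s once at the module boundary, so
resistances are in Pa s/mm$^3$ and pressure drops in Pa.

**Geometry.** At every bifurcation, radii obey Murray's law
$r_p^\gamma = r_{s1}^\gamma + r_{s2}^\gamma$; daughters of a new
bifurcation must satisfy the symmetry bound
$\min(r_{s1},r_{s2})/\max(r_{s1},r_{s2}) > \delta$ (optionally a step map
over the bifurcation level of the parent); every vessel must satisfy the
aspect bound $l/r > 2$; vessels must not inter-penetrate; and optional
windows constrain the bifurcation angle $\theta$ (between the surviving
distal segment and the new vessel) and the opening angle $\phi$ (between
the new vessel and the plane of the split vessel).

**Closure.** The root radius and root inflow are fixed; the pressure drop
is an output. Radii follow from a fixed point: bottom-up reduced
(subtree-equivalent) resistances $R^*$, sibling ratios
$r_{s1}/r_{s2} = (q_{s1}R^*_{s1}/(q_{s2}R^*_{s2}))^{1/4}$ — which equalise
the pressure drop to all distal terminals — normalised through Murray's
law, top-down radii from the fixed root radius, and a viscosity refresh
from the new radii, iterated until the largest relative radius change is
below `tol` (default `1e-6`, cap 200 iterations; the viscosity law is a
mild contraction so a handful of sweeps suffice). Unary chains (tortuous
vessels represented as several collinear-ish links) are treated as series
resistances carrying a single radius; junctions with three or more
children generalise the sibling rule with $r_c \propto (q_c R^*_c)^{1/4}$
and $\sum_c r_c^\gamma = r_p^\gamma$.

## The growth loop

Each stage repeats four steps until its terminal budget is committed:

1. **Terminal sampling.** A candidate terminal position is drawn from the
   stage's placement density restricted to $\Omega$ (uniform, Gaussian,
   Gaussian mixture, or a user function under bounded rejection). It is
   rejected while closer than
   $l_{lim} = f\, l_c\, (\nu/(N_T+1))^{1/D}$ to the existing forest, where
   $l_c$ is the equivalent disc/sphere radius of $\Omega$, $N_T$ the
   current terminal count and $f$ an accumulated relaxation factor:
   every `n_fail` consecutive failures multiply $f$ by `f_r`, and $f$
   resets to 1 after a successful connection (the base threshold is
   re-derived each iteration; relaxation is a local escape hatch).
   Failures of the connection search below count towards `n_fail` as well.
2. **Candidate enumeration.** Every eligible vessel within $f_n l_c$ of
   the terminal is considered. For each, the triangle spanned by the
   terminal and the vessel's endpoints is discretised into a barycentric
   lattice with $\Delta v$ points per side, vertices excluded
   ($\Delta v(\Delta v + 1)/2 - 3$ points). Branching behaviours restrict
   the locus: non-branching vessels are ineligible, distal vessels admit
   only their distal point (appending an extra child, no split), fixed
   vessels only lattice points on their own axis, versatile vessels the
   whole lattice. Degenerate (collinear) triangles fall back to the axis
   points.
3. **Scoring and feasibility.** Each candidate split is evaluated on a
   tentatively re-converged state: flows are frozen at the current $q_f$,
   only the root path of the target vessel is re-reduced (constant-time
   per-ancestor updates using the identity $t_c^4 = q_c R^*_c$), and a
   two-iteration local fixed point refreshes the viscosities of the new
   vessels from radii estimated at the parent's current scale. Without
   constrained outlets this frozen-flow evaluation is exact up to the
   viscosity refresh, because a uniform rescaling of all terminal
   outflows leaves every radius unchanged under the fixed-root-radius
   closure. The feasibility gate applies, in order: eligibility by
   behaviour; bifurcation-site containment by the target's role
   (distribution and perforator vessels only bifurcate inside $\Omega$;
   transport vessels anywhere); angle windows; aspect and symmetry bounds
   on the new trio; aspect bounds along the re-scaled root path;
   new-segment containment by the stage's vessel type (distribution
   vessels wholly inside $\Omega$, perforator vessels with their distal
   end inside, transport vessels unconstrained); and cylinder
   non-intersection against all vessels outside the junction
   neighbourhood. The feasible candidate of minimum cost wins; ties keep
   the earliest candidate in the deterministic enumeration order.
4. **Commit and re-convergence.** The winning split replaces the target
   $v_j$ by $v_p$, $v_s$ and the new terminal $v_{new}$; $v_s$ inherits
   $v_j$'s children, role, behaviour and outlet identity, while $v_p$
   keeps the role and becomes versatile (a non-branching target leaves
   both halves non-branching, so splitting pre-existing anatomy creates
   no new growth permissions; keeping the role rather than resetting it
   to "distribution" preserves containment semantics for transport and
   perforator vessels). Terminal outflows are re-split over the new
   terminal count and the radius fixed point is run at full tolerance.

## Keeping constraints honest as the tree reshapes

A subtlety of constructive optimisation is that radii keep changing after
a vessel is created: vessels on frequently used root paths thicken as
their subtrees capture more terminals. Two mechanisms keep the
constraints meaningful on the finished tree:

- **Aspect ratio.** After every commit the aspect bound is re-checked for
  every vessel whose radius increased (the full reshaped tree, not just
  the new trio), and during the search candidate trios and their root
  paths must pass the bound with a 1% margin (`l/r > 2.02`). A commit
  that would push any vessel below the bound is rolled back and the
  next-cheapest candidate for the same terminal is tried (candidates are
  collected in cost order in one search pass; rollbacks are logged as
  `growth_rollbacks`). The connection finally kept is therefore the
  minimum-cost one whose *committed* tree satisfies the bound, and
  `l/r > 2` holds for every generated vessel of a finished tree.
- **Non-intersection.** Deciding what counts as inter-penetration in a
  connected tree needs care: at every junction the parent cylinder
  overlaps its daughters, and a shallow-angle daughter overlaps its
  sibling over an extended wedge — that is continuous lumen, not
  penetration. The package therefore classifies a cylinder overlap as an
  intersection only when the whole violating region lies outside the
  junction region: along the overlap interval (distance between the two
  axes is convex along a segment, so the violating range is an interval,
  bisected at its ends), the arc length *measured along the tree* between
  overlapping points must everywhere exceed twice the combined
  largest-attained radii. A branch looping back onto a remote part of the
  tree fails this everywhere and is rejected; a junction wedge touches
  arc zero and is exempt. Arc lengths are invariant when later splits
  subdivide vessels, which keeps the classification stable over a run.
  The constraint is enforced when vessels are created (the new vessel and
  both split halves are checked against the whole forest with a 5%
  clearance margin, at their tentatively converged radii, and re-checked
  at the exact radii immediately after the commit); the margin absorbs
  the few-percent drift of neighbouring radii over the rest of the run.

`audit_forest()` re-checks a finished forest with independent R
implementations of all formulas. Its intersection audit asks whether any
vessel axis runs *deep* inside another vessel — closest approach within
half the combined radii — at points far apart along the tree; overlaps
contiguous with a junction are continuous lumen and tangential wall
grazing is contact, not penetration. This operational definition is
invariant under later splits and robust to the residual radius drift the
constructive margins leave behind, so the suite requires a clean audit
on generated trees. The symmetry
bound is a creation-time constraint on the newly formed bifurcation:
sibling ratios drift as the two subtrees grow differently, so the audit
reports post-hoc ratios while the constructive guarantee applies at
creation.

## Cost functionals

Two stage-selectable costs are implemented. The *volumetric* cost is the
increase in total intravascular volume
$\sum_i l_i \pi r_i^2$ caused by the candidate. The *sprouting* cost adds
biological terms,
$$F_{sprout} = c_v\,\frac{\Delta F_{vol}}{V_{ref}} +
  c_p\,\frac{r_p}{r_{ref}} +
  c_d\left(\frac{\|x^d-x^p\|}{l_{ref}}\right)^2,$$
where the degradation term (parent-wall exposure, proportional to the
tentative radius of the new vessel's parent) favours sprouting from small
vessels and the diffusion term (growth-signal transport) favours nearby
parents. $V_{ref}$ is the currently vascularised volume — the total
intravascular volume of the forest before the insertion — and $l_{ref}$
its equivalent-sphere radius; $r_{ref}$ is the root radius of the tree
being joined. This reading of the references makes all three terms of
comparable magnitude throughout a run (with $V_{ref}$ the territory
measure instead, the volume and diffusion terms would be orders of
magnitude apart and the parent-radius term would dominate selection,
which empirically drives a single inlet to capture the whole domain).
With multiple inlets the sprouting cost then prevents monopolisation:
terminals connect predominantly to the nearest front, and because each
inlet is a separate tree sharing the forest-wide $q_f$, balanced inlet
flows emerge from the cost rather than being imposed.

## Staged growth

A growth process is an ordered list of stages
$\{\Omega, \mathcal{P}_{geo}, \mathcal{P}_{opt}, \mathcal{T}_{init},
N_{T,final}, F\}$: each stage has its own domain, geometric parameters
($\gamma$, $\delta$ — possibly level-dependent), optimisation parameters
($\nu, f_r, f_n, \Delta v$), terminal budget, cost functional, generated
vessel type (role and behaviour), placement density, optional new inlets,
and an optional restriction of eligible parent vessels to earlier stages.
Pre-existing anatomy (e.g. traced from images) enters as stage 0 through
the interchange table, with per-vessel roles and branching behaviours
controlling how completion may attach to it.

## Fixture scale and what the generator does and does not emulate

The packaged fixtures use unit-radius domains (mm), root radii of 0.05 mm
and a total inflow of 1 mm$^3$/s per unit territory; with the fixture
budgets (200–2000 terminals) terminal radii land in the arteriolar range
(5–20 µm), comfortably above the viscosity pole. Where a benchmark
scenario starts from a pre-existing tree whose exact geometry is not
published, the fixture constructs a small symmetric synthetic stand-in
(labelled as such in `fixtures()`), which suffices for the structural and
budget-based checks. The generator emulates space-filling growth,
staged hierarchies, heterogeneous placement densities and flow diversion;
it does not emulate anastomoses (the tree topology is enforced), pulsatile
or compliant flow, plasma skimming/variable hematocrit, or curved vessels
(tortuosity must be supplied as unary chains in the input). Passing tests
therefore validate the constructive algorithm and its invariants, not
anatomical fidelity to any specific organ.

## Numerical choices

- Radius fixed point: tolerance $10^{-6}$ (relative radius change),
  iteration cap 200, failure raises an error carrying the residual.
- Candidate scoring: two local viscosity iterations; full-tolerance
  re-convergence after each commit. Equality of the resulting selection
  with an exhaustive full-recompute search is a property test in the
  suite.
- Angle computations clamp `acos` arguments to $[-1,1]$; a degenerate
  bifurcation plane (collinear parent and distal segments) disables the
  opening-angle constraint for that candidate.
- Segment containment uses `max(2, ceil(l / (0.1 l_c)) + 1)` membership
  checks, tying the resolution to the perfusion scale; thin-shell domains
  are therefore checked at sampled points, not continuously.
- Membership is closed (boundary points inside); rejection near
  boundaries is handled by the segment and constraint checks.
- `n_fail` defaults to 100 and the per-stage attempt guard to $10^6$;
  both are configurable.
- Ties in candidate costs break by the deterministic lattice/vessel
  enumeration order, making runs bit-reproducible from (configuration,
  seed).
- Mesh domains: membership by parity ray casting along a fixed irrational
  direction, volume by the divergence theorem; extruded shells test the
  unsigned distance to the surface against the inward/outward offsets.

## Known limitations

- The brute-force search is quadratic in tree size; the packaged
  benchmark fixtures run at their reference budgets (200 to 2000
  terminals per scenario), which is the scale the package targets.
- Between the sampled containment checks a segment can leave a thin
  domain undetected; shells thinner than about a tenth of $l_c$ need a
  smaller check spacing.
- Constrained-outlet trees make the frozen-flow candidate evaluation
  slightly approximate (outlet flows do not rescale with $q_f$); the
  post-commit full re-convergence corrects any drift before the next
  step.
- The selection margins on aspect (1%) and clearance (5%) make the
  effective constraints marginally stricter than their nominal forms;
  this is the price of keeping the nominal constraints true on the
  finished tree.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
stage <- growth_stage(
  disc_domain(radius = 1), budget = 200,
  geo = geo_params(gamma = 3, delta = 0),
  opt = opt_params(nu = 1, f_r = 0.9, f_n = 8, delta_v = 7),
  roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1))
res <- run_stages(list(stage))
vessels(res$forest)[1:3, c("radius", "flow", "level")]
audit_forest(res$forest, domain = disc_domain(radius = 1))$ok
```
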