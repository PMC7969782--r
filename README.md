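# vasctree

Synthetic arterial trees for perfusion domains, grown by staged constrained
constructive optimisation.

Researchers modelling organ perfusion need vascular networks below the
resolution of imaging: arteriolar trees that are anatomically plausible,
hemodynamically consistent, and tailored to a territory. `vasctree` builds
such networks segment by segment. Starting from one or more inlets (or from
a pre-existing tree traced from images), it repeatedly samples a terminal
position inside the perfusion domain Ω, enumerates every admissible
bifurcation site on nearby vessels, and commits the connection that
minimises a cost functional, re-converging the whole tree's radii after
every step.

The model in brief:

- Poiseuille hemodynamics with a radius-dependent apparent viscosity
  (Fåhræus–Lindqvist effect), equal outflow q_f at all free terminals,
  prescribed flow fractions at constrained outlets, fixed root radius and
  inflow per tree.
- Murray's law `r_p^γ = r_s1^γ + r_s2^γ` at every bifurcation, a symmetry
  bound `min(r_s1,r_s2)/max(r_s1,r_s2) > δ` (optionally level-dependent),
  aspect ratio `l/r > 2`, non-intersection of vessel cylinders, and
  optional bifurcation/opening-angle windows.
- Radii from a fixed point: bottom-up reduced resistances, sibling ratios
  `(q_1 R*_1 / (q_2 R*_2))^(1/4)` that equalise terminal pressure drops,
  top-down radii from the fixed root radius.
- Two cost functionals: incremental tree volume, and a sprouting mixture
  cost adding parent-wall degradation and growth-signal diffusion terms —
  useful to balance concurrent inlets.
- Staged growth: a sequence of stages, each with its own domain, terminal
  budget, parameters, cost, generated vessel type (distribution, transport
  or perforator role; non-branching, distal, fixed or versatile branching
  behaviour) and terminal placement density (uniform, Gaussian, mixtures).

See the vignette (`vignettes/staged-vascular-growth.Rmd`) for the full
account of the method and its numerical choices.

## A worked example

```r
library(vasctree)
set.seed(1)
stage <- growth_stage(
  disc_domain(radius = 1),        # unit-disc territory (mm)
  budget = 200,                   # terminals to add
  geo = geo_params(gamma = 3, delta = 0),
  opt = opt_params(nu = 1, f_r = 0.9, f_n = 8, delta_v = 7),
  roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1))
res <- run_stages(list(stage))
res$forest
#> <vascular_forest: 401 vessels, 201 terminals, 1 tree(s), gamma=3>
#>   root r1 = 0.05 mm, Q = 1 mm^3/s

range(vessels(res$forest)$radius)
#> [1] 0.00701193 0.05000000
audit_forest(res$forest, domain = disc_domain(radius = 1))$ok
#> [1] TRUE
write_tree(res$forest, "tree.csv")     # interchange table
write_vtk(res$forest, "tree.vtk")      # for ParaView
```

A 200-terminal tree in the unit disc contains 401 vessels (each committed
terminal splits one segment and adds one). Radii taper from the fixed
50 µm root to ~7 µm terminals; the audit re-checks Murray residuals,
symmetry, aspect ratios, exact flow conservation, containment and
non-intersection on the finished tree.

Packaged setups for the benchmark scenarios (sequential, hierarchical and
scale-specific staged growth, concurrent two-inlet growth under both
costs, Gaussian and mixture placement densities, constrained outlets) are
listed by `fixtures()` and run with `run_fixture(name, seed)`.

A thin command-line interface is installed at `inst/cli/vasctree.R`:

```sh
Rscript inst/cli/vasctree.R grow --config inst/extdata/two_inlet_staged.yaml \
    --seed 1 --out tree.csv --vtk tree.vtk
Rscript inst/cli/vasctree.R audit --tree tree.csv
Rscript inst/cli/vasctree.R report --tree tree.csv
```

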