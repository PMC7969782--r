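Package: vasctree
Title: Staged Constrained Constructive Optimisation of Arterial Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic generation of synthetic arterial trees in 2D and 3D
    perfusion domains by staged constrained constructive optimisation.
    Trees grow one terminal at a time under Murray's law, symmetry and
    aspect-ratio constraints, with Poiseuille hemodynamics and a
    Fahraeus-Lindqvist radius-dependent viscosity. Supports multi-stage
    growth with per-stage domains, cost functionals (tree volume and a
    sprouting mixture cost), vessel roles (distribution, transport,
    perforator), branching behaviours for vascular completion from
    pre-existing trees, heterogeneous terminal-placement densities and
    constrained outlet flows. Includes implicit and surface-mesh domains,
    interchange and VTK export, a constraint auditor, morphometry
    summaries and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    utils,
    stats,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
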