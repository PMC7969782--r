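#' Packaged experiment fixtures
#'
#' Ready-made growth setups for the academic benchmark scenarios: classic
#' single-stage growth in a unit disc, sequential growth of two disjoint
#' territories from a small pre-existing tree, hierarchical annulus-then-disc
#' growth, scale-specific growth with a tightening-then-relaxing symmetry
#' bound, concurrent growth from two opposite equiradial inlets (volumetric,
#' sprouting and two-stage mixed criteria; 2D disc and 3D sphere),
#' heterogeneous Gaussian and Gaussian-mixture placement densities, and
#' constrained-outlet flow diversion. Where a scenario starts from a
#' pre-existing tree whose exact geometry is not published, the fixture
#' builds a small synthetic symmetric stand-in.
#'
#' Default physical scale of the fixtures: domains of unit radius (mm), root
#' radius r1 = 0.05 mm and total inflow 1 mm^3/s per unit territory, which
#' puts terminal radii in the arteriolar range for the fixture budgets.
#'
#' @return `fixtures()`: data.frame of fixture names and descriptions;
#'   `fixture(name)`: list with `stages`, an `init` forest builder (or NULL)
#'   and the `domains` involved; `run_fixture()`: result of [run_stages()].
#' @export
fixtures <- function() {
  data.frame(name = names(.fixture_registry()),
             description = vapply(.fixture_registry(), `[[`, "",
                                  "description"))
}

#' @rdname fixtures
#' @param name fixture name as listed by `fixtures()`.
#' @export
fixture <- function(name) {
  reg <- .fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; see fixtures()")
  reg[[name]]$build()
}

#' @rdname fixtures
#' @param seed RNG seed.
#' @param budgets optional per-stage budget override (same length as the
#'   fixture's stage list), for reduced-size runs.
#' @export
run_fixture <- function(name, seed = 1, budgets = NULL) {
  fx <- fixture(name)
  stages <- fx$stages
  if (!is.null(budgets)) {
    stopifnot(length(budgets) == length(stages))
    for (t in seq_along(stages)) stages[[t]]$budget <- as.integer(budgets[t])
  }
  if (!is.null(seed)) set.seed(seed)
  forest <- if (!is.null(fx$init)) fx$init() else NULL
  run_stages(stages, forest = forest, seed = NULL)
}

.fx_opt <- function(nu = 1, delta_v = 7) {
  opt_params(nu = nu, f_r = 0.9, f_n = 8, delta_v = delta_v)
}

# synthetic stand-in for a small pre-existing tree feeding two territories
.fx_sequential_init <- function() {
  f <- vascular_forest(gamma = 3)
  add_root_vessel(f, c(0, 3), c(0, 2), radius = 0.05, inflow = 2,
                  role = "transport", behaviour = "non-branching", stage = 0L)
  add_child_vessel(f, 1, c(-1.5, 0.9), role = "perforator",
                   behaviour = "distal", stage = 0L)
  add_child_vessel(f, 1, c(1.5, 0.9), role = "perforator",
                   behaviour = "distal", stage = 0L)
  assign_flows(f)
  update_radii(f)
  f
}

# synthetic initialisation with one distal artery leaving the disc
.fx_outlet_init <- function(fraction = NA_real_) {
  function() {
    f <- vascular_forest(gamma = 3)
    add_root_vessel(f, c(-1, 0), c(-0.4, 0), radius = 0.05, inflow = 1,
                    role = "distribution", behaviour = "versatile", stage = 0L)
    add_child_vessel(f, 1, c(-0.8, 0.8), role = "transport",
                     behaviour = "non-branching", stage = 0L,
                     outlet_fraction = fraction)
    add_child_vessel(f, 1, c(0.2, 0), role = "distribution",
                     behaviour = "versatile", stage = 0L)
    assign_flows(f)
    update_radii(f)
    f
  }
}

# Symmetric pre-existing initial forest for the concurrent-inlet scenarios:
# each equiradial inlet carries a small two-level tree that coarsely
# vascularises its half of the domain (the published scenario starts from a
# given initial tree; this synthetic stand-in anchors each inlet's
# territory with identical structure and reach).
.fx_two_inlet_init <- function(D) {
  function() {
    f <- vascular_forest(gamma = 3)
    half <- function(sgn, z = FALSE) {
      pad <- function(p) if (z) c(p, 0) else p
      r0 <- add_root_vessel(f, pad(c(sgn * 1, 0)), pad(c(sgn * 0.65, 0)),
                            radius = 0.05, inflow = 0.5)
      c1 <- add_child_vessel(f, r0, pad(c(sgn * 0.4, 0.3)))
      c2 <- add_child_vessel(f, r0, pad(c(sgn * 0.4, -0.3)))
      add_child_vessel(f, c1, pad(c(sgn * 0.15, 0.5)))
      add_child_vessel(f, c1, pad(c(sgn * 0.62, 0.62)))
      add_child_vessel(f, c2, pad(c(sgn * 0.15, -0.5)))
      add_child_vessel(f, c2, pad(c(sgn * 0.62, -0.62)))
    }
    half(-1, z = (D == 3))
    half(1, z = (D == 3))
    assign_flows(f)
    update_radii(f)
    f
  }
}

.fx_two_inlet_stages <- function(D, cost) {
  dom <- if (D == 2) disc_domain(radius = 1) else sphere_domain(radius = 1)
  co <- if (D == 2) sprout_coeffs(0.5e2, 0.5, 1.0) else sprout_coeffs(1e4, 0.5, 1.0)
  base <- function(budget, cost, coeffs)
    growth_stage(dom, budget, geo = geo_params(3, 0), opt = .fx_opt(nu = 1),
                 cost = cost, coeffs = coeffs)
  switch(cost,
         vol = list(base(1000, "vol", NULL)),
         sprout = list(base(1000, "sprout", co)),
         staged = list(base(25, "sprout", co),
                       base(975, "vol", NULL)))
}

.fixture_registry <- function() {
  reg <- list()
  add <- function(name, description, build) {
    reg[[name]] <<- list(description = description, build = build)
  }

  add("unit_disc", "classic single-stage growth in a unit disc (200 terminals)",
      function() {
        dom <- disc_domain(radius = 1)
        list(stages = list(growth_stage(
          dom, 200, geo = geo_params(3, 0), opt = .fx_opt(nu = 1),
          roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1))),
          init = NULL, domains = list(dom))
      })

  add("sequential_two_territories",
      "sequential growth of two disjoint discs from a pre-existing tree (budgets 800/1200)",
      function() {
        d1 <- disc_domain(center = c(-1.5, 0), radius = 1, label = "territory_1")
        d2 <- disc_domain(center = c(1.5, 0), radius = 1, label = "territory_2")
        st <- function(dom, budget)
          growth_stage(dom, budget, geo = geo_params(3, 0),
                       opt = .fx_opt(nu = 1.5))
        list(stages = list(st(d1, 800), st(d2, 1200)),
             init = .fx_sequential_init, domains = list(d1, d2))
      })

  add("hierarchical_annulus_disc",
      "hierarchical growth: annulus stage then full-disc stage (budgets 50/1950)",
      function() {
        ann <- annulus_domain(inner = 0.5, outer = 1)
        full <- disc_domain(radius = 1)
        list(stages = list(
          growth_stage(ann, 50, geo = geo_params(3, 0), opt = .fx_opt(nu = 1),
                       roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1)),
          growth_stage(full, 1950, geo = geo_params(3, 0),
                       opt = .fx_opt(nu = 1))),
          init = NULL, domains = list(ann, full))
      })

  add("scale_specific_disc",
      "scale-specific growth in a disc with symmetry bounds 0.7/0.5/0.2 (budgets 50/450/1500)",
      function() {
        dom <- disc_domain(radius = 1)
        st <- function(budget, delta, roots = NULL)
          growth_stage(dom, budget, geo = geo_params(3, delta),
                       opt = .fx_opt(nu = 1.5), roots = roots)
        list(stages = list(
          st(50, 0.7, root_spec(c(-1, 0), radius = 0.05, inflow = 1)),
          st(450, 0.5), st(1500, 0.2)),
          init = NULL, domains = list(dom))
      })

  add("two_inlet_disc_vol",
      "concurrent growth from two opposite inlets, volumetric cost (1000 terminals)",
      function() list(stages = .fx_two_inlet_stages(2, "vol"),
                      init = .fx_two_inlet_init(2),
                      domains = list(disc_domain(radius = 1))))
  add("two_inlet_disc_sprout",
      "concurrent growth from two opposite inlets, sprouting cost (1000 terminals)",
      function() list(stages = .fx_two_inlet_stages(2, "sprout"),
                      init = .fx_two_inlet_init(2),
                      domains = list(disc_domain(radius = 1))))
  add("two_inlet_disc_staged",
      "concurrent growth from two opposite inlets: 25 sprouting + 975 volumetric terminals",
      function() list(stages = .fx_two_inlet_stages(2, "staged"),
                      init = .fx_two_inlet_init(2),
                      domains = list(disc_domain(radius = 1))))
  add("two_inlet_sphere_staged",
      "3D concurrent growth in a sphere from two inlets: 25 sprouting + 975 volumetric",
      function() list(stages = .fx_two_inlet_stages(3, "staged"),
                      init = .fx_two_inlet_init(3),
                      domains = list(sphere_domain(radius = 1))))

  add("gaussian_disc",
      "unit disc with Gaussian placement density, mean (0,0), sd (0.25,0.25)",
      function() {
        dom <- disc_domain(radius = 1)
        list(stages = list(growth_stage(
          dom, 1000, geo = geo_params(3, 0), opt = .fx_opt(nu = 1),
          density = gaussian_density(c(0, 0), c(0.25, 0.25)),
          roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1))),
          init = NULL, domains = list(dom))
      })

  add("gaussian_mixture_disc",
      "unit disc with a two-component Gaussian mixture placement density",
      function() {
        dom <- disc_domain(radius = 1)
        dens <- mixture_density(means = list(c(0, 0.5), c(0, -0.5)),
                                sds = list(c(0.25, 0.25), c(0.10, 0.10)),
                                weights = c(0.5, 0.5))
        list(stages = list(growth_stage(
          dom, 1000, geo = geo_params(3, 0), opt = .fx_opt(nu = 1),
          density = dens,
          roots = root_spec(c(-1, 0), radius = 0.05, inflow = 1))),
          init = NULL, domains = list(dom))
      })

  outlet_fx <- function(fraction, what) {
    function() {
      dom <- disc_domain(radius = 1)
      list(stages = list(growth_stage(dom, 200, geo = geo_params(3, 0),
                                      opt = .fx_opt(nu = 1))),
           init = .fx_outlet_init(fraction), domains = list(dom))
    }
  }
  add("outlet_unconstrained",
      "disc with a distal artery leaving the domain, outflow unconstrained (200 terminals)",
      outlet_fx(NA_real_))
  add("outlet_half",
      "disc with a distal artery constrained to 0.5 Q (200 terminals)",
      outlet_fx(0.5))
  add("outlet_099",
      "disc with a distal artery constrained to 0.99 Q (200 terminals)",
      outlet_fx(0.99))

  reg
}
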