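# small forest builders used across the test files

# single root vessel in the unit disc, converged
one_vessel_forest <- function(r1 = 0.05, Q = 1) {
  f <- vascular_forest(gamma = 3)
  add_root_vessel(f, c(-1, 0), c(0, 0), radius = r1, inflow = Q)
  assign_flows(f)
  update_radii(f)
  f
}

# symmetric one-level bifurcation: equal child lengths and flows
symmetric_bifurcation <- function(r1 = 0.05, Q = 1, eta = 3.6) {
  f <- vascular_forest(gamma = 3)
  add_root_vessel(f, c(0, 0), c(0, 1), radius = r1, inflow = Q)
  add_child_vessel(f, 1, c(-0.5, 1.5))
  add_child_vessel(f, 1, c(0.5, 1.5))
  assign_flows(f)
  update_radii(f, constant_viscosity = eta)
  f
}

# grow a small tree in the unit disc through the engine
grown_disc_forest <- function(n_terminals, seed = 1, delta = 0,
                              outlet_fraction = NULL) {
  set.seed(seed)
  f <- vascular_forest(gamma = 3)
  if (!is.null(outlet_fraction) && !is.na(outlet_fraction)) {
    f <- (vasctree::fixture("outlet_half")$init)()
    set_outlet(f, 2, outlet_fraction)
    assign_flows(f)
    update_radii(f)
  }
  st <- growth_stage(disc_domain(radius = 1), n_terminals,
                     geo = geo_params(3, delta),
                     opt = opt_params(nu = 1, f_r = 0.9, f_n = 8, delta_v = 7),
                     roots = if (is.null(outlet_fraction))
                       root_spec(c(-1, 0), 0.05, 1))
  grow_stage(f, st)
  f
}

# random micro-instance for oracle-equivalence tests: a tree grown to
# k terminals plus a freshly sampled terminal point
micro_instance <- function(seed, k = NULL) {
  set.seed(seed)
  if (is.null(k)) k <- sample(1:4, 1)
  dom <- disc_domain(radius = 1)
  st <- growth_stage(dom, k, geo = geo_params(3, 0),
                     opt = opt_params(nu = 1, delta_v = 5),
                     roots = root_spec(c(-1, 0), 0.05, 1))
  f <- vascular_forest(gamma = 3)
  grow_stage(f, st)
  x <- sample_point(dom)[1, ]
  while (min_point_distance(f, x)$distance <
           distance_threshold(n_terminals(f), 1, 2)) {
    x <- sample_point(dom)[1, ]
  }
  list(forest = f, stage = st, x = x[1:2])
}

make_cube_stl <- function(path) {
  # unit cube as 12 ASCII STL facets
  v <- list(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
            c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tris <- list(c(1,3,2), c(1,4,3), c(5,6,7), c(5,7,8),
               c(1,2,6), c(1,6,5), c(2,3,7), c(2,7,6),
               c(3,4,8), c(3,8,7), c(4,1,5), c(4,5,8))
  con <- file(path, "w")
  writeLines("solid cube", con)
  for (t in tris) {
    writeLines("facet normal 0 0 0", con)
    writeLines("outer loop", con)
    for (k in t) writeLines(sprintf("vertex %g %g %g",
                                    v[[k]][1], v[[k]][2], v[[k]][3]), con)
    writeLines("endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid cube", con)
  close(con)
  path
}

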