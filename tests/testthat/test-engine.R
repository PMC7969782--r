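test_that("the minimum-distance threshold follows the perfusion scaling", {
  expect_equal(distance_threshold(0, 1, 2, nu = 1), 1)
  expect_equal(distance_threshold(7, 1, 3, nu = 1), 0.5)     # (1/8)^(1/3)
  expect_equal(distance_threshold(0, 1, 2, nu = 1, relaxation = 0.9^2),
               0.81)
  expect_equal(distance_threshold(3, 2, 2, nu = 2), 2 * sqrt(2 / 4))
})

test_that("the candidate lattice has the prescribed size and restrictions", {
  xt <- c(0.3, 0.6); xp <- c(-1, 0); xd <- c(0, 0)
  expect_equal(nrow(candidate_lattice(xt, xp, xd, 6)), 18)   # 21 - 3
  expect_equal(nrow(candidate_lattice(xt, xp, xd, 7)), 25)   # 28 - 3
  expect_equal(nrow(candidate_lattice(xt, xp, xd, 7, "non-branching")), 0)
  # fixed behaviour: only points on the vessel axis
  pts <- candidate_lattice(xt, xp, xd, 7, "fixed")
  expect_equal(nrow(pts), 5)                                 # dv - 2
  expect_true(all(abs(pts[, 2]) < 1e-14))                    # on the x-axis
  # distal behaviour: the single distal point
  pts <- candidate_lattice(xt, xp, xd, 7, "distal")
  expect_equal(nrow(pts), 1)
  expect_equal(pts[1, ], c(0, 0, 0))
  # degenerate (collinear) triangle falls back to the axis
  pts <- candidate_lattice(c(0.5, 0), xp, xd, 7, "versatile")
  expect_true(all(abs(pts[, 2]) < 1e-14))
  # vertices are excluded
  pts <- candidate_lattice(xt, xp, xd, 7)
  expect_false(any(apply(pts, 1, function(p) all(p == c(xt, 0)))))
  expect_false(any(apply(pts, 1, function(p) all(p == c(xp, 0)))))
})

test_that("best_connection matches the exhaustive full-recompute oracle", {
  # small version of the oracle-equivalence property; the acceptance suite
  # runs it over 50 instances
  agree <- 0
  for (sd in 1:8) {
    mi <- micro_instance(100 + sd)
    eng <- best_connection(mi$forest, mi$stage, mi$x)
    orc <- orc_best_connection(mi$forest, mi$stage, mi$x)
    expect_equal(is.null(orc), !isTRUE(eng$found))
    if (!is.null(orc)) {
      expect_equal(eng$vessel, orc$vessel)
      expect_equal(eng$x_b, orc$x_b, tolerance = 1e-12)
      agree <- agree + 1
    }
  }
  expect_gt(agree, 4)  # most instances admit a connection
})

test_that("root creation respects containment and the aspect constraint", {
  set.seed(41)
  f <- vascular_forest()
  st <- growth_stage(annulus_domain(inner = 0.5, outer = 1), 1)
  id <- create_root(f, st, root_spec(c(-1, 0), 0.03, 1))
  v <- vessels(f)
  expect_equal(id, 1)
  expect_gt(v$length[1] / v$radius[1], 2)
  expect_true(segment_in_domain(st$domain, c(v$xp_x[1], v$xp_y[1]),
                                c(v$xd_x[1], v$xd_y[1])))
  # a domain too small for the aspect ratio at this root radius fails
  g <- vascular_forest()
  tiny <- growth_stage(disc_domain(radius = 0.04), 1,
                       opt = opt_params(max_attempts = 2000))
  expect_error(create_root(g, tiny, root_spec(c(-0.04, 0), 0.05, 1)),
               "attempt budget")
})

test_that("stage budgets are honoured exactly", {
  set.seed(42)
  f <- vascular_forest()
  st <- growth_stage(disc_domain(radius = 1), 1,
                     roots = root_spec(c(-1, 0), 0.05, 1))
  grow_stage(f, st)
  expect_equal(n_terminals(f), 2)          # root tip + one new terminal
  expect_true(n_vessels(f) %in% c(2, 3))
  n0 <- n_vessels(f)
  zero <- growth_stage(disc_domain(radius = 1), 0)
  grow_stage(f, zero)
  expect_equal(n_vessels(f), n0)           # budget 0 is the identity
})

test_that("runs are reproducible bit-for-bit from (config, seed)", {
  run <- function() {
    set.seed(77)
    f <- vascular_forest()
    st <- growth_stage(disc_domain(radius = 1), 40,
                       roots = root_spec(c(-1, 0), 0.05, 1))
    grow_stage(f, st)
    vessels(f)
  }
  expect_identical(run(), run())
})

test_that("relaxation shrinks the threshold until sampling succeeds", {
  # nu far above 1 makes the initial threshold larger than the domain, so
  # terminals are only accepted after relaxation steps
  set.seed(43)
  f <- vascular_forest()
  st <- growth_stage(disc_domain(radius = 1), 3,
                     opt = opt_params(nu = 50, f_r = 0.9, n_fail = 20),
                     roots = root_spec(c(-1, 0), 0.05, 1))
  log <- grow_stage(f, st)
  expect_equal(log$terminals_added, 3)
  expect_gt(log$relaxations, 0)
})

test_that("stage labels and vessel typing are recorded on creation", {
  set.seed(44)
  res <- run_stages(list(
    growth_stage(disc_domain(radius = 1), 10,
                 roots = root_spec(c(-1, 0), 0.05, 1)),
    growth_stage(disc_domain(radius = 1), 10, role = "perforator")))
  v <- vessels(res$forest)
  expect_setequal(unique(v$stage), c(1, 2))
  expect_equal(sum(v$stage == 2 & v$terminal & v$role == "perforator"), 10)
})

test_that("parent-stage restriction confines eligible target vessels", {
  set.seed(45)
  f <- vascular_forest()
  s1 <- growth_stage(disc_domain(radius = 1), 10,
                     roots = root_spec(c(-1, 0), 0.05, 1))
  grow_stage(f, s1)
  v1 <- vessels(f)
  s2 <- growth_stage(disc_domain(radius = 1), 10, seed_stages = 1,
                     label = 2)
  grow_stage(f, s2)
  v2 <- vessels(f)
  # every stage-2 terminal's proximal junction lies on a (split piece of a)
  # stage-1 vessel, never on the pre-existing stage-0 root
  new_term <- v2$id[v2$stage == 2 & v2$terminal]
  for (i in new_term) expect_gt(v2$stage[v2$parent[i]], 0)
})
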