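test_that("Murray's law check accepts exact power-law triples", {
  expect_true(check_murray(5, 3, 4, gamma = 2)$ok)       # 25 = 9 + 16
  expect_equal(check_murray(2^(1 / 3), 1, 1, gamma = 3)$residual, 0,
               tolerance = 1e-12)
  expect_false(check_murray(1, 1, 1, gamma = 3)$ok)
})

test_that("symmetry and aspect checks implement strict inequalities", {
  expect_true(check_symmetry(1, 5, delta = 0))           # vacuous bound
  expect_true(check_symmetry(1, 1, delta = 0.99))
  expect_false(check_symmetry(1, 0.3, delta = 0.4))
  expect_true(check_aspect(2.1, 1))
  expect_false(check_aspect(2, 1))                       # strict
  expect_true(check_aspect(1e-3, 1e-4))                  # scale invariant
})

test_that("bifurcation angles are robust at the arccos boundaries", {
  expect_equal(bifurcation_angle(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(bifurcation_angle(c(0, 0), c(1, 0), c(2, 0)), 0)
  # nearly antiparallel arms must not produce NaN from acos
  th <- bifurcation_angle(c(0, 0, 0), c(1, 0, 0), c(-1, 1e-16, 0))
  expect_false(is.nan(th))
  expect_equal(th, 180, tolerance = 1e-6)
  expect_error(bifurcation_angle(c(0, 0), c(0, 0), c(1, 0)), "zero-length")
})

test_that("opening angle measures elevation from the bifurcation plane", {
  # plane spanned by v_p (towards (-1,0,0)) and v_s (towards (1,0,0)) is
  # degenerate; use a bent configuration in the x-y plane
  xb <- c(0, 0, 0); xp <- c(-1, 0.2, 0); xd <- c(1, 0, 0)
  expect_equal(opening_angle(xb, xp, xd, c(0.5, 0.5, 0)), 0,
               tolerance = 1e-9)                          # in-plane
  expect_equal(opening_angle(xb, xp, xd, c(0, 0, 1)), 90,
               tolerance = 1e-9)                          # along the normal
  expect_error(opening_angle(xb, c(-1, 0, 0), xd, c(0, 1, 0)), "collinear")
  # random configurations agree with an independent projection construction
  set.seed(21)
  for (k in 1:20) {
    xp <- rnorm(3); xd <- rnorm(3); xt <- rnorm(3)
    nvec <- c((xd[2]) * (xp[3]) - (xd[3]) * (xp[2]),
              (xd[3]) * (xp[1]) - (xd[1]) * (xp[3]),
              (xd[1]) * (xp[2]) - (xd[2]) * (xp[1]))
    if (sqrt(sum(nvec^2)) < 1e-6) next
    v <- xt
    proj <- v - sum(v * nvec) / sum(nvec^2) * nvec        # onto the plane
    ang <- acos(min(1, sum(v * proj) / sqrt(sum(v^2) * sum(proj^2)))) * 180 / pi
    expect_equal(opening_angle(c(0, 0, 0), xp, xd, xt), ang, tolerance = 1e-6)
  }
})

test_that("the admissibility gate applies eligibility and containment", {
  f <- one_vessel_forest()
  st <- growth_stage(disc_domain(radius = 1), 5)
  # vacuous gate accepts an easy interior candidate
  res <- admissible(f, st, 1, c(-0.5, 0), c(-0.3, 0.4))
  expect_true(res$admissible)
  # non-branching parent vessel is never eligible
  g <- vascular_forest()
  add_root_vessel(g, c(-1, 0), c(0, 0), 0.05, 1, behaviour = "non-branching")
  assign_flows(g); update_radii(g)
  res <- admissible(g, st, 1, c(-0.5, 0), c(-0.3, 0.4))
  expect_false(res$admissible)
  expect_equal(res$reason, "eligibility")
  # distribution vessel cannot host a bifurcation outside the domain
  h <- vascular_forest()
  add_root_vessel(h, c(-2, 0), c(0, 0), 0.05, 1)
  assign_flows(h); update_radii(h)
  res <- admissible(h, st, 1, c(-1.5, 0), c(-1.4, 0.3))
  expect_false(res$admissible)
  expect_equal(res$reason, "role-containment")
})

test_that("angle windows gate candidates during growth", {
  set.seed(31)
  f <- vascular_forest()
  st <- growth_stage(disc_domain(radius = 1), 30,
                     angles = angle_params(theta_min = 40),
                     roots = root_spec(c(-1, 0), 0.05, 1))
  grow_stage(f, st)
  v <- vessels(f)
  # re-measure every generated bifurcation angle post hoc
  for (i in v$id[v$n_children == 2]) {
    ch <- children_of(f, i)
    gen <- ch[v$stage[ch] > 0 & v$terminal[ch]]
    if (length(gen) == 0) next
    xb <- c(v$xd_x[i], v$xd_y[i], 0)
    th <- bifurcation_angle(xb, c(v$xd_x[ch[1]], v$xd_y[ch[1]], 0),
                            c(v$xd_x[ch[2]], v$xd_y[ch[2]], 0))
    expect_gt(th, 40)
    expect_lt(th, 140)
  }
})

test_that("a grown forest passes the full post-hoc constraint audit", {
  f <- grown_disc_forest(60, seed = 22)
  a <- audit_forest(f, domain = disc_domain(radius = 1), gamma = 3, delta = 0)
  expect_true(a$ok)
  expect_true(all(a$bifurcations$murray_residual < 1e-6))
  expect_null(a$intersections)
  expect_gt(a$min_aspect, 2)
})
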