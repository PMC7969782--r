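test_that("viscosity law matches its large-radius limit and direct formula", {
  # the exponential terms vanish and kappa tends to 1, so eta tends to
  # 1.125 * 3.2 = 3.6 cP; at r = 10 mm kappa is still 1.00011
  expect_equal(blood_viscosity(1e4), 1.125 * (1 + 2.2), tolerance = 1e-6)
  expect_equal(blood_viscosity(10), 1.125 * (1 + 2.2), tolerance = 1e-3)
  # independent evaluation of the formula at an arteriolar radius
  r <- 0.1
  kap <- (r / (r - 5.5e-4))^2
  eta <- 1.125 * (kap + kap^2 * (6 * exp(-170 * r) -
                                   2.44 * exp(-8.09 * r^0.64) + 2.2))
  expect_equal(blood_viscosity(0.1), eta, tolerance = 1e-12)
  expect_error(blood_viscosity(5.5e-4), "5.5e-4")
  expect_error(blood_viscosity(1e-4))
})

test_that("Poiseuille resistance scales with the fourth power of radius", {
  R0 <- poiseuille_resistance(1, 1, 3.6)
  expect_equal(poiseuille_resistance(2, 1, 3.6), R0 / 16)
  expect_equal(poiseuille_resistance(1, 2, 3.6), 2 * R0)
  # constants cancel when eta (in cP) equals 1000 * pi / 8
  expect_equal(poiseuille_resistance(1, 1, 1000 * pi / 8), 1)
  expect_error(poiseuille_resistance(-1, 1, 3.6))
})

test_that("flow assignment splits the inflow across free terminals", {
  f <- vascular_forest()
  add_root_vessel(f, c(-1, 0), c(0, 0), 0.05, 1)
  insert_terminal(f, 1, c(-0.5, 0), c(-0.3, 0.4))
  insert_terminal(f, 1, c(-0.75, 0), c(-0.6, -0.4))
  insert_terminal(f, 2, c(-0.4, 0.2), c(-0.1, 0.3))
  assign_flows(f)
  v <- vessels(f)
  expect_equal(n_terminals(f), 4)
  expect_true(all(v$flow[v$terminal] == 0.25))          # equal split of Q
  expect_equal(v$flow[1], 1)
})

test_that("constrained outlets carry their fraction; the rest split equally", {
  f <- vascular_forest()
  add_root_vessel(f, c(-1, 0), c(0, 0), 0.05, 1)
  add_child_vessel(f, 1, c(0.5, 0.5), behaviour = "non-branching",
                   outlet_fraction = 0.5)
  add_child_vessel(f, 1, c(0.5, -0.5))
  # grow the free side to 5 free terminals
  for (k in 1:4) {
    v <- vessels(f)
    leaves <- v$id[v$terminal & !v$outlet]
    j <- leaves[length(leaves)]
    xb <- c((v$xp_x[j] + v$xd_x[j]) / 2, (v$xp_y[j] + v$xd_y[j]) / 2)
    insert_terminal(f, j, xb, xb + c(0.1, 0.12 * (-1)^k))
  }
  assign_flows(f)
  v <- vessels(f)
  free <- v$terminal & !v$outlet
  expect_equal(sum(free), 5)
  expect_true(all(abs(v$flow[free] - 0.1) < 1e-15))     # (1 - 0.5)/5 each
  expect_equal(v$flow[v$outlet], 0.5)

  g <- vascular_forest()
  add_root_vessel(g, c(-1, 0), c(0, 0), 0.05, 1)
  add_child_vessel(g, 1, c(0.5, 0.5), outlet_fraction = 0.6)
  add_child_vessel(g, 1, c(0.5, -0.5), outlet_fraction = 0.5)
  add_child_vessel(g, 1, c(0.5, 0))
  expect_error(assign_flows(g), "consume")
})

test_that("flow conservation at junctions is exact", {
  f <- grown_disc_forest(40, seed = 12)
  v <- vessels(f)
  for (i in v$id[v$n_children > 0]) {
    expect_identical(v$flow[i], sum(v$flow[children_of(f, i)]))
  }
})

test_that("symmetric bifurcation collapses to the Murray closed form", {
  f <- symmetric_bifurcation(r1 = 0.05, eta = 3.6)
  v <- vessels(f)
  expect_equal(v$radius[2], 0.05 * 2^(-1 / 3), tolerance = 1e-9)
  expect_equal(v$radius[3], 0.05 * 2^(-1 / 3), tolerance = 1e-9)
})

test_that("a single vessel keeps its root radius and converges at once", {
  f <- vascular_forest()
  add_root_vessel(f, c(-1, 0), c(0, 0), 0.05, 1)
  assign_flows(f)
  update_radii(f, max_iter = 50)
  expect_equal(vessels(f)$radius, 0.05)
})

test_that("the radius fixed point is stable: re-running stays put", {
  f <- grown_disc_forest(30, seed = 13)
  assign_flows(f); update_radii(f, tol = 1e-10, max_iter = 300)
  r1 <- vessels(f)$radius
  update_radii(f, tol = 1e-10, max_iter = 300)
  r2 <- vessels(f)$radius
  expect_equal(r2, r1, tolerance = 1e-9)
})

test_that("Murray's law holds at every bifurcation of a converged tree", {
  f <- grown_disc_forest(40, seed = 14)
  assign_flows(f); update_radii(f, tol = 1e-9, max_iter = 300)
  v <- vessels(f)
  for (i in v$id[v$n_children >= 2]) {
    rs <- v$radius[children_of(f, i)]
    expect_lt(abs(v$radius[i]^3 - sum(rs^3)) / v$radius[i]^3, 1e-6)
  }
})

test_that("terminal path pressure drops are equalised by the ratio rule", {
  f <- grown_disc_forest(50, seed = 15)
  assign_flows(f)
  update_radii(f, tol = 1e-8, max_iter = 300)
  dp <- terminal_path_drops(f)
  spread <- (max(dp$dp) - min(dp$dp)) / mean(dp$dp)
  expect_lt(spread, 10 * 1e-8 * 1e4)  # tol amplified through R ~ r^-4 paths
  expect_lt(spread, 1e-3)
  # series law: the path drop equals the sum of per-vessel drops
  v <- vessels(f)
  one <- dp$id[1]
  acc <- 0; i <- one
  pd <- pressure_drops(f)
  while (!is.na(i)) { acc <- acc + pd$dp[i]; i <- v$parent[i] }
  expect_equal(acc, dp$dp[dp$id == one], tolerance = 1e-12)
})

test_that("radii respond monotonically to outlet constraints", {
  build <- function(frac) {
    f <- vascular_forest()
    add_root_vessel(f, c(-1, 0), c(-0.4, 0), 0.05, 1)
    add_child_vessel(f, 1, c(-0.1, 0.6), behaviour = "non-branching",
                     outlet_fraction = frac)
    add_child_vessel(f, 1, c(0.2, 0))
    insert_terminal(f, 3, c(-0.1, 0), c(0.1, 0.4))
    insert_terminal(f, 3, c(-0.25, 0), c(0, -0.45))
    assign_flows(f); update_radii(f, tol = 1e-9, max_iter = 300)
    vessels(f)
  }
  fr <- c(0.1, 0.3, 0.5, 0.8)
  rads <- lapply(fr, build)
  # all non-outlet-side radii weakly decrease as the diverted fraction rises
  nonout <- which(!rads[[1]]$outlet)
  nonout <- setdiff(nonout, 1)  # root radius is fixed
  for (k in 2:length(fr)) {
    expect_true(all(rads[[k]]$radius[nonout] <=
                      rads[[k - 1]]$radius[nonout] + 1e-12))
  }
})

test_that("incremental candidate evaluation matches a full recomputation", {
  f <- grown_disc_forest(15, seed = 16)
  assign_flows(f); update_radii(f)
  v <- vessels(f)
  qf <- v$flow[v$terminal & !v$outlet][1]
  set.seed(17)
  for (k in 1:10) {
    j <- sample(v$id, 1)
    xb <- c((v$xp_x[j] + v$xd_x[j]) / 2, (v$xp_y[j] + v$xd_y[j]) / 2, 0)
    xt <- xb + c(runif(1, 0.05, 0.2), runif(1, 0.05, 0.2), 0)
    inc <- vt_eval_candidate(f$ptr, j, xb, xt, FALSE, 1L, TRUE)
    # full recomputation: rebuild the candidate tree with the same frozen
    # per-vessel viscosities and the frozen terminal outflow (realised by
    # scaling the root inflow so the equal split reproduces the old q_f)
    h <- insert_terminal(f, j, xb[1:2], xt[1:2])
    tab <- forest_to_table(f, canonical = FALSE)
    eta <- vessels(f)$viscosity
    # the engine freezes the viscosity of the whole trio at eta(v_j)
    eta[c(h$v_p, h$v_s, h$v_new)] <- v$viscosity[j]
    rollback_insertion(f, h)
    nT <- sum(!(tab$id %in% tab$parent))
    tab$root_inflow[!is.na(tab$root_inflow)] <- qf * nT
    tab$length <- sqrt((tab$xd_x - tab$xp_x)^2 + (tab$xd_y - tab$xp_y)^2 +
                       (tab$xd_z - tab$xp_z)^2)
    tab$flow <- orc_flows(tab)
    full <- orc_radii(tab, gamma = 3, eta_fixed = eta)
    root_row <- which(is.na(tab$parent))
    expect_equal(inc$Rstar_root, full$Rstar[root_row], tolerance = 1e-10)
    vol_factor <- full$volume / (pi * tab$root_radius[root_row]^2)
    expect_equal(inc$Vstar_root, vol_factor, tolerance = 1e-10)
  }
})
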