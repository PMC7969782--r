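test_that("terminal insertion splits the target and rollback is bit-identical", {
  f <- one_vessel_forest()
  before <- vessels(f)
  h <- insert_terminal(f, 1, c(-0.5, 0), c(-0.3, 0.4))
  expect_equal(n_vessels(f), 3)
  expect_equal(n_terminals(f), 2)
  v <- vessels(f)
  # v_s inherits the distal endpoint, v_p keeps the parent link
  expect_equal(v$parent[h$v_s], h$v_p)
  expect_equal(v$parent[h$v_new], h$v_p)
  expect_identical(c(v$xd_x[h$v_p], v$xd_y[h$v_p]), c(-0.5, 0))
  rollback_insertion(f, h)
  expect_identical(vessels(f), before)
})

test_that("repeated insert/rollback pairs leave the forest unchanged", {
  f <- grown_disc_forest(10, seed = 5)
  assign_flows(f); update_radii(f)
  before <- vessels(f)
  set.seed(11)
  for (k in 1:10) {
    j <- sample(n_vessels(f), 1)
    v <- vessels(f)
    xb <- c((v$xp_x[j] + v$xd_x[j]) / 2, (v$xp_y[j] + v$xd_y[j]) / 2)
    h <- insert_terminal(f, j, xb, xb + c(0.05, 0.07))
    assign_flows(f); update_radii(f)
    rollback_insertion(f, h)
  }
  expect_identical(vessels(f), before)
})

test_that("distal-behaviour attachment appends a child without splitting", {
  f <- vascular_forest()
  add_root_vessel(f, c(-1, 0), c(0, 0), 0.05, 1, behaviour = "distal")
  h <- insert_terminal(f, 1, c(0, 0), c(0.4, 0.3))
  expect_equal(n_vessels(f), 2)
  expect_equal(vessels(f)$n_children[1], 1)
  expect_true(is.na(h$v_s))
  # a second distal attachment makes a true bifurcation at the same junction
  insert_terminal(f, 1, c(0, 0), c(0.4, -0.3))
  expect_equal(vessels(f)$n_children[1], 2)
  expect_error(insert_terminal(f, 1, c(-0.5, 0), c(0, 0.5)),
               "distal point")
})

test_that("split inheritance: roles, behaviours and outlet identity move to v_s", {
  f <- vascular_forest()
  add_root_vessel(f, c(-1, 0), c(0, 0), 0.05, 1, role = "transport",
                  behaviour = "versatile")
  add_child_vessel(f, 1, c(0.5, 0.5), role = "transport",
                   behaviour = "non-branching", outlet_fraction = 0.3)
  add_child_vessel(f, 1, c(0.5, -0.5))
  assign_flows(f)
  h <- insert_terminal(f, 1, c(-0.5, 0), c(-0.2, 0.4))
  v <- vessels(f)
  expect_equal(v$role[h$v_s], "transport")       # v_s inherits the role
  expect_equal(v$role[h$v_p], "transport")       # v_p keeps it, now versatile
  expect_equal(v$behaviour[h$v_p], "versatile")
  expect_equal(v$n_children[h$v_s], 2)           # children re-parented
  # splitting a non-branching vessel keeps both halves non-branching
  f2 <- vascular_forest()
  add_root_vessel(f2, c(-1, 0), c(0, 0), 0.05, 1, behaviour = "non-branching")
  h2 <- insert_terminal(f2, 1, c(-0.5, 0), c(-0.2, 0.4))
  v2 <- vessels(f2)
  expect_equal(v2$behaviour[h2$v_p], "non-branching")
  expect_equal(v2$behaviour[h2$v_s], "non-branching")
})

test_that("neighbourhood queries agree with a brute-force scan", {
  f <- grown_disc_forest(25, seed = 2)
  v <- vessels(f)
  expect_setequal(neighbourhood(f, c(0, 0), 1e6), v$id)
  expect_length(neighbourhood(f, c(50, 50), 0.5), 0)
  set.seed(9)
  for (k in 1:50) {
    x <- c(runif(2, -1.2, 1.2), 0)
    rad <- runif(1, 0.05, 0.8)
    brute <- v$id[vapply(v$id, function(i)
      orc_dist_point_seg(x, c(v$xp_x[i], v$xp_y[i], v$xp_z[i]),
                         c(v$xd_x[i], v$xd_y[i], v$xd_z[i])) <= rad,
      logical(1))]
    expect_setequal(neighbourhood(f, x, rad), brute)
  }
})

test_that("min_point_distance finds interior closest points", {
  f <- vascular_forest()
  add_root_vessel(f, c(0, 0), c(0, 1), 0.05, 1)
  expect_equal(min_point_distance(f, c(1, 0.5))$distance, 1)
  expect_equal(min_point_distance(f, c(0, 0.3))$distance, 0)
  g <- grown_disc_forest(15, seed = 3)
  v <- vessels(g)
  set.seed(4)
  for (k in 1:50) {
    x <- c(runif(2, -1, 1), 0)
    brute <- min(vapply(v$id, function(i)
      orc_dist_point_seg(x, c(v$xp_x[i], v$xp_y[i], v$xp_z[i]),
                         c(v$xd_x[i], v$xd_y[i], v$xd_z[i])), numeric(1)))
    expect_equal(min_point_distance(g, x)$distance, brute, tolerance = 1e-12)
  }
  expect_error(min_point_distance(vascular_forest(), c(0, 0)), "empty")
})

test_that("bifurcation levels count true bifurcations only", {
  f <- vascular_forest()
  add_root_vessel(f, c(0, 0), c(0, 1), 0.05, 1)
  expect_equal(bifurcation_level(f, 1), 0)
  # unary chain (tortuous vessel): two links, no level increment
  add_child_vessel(f, 1, c(0.1, 2))
  add_child_vessel(f, 2, c(0, 3))
  expect_equal(bifurcation_level(f, 3), 0)
  # true bifurcation below the chain
  add_child_vessel(f, 3, c(-0.5, 4))
  add_child_vessel(f, 3, c(0.5, 4))
  expect_equal(bifurcation_level(f, 4), 1)
  expect_equal(bifurcation_level(f, 5), 1)
})

test_that("terminal flows sum to the root inflows exactly", {
  f <- grown_disc_forest(30, seed = 6)
  v <- vessels(f)
  expect_lt(abs(sum(v$flow[v$terminal]) - sum(forest_roots(f)$inflow)) /
              sum(forest_roots(f)$inflow), 1e-12)
})

test_that("interchange tables reject malformed records", {
  f <- grown_disc_forest(5, seed = 8)
  tab <- forest_to_table(f)
  bad <- tab
  bad$parent[nrow(bad)] <- 9999
  expect_error(forest_from_table(bad),
               paste0("unresolvable parent id.*", bad$id[nrow(bad)]))
  dup <- rbind(tab, tab[nrow(tab), ])
  expect_error(forest_from_table(dup), "duplicate")
})
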