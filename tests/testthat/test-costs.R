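test_that("tree volume is the cylinder-volume sum", {
  f <- vascular_forest()
  add_root_vessel(f, c(0, 0), c(0, 1), 1, 1)  # l = 1, r fixed at 1
  assign_flows(f); update_radii(f)
  expect_equal(tree_volume(f), pi, tolerance = 1e-12)
  g <- grown_disc_forest(30, seed = 23)
  v <- vessels(g)
  expect_equal(tree_volume(g), sum(v$length * pi * v$radius^2),
               tolerance = 1e-15)
  # compiled-path total agrees with the table sum
  expect_equal(vt_total_volume(g$ptr), tree_volume(g), tolerance = 1e-12)
})

test_that("delta_volume is deterministic and restores the forest", {
  f <- grown_disc_forest(12, seed = 24)
  assign_flows(f); update_radii(f)
  before <- vessels(f)
  d1 <- delta_volume(f, 1, c(-0.7, 0), c(-0.5, 0.35))
  d2 <- delta_volume(f, 1, c(-0.7, 0), c(-0.5, 0.35))
  expect_identical(d1, d2)
  expect_identical(vessels(f), before)
  expect_gt(d1, 0)
})

test_that("farther terminals cost more volume than nearer ones", {
  f <- one_vessel_forest()
  near <- delta_volume(f, 1, c(-0.5, 0), c(-0.4, 0.3))
  far <- delta_volume(f, 1, c(-0.5, 0), c(-0.2, 0.75))
  expect_gt(far, near)
})

test_that("sprouting cost decomposes into its three mixture terms", {
  f <- grown_disc_forest(10, seed = 25)
  assign_flows(f); update_radii(f)
  dom <- disc_domain(radius = 1)
  v <- vessels(f)
  # pure-volume coefficients rank candidates exactly like delta_volume
  xts <- list(c(-0.6, 0.3), c(-0.3, 0.5))
  co_v <- sprout_coeffs(c_v = 1, c_p = 0, c_d = 0)
  sc <- vapply(xts, function(xt)
    sprout_cost(f, 1, c(-0.7, 0), xt, co_v), numeric(1))
  dv <- vapply(xts, function(xt)
    delta_volume(f, 1, c(-0.7, 0), xt), numeric(1))
  expect_equal(order(sc), order(dv))
  expect_equal(sc, dv / tree_volume(f), tolerance = 1e-9)
  # pure degradation term is increasing in the parent radius
  co_p <- sprout_coeffs(c_v = 0, c_p = 1, c_d = 0)
  thick <- v$id[which.max(v$radius)]
  thin <- v$id[v$terminal][which.min(v$radius[v$terminal])]
  xb_of <- function(j) c((v$xp_x[j] + v$xd_x[j]) / 2,
                         (v$xp_y[j] + v$xd_y[j]) / 2)
  c_thick <- sprout_cost(f, thick, xb_of(thick), xb_of(thick) + c(0.08, 0.1),
                         co_p)
  c_thin <- sprout_cost(f, thin, xb_of(thin), xb_of(thin) + c(0.08, 0.1),
                        co_p)
  expect_gt(c_thick, c_thin)
  # pure diffusion term is exactly quadratic in the new-vessel length
  co_d <- sprout_coeffs(c_v = 0, c_p = 0, c_d = 1)
  base <- c(-0.7, 0)
  c1 <- sprout_cost(f, 1, base, base + c(0.06, 0.08), co_d)
  c2 <- sprout_cost(f, 1, base, base + c(0.12, 0.16), co_d)
  expect_equal(c2 / c1, 4, tolerance = 1e-9)
})

test_that("sprouting coefficients are validated", {
  expect_error(sprout_coeffs(0, 0, 0))
  expect_error(sprout_coeffs(-1, 0.5, 1))
})
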