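test_that("point membership follows the closed-region convention", {
  disc <- disc_domain(radius = 1)
  expect_true(domain_contains(disc, c(0, 0)))
  expect_false(domain_contains(disc, c(2, 0)))
  expect_true(domain_contains(disc, c(1, 0)))          # boundary is inside
  ann <- annulus_domain(inner = 0.5, outer = 1)
  expect_false(domain_contains(ann, c(0, 0)))          # hole
  expect_true(domain_contains(ann, c(0.75, 0)))
  expect_error(domain_contains(disc, c(0, 0, 0.5)), "dimension")
  sph <- sphere_domain(radius = 1)
  expect_true(domain_contains(sph, c(0, 0, 0.99)))
  expect_false(domain_contains(sph, c(0, 0, 1.01)))
  shl <- shell_domain(inner = 0.5, outer = 1)
  expect_false(domain_contains(shl, c(0, 0, 0)))
  expect_true(domain_contains(shl, c(0, 0, 0.7)))
})

test_that("implicit-shape measures match closed forms", {
  expect_equal(domain_measure(disc_domain(radius = 2)), 4 * pi,
               tolerance = 1e-9)
  expect_equal(domain_measure(annulus_domain(inner = 0.5, outer = 1)),
               0.75 * pi, tolerance = 1e-9)
  expect_equal(domain_measure(sphere_domain(radius = 1)), 4 / 3 * pi,
               tolerance = 1e-9)
  expect_equal(domain_measure(shell_domain(inner = 0.5, outer = 1)),
               4 / 3 * pi * (1 - 0.125), tolerance = 1e-9)
  expect_equal(domain_measure(box_domain(c(0, 0, 0), c(2, 3, 4))), 24,
               tolerance = 1e-9)
})

test_that("characteristic length is the equivalent disc/sphere radius", {
  expect_equal(characteristic_length(disc_domain(radius = 1)), 1)
  expect_equal(characteristic_length(sphere_domain(radius = 1)), 1)
  expect_equal(characteristic_length(annulus_domain(inner = 0.5, outer = 1)),
               sqrt(0.75), tolerance = 1e-12)
  # invariance under rigid motion
  expect_equal(characteristic_length(disc_domain(center = c(7, -3), radius = 1)),
               characteristic_length(disc_domain(radius = 1)))
})

test_that("uniform sampling is unbiased and respects the domain", {
  set.seed(42)
  disc <- disc_domain(radius = 1)
  X <- sample_point(disc, n = 1e5)
  expect_true(all(X[, 1]^2 + X[, 2]^2 <= 1))
  expect_true(all(abs(colMeans(X)[1:2]) < 0.02))
  # Monte-Carlo area from the membership indicator matches the closed form
  U <- cbind(runif(1e5, -1, 1), runif(1e5, -1, 1), 0)
  phat <- mean(domain_contains(disc, U))
  se <- sqrt(phat * (1 - phat) / 1e5)
  expect_lt(abs(phat * 4 - pi), 3 * se * 4)
})

test_that("Gaussian placement density has the prescribed spread", {
  set.seed(7)
  disc <- disc_domain(radius = 1)
  X <- sample_point(disc, gaussian_density(c(0, 0), c(0.25, 0.25)), n = 1e5)
  expect_true(all(X[, 1]^2 + X[, 2]^2 <= 1))  # all draws inside by design
  # truncation at radius 1 removes ~ nothing at sigma 0.25
  expect_lt(abs(sd(X[, 1]) - 0.25) / 0.25, 0.05)
  expect_lt(abs(sd(X[, 2]) - 0.25) / 0.25, 0.05)
})

test_that("degenerate densities fail with an acceptance-floor error", {
  disc <- disc_domain(radius = 1)
  expect_error(sample_point(disc, function_density(function(x) 0, pmax = 1),
                            floor = 1e-3),
               "acceptance rate")
  # density concentrated far outside the domain
  expect_error(sample_point(disc, gaussian_density(c(50, 50), c(0.1, 0.1)),
                            floor = 1e-4),
               "acceptance rate")
})

test_that("segment containment samples interior points", {
  disc <- disc_domain(radius = 1)
  ann <- annulus_domain(inner = 0.5, outer = 1)
  expect_true(segment_in_domain(disc, c(-0.5, 0), c(0.5, 0)))
  expect_false(segment_in_domain(ann, c(-0.8, 0), c(0.8, 0), n_checks = 9))
  expect_true(segment_in_domain(disc, c(0.3, 0.3), c(0.3, 0.3)))  # degenerate
  expect_error(segment_in_domain(disc, c(0, 0), c(1, 0), n_checks = 1))
})

test_that("mesh domains: membership by ray casting, volume by divergence", {
  stl <- make_cube_stl(tempfile(fileext = ".stl"))
  dom <- mesh_domain(path = stl)
  expect_equal(domain_measure(dom), 1, tolerance = 1e-9)
  expect_true(domain_contains(dom, c(0.5, 0.5, 0.5)))
  expect_false(domain_contains(dom, c(1.5, 0.5, 0.5)))
  expect_false(domain_contains(dom, c(-0.01, 0.5, 0.5)))
  set.seed(3)
  X <- sample_point(dom, n = 2000)
  expect_true(all(X >= -1e-12 & X <= 1 + 1e-12))
})

test_that("extruded shells keep points within the offset band of a surface", {
  stl <- make_cube_stl(tempfile(fileext = ".stl"))
  m <- read_surface_mesh(stl)
  dom <- extruded_shell_domain(vertices = m$vertices, faces = m$faces,
                               inward = 0.2, outward = 0.2)
  expect_true(domain_contains(dom, c(0.5, 0.5, 0.1)))    # 0.1 inside surface
  expect_true(domain_contains(dom, c(0.5, 0.5, -0.1)))   # 0.1 outside
  expect_false(domain_contains(dom, c(0.5, 0.5, 0.5)))   # deep interior
  expect_false(domain_contains(dom, c(0.5, 0.5, -0.5)))  # far outside
})
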