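test_that("border-zone annulus has the analytic area and half-open bounds", {
  m <- suite_mesh02()
  A <- element_areas(m)
  bz <- m$region == "border_zone"
  expect_lt(abs(sum(A[bz]) - pi * (7^2 - 5^2)) / (pi * (7^2 - 5^2)), 0.02)
  cc <- element_centroids(m)
  r <- sqrt((cc[, 1L] - 15)^2 + (cc[, 2L] - 15)^2)
  expect_true(all(r[bz] > 5 & r[bz] <= 7))
  expect_true(all(r > 5))                      # the hole is real
  expect_true(all(r[!bz] > 7))
  expect_setequal(unique(m$region), c("healthy", "border_zone"))
})

test_that("mesh resolution and connectivity match the request", {
  m <- suite_mesh02()
  expect_lt(abs(mean_edge_length(m) - 0.2) / 0.2, 0.1)
  expect_identical(bzep:::cpp_n_components(m$elements, nrow(m$nodes)), 1L)
  # no node strictly inside the scar circle (minus half an edge)
  rn <- sqrt((m$nodes[, 1L] - 15)^2 + (m$nodes[, 2L] - 15)^2)
  expect_true(all(rn > 5 - m$h))
})

test_that("a zero-diameter scar gives a plain sheet", {
  m <- build_mesh(geometry_config(resolution = 0.5, scar_diameter = 0,
                                  bz_thickness = 0))
  expect_true(all(m$region == "healthy"))
  expect_lt(abs(sum(element_areas(m)) - 900), 1e-6)
})

test_that("too-coarse resolutions and invalid configs are rejected", {
  expect_error(build_mesh(geometry_config(resolution = 2)), "coarse")
  expect_error(geometry_config(scar_diameter = 28, bz_thickness = 2))
  expect_error(geometry_config(resolution = 0))
})

test_that("node set and hole are exactly mirror-symmetric", {
  m <- suite_mesh02()
  mir <- mirror_index(m)
  expect_false(anyNA(mir))
  expect_equal(m$nodes[mir, 1L], 30 - m$nodes[, 1L], tolerance = 1e-9)
  expect_equal(m$nodes[mir, 2L], m$nodes[, 2L], tolerance = 1e-12)
})

test_that("fiber assignment is horizontal, seeded-random, or rejected", {
  m <- suite_mesh02()
  expect_true(all(m$fiber_angle == 0))
  m1 <- assign_fibers(m, "random", seed = 42L)
  m2 <- assign_fibers(m, "random", seed = 42L)
  expect_identical(m1$fiber_angle, m2$fiber_angle)
  m3 <- assign_fibers(m, "random", seed = 43L)
  expect_false(identical(m1$fiber_angle, m3$fiber_angle))
  bz <- m$region == "border_zone"
  expect_true(all(m1$fiber_angle[!bz] == 0))
  th <- m1$fiber_angle[bz]
  expect_true(all(th >= 0 & th < pi))
  # Rayleigh test on the doubled angles: no rejection of uniformity
  n <- length(th)
  rbar2 <- Mod(mean(exp(2i * th)))^2
  p <- exp(-n * rbar2)
  expect_gt(n, 1000)
  expect_gt(p, 0.01)
  expect_error(assign_fibers(m, "diagonal"))
})

test_that("stimulus node set is a symmetric half-disc on the bottom edge", {
  m <- suite_mesh02()
  s <- m$stim_nodes
  expect_gt(length(s), 10)  # ~16 nodes in the half-disc at 0.2 mm
  expect_true(all(m$nodes[s, 2L] <= 0.5))
  expect_true(all(abs(m$nodes[s, 1L] - 15) <= 0.5))
  mir <- mirror_index(m)
  expect_setequal(mir[s], s)
  # a mesh with no node at the bottom-edge midpoint: sub-spacing radii fail
  m2 <- bzep:::strip_mesh(length = 13, width = 4, resolution = 3)
  expect_error(place_stimulus(m2, radius = 1e-4), "larger")
})
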