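# Triangulated surface model, rigid transforms and cylinder axis fitting.

test_that("triangle properties match closed forms", {
  s <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 2, 3)))
  p <- triangle_properties(s)
  expect_equal(p$centroids[1, ], c(1, 1, 0) / 3, tolerance = 1e-15)
  expect_equal(p$normals[1, ], c(0, 0, 1), tolerance = 1e-15)
  expect_equal(p$areas[1], 0.5, tolerance = 1e-15)

  # reversed winding flips the normal
  s2 <- tri_surface(s$vertices, rbind(c(1, 3, 2)))
  expect_equal(s2$normals[1, ], c(0, 0, -1), tolerance = 1e-15)

  # equilateral triangle of side 2: area = sqrt(3)/4 * s^2
  eq <- tri_surface(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                    rbind(c(1, 2, 3)))
  expect_equal(eq$areas[1], sqrt(3), tolerance = 1e-12)
})

test_that("degenerate faces are removed with a warning", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face is collinear
  expect_warning(s <- tri_surface(v, f), "1 degenerate")
  expect_equal(nrow(s$faces), 1L)
  expect_error(suppressWarnings(tri_surface(v, rbind(c(1, 2, 4)))),
               "empty mesh")
})

test_that("surface invariants hold on generated fixtures", {
  for (kind in c("flat_congruent", "cylinder_congruent",
                 "cylinder_incongruent", "flat_with_depressions")) {
    j <- make_joint(fixture_spec(kind, resolution = 200, radius_tibia = 26))
    for (s in list(j$talus, j$tibia)) {
      expect_true(all(s$areas > 0))
      expect_lt(max(abs(sqrt(rowSums(s$normals^2)) - 1)), 1e-9)
      expect_true(is_orientation_consistent(s))
    }
  }
})

test_that("rigid transforms preserve metric quantities", {
  j <- make_joint(fixture_spec("cylinder_congruent", resolution = 150))
  s <- j$talus
  pose <- rigid_pose(edem:::.rodrigues(c(1, 2, 2) / 3, 0.7), c(3, -4, 5))
  s2 <- apply_pose(s, pose)
  d0 <- as.matrix(dist(s$vertices[1:40, ]))
  d1 <- as.matrix(dist(s2$vertices[1:40, ]))
  expect_lt(max(abs(d0 - d1)), 1e-12)
  expect_lt(max(abs(s$areas - s2$areas)), 1e-12)
})

test_that("rotation about an axis follows the right-hand convention", {
  ax <- joint_axis(c(0, 0, 0), c(0, 0, 1))
  expect_equal(rotate_about_axis(c(1, 0, 0), ax, 90), c(0, 1, 0),
               tolerance = 1e-12)
  j <- make_joint(fixture_spec("flat_congruent", resolution = 50))
  s <- j$talus
  expect_lt(max(abs(rotate_about_axis(s, ax, 0)$vertices - s$vertices)), 1e-15)
  expect_lt(max(abs(rotate_about_axis(s, ax, 360)$vertices - s$vertices)), 1e-12)
  # the axis point is the rotation centre
  ax2 <- joint_axis(c(5, 0, 0), c(0, 0, 1))
  expect_equal(rotate_about_axis(c(6, 0, 0), ax2, 90), c(5, 1, 0),
               tolerance = 1e-12)
})

test_that("translation shifts centroids and nothing else", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 50))
  s <- j$talus
  expect_identical(translate_surface(s, c(0, 0, 0))$vertices, s$vertices)
  # 0.57 mm superior shift, the scale of a talus displacement during stance
  u <- c(0, 0.57, 0)
  s2 <- translate_surface(s, u)
  expect_equal(s2$centroids - s$centroids,
               matrix(u, nrow(s$centroids), 3, byrow = TRUE),
               tolerance = 1e-15)
  expect_identical(s2$normals, s$normals)
  expect_identical(s2$areas, s$areas)
  s3 <- translate_surface(s2, -u)
  expect_lt(max(abs(s3$vertices - s$vertices)), 1e-15)
})

test_that("cylinder fit recovers an exact generating axis", {
  j <- make_joint(fixture_spec("cylinder_congruent", radius_talus = 20,
                               arc_deg = 60, resolution = 600))
  ax <- fit_cylinder_axis(j$talus)
  expect_lt(acos(min(abs(sum(ax$direction * c(0, 0, 1))), 1)), 1e-6)
  # the fitted axis point lies on the true axis (x = y = 0)
  expect_lt(sqrt(sum(ax$point[1:2]^2)), 1e-9)
  expect_equal(attr(ax, "radius"), 20, tolerance = 1e-3)
})

test_that("cylinder fit tolerates measurement noise", {
  j <- make_joint(fixture_spec("cylinder_congruent", radius_talus = 20,
                               arc_deg = 60, resolution = 700))
  set.seed(42)
  for (rep in 1:25) {
    v <- j$talus$vertices + matrix(stats::rnorm(length(j$talus$vertices),
                                                sd = 0.01), ncol = 3)
    ax <- fit_cylinder_axis(tri_surface(v, j$talus$faces))
    ang <- acos(min(abs(sum(ax$direction * c(0, 0, 1))), 1)) * 180 / pi
    expect_lt(ang, 0.1)
  }
})

test_that("cylinder fit rejects planar surfaces", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 200))
  expect_error(fit_cylinder_axis(j$talus), "degenerate")
})

test_that("cylinder fit is equivariant under rigid transforms", {
  j <- make_joint(fixture_spec("cylinder_congruent", arc_deg = 80,
                               resolution = 500))
  ax0 <- fit_cylinder_axis(j$talus)
  R <- edem:::.rodrigues(c(2, 1, -1) / sqrt(6), 0.9)
  pose <- rigid_pose(R, c(10, -3, 7))
  ax1 <- fit_cylinder_axis(apply_pose(j$talus, pose),
                           reference_direction = as.numeric(R %*% c(0, 0, 1)))
  d_expect <- as.numeric(R %*% ax0$direction)
  expect_lt(sqrt(sum((ax1$direction - d_expect)^2)), 1e-9)
})

test_that("orientation repair flips a surface facing away", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 100))
  flipped <- flip_surface(j$talus)
  expect_warning(fixed <- orient_facing(flipped, j$tibia), "flipping")
  expect_equal(fixed$normals, j$talus$normals, tolerance = 1e-12)
  expect_identical(orient_facing(j$talus, j$tibia)$faces, j$talus$faces)
})
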