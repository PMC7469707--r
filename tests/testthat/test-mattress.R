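# Spring mattress: Poisson factor, normal-ray casting, length threshold,
# strain-dependent stiffness.

test_that("poisson factor matches the closed form", {
  expect_equal(poisson_factor(0), 1.0, tolerance = 1e-15)
  expect_equal(poisson_factor(0.25), 1.2, tolerance = 1e-12)
  expect_equal(poisson_factor(0.4247), 2.6813, tolerance = 1e-4)
  expect_error(poisson_factor(0.5), "nu")
  expect_error(poisson_factor(-0.1), "nu")
})

test_that("parallel plates give a uniform gap equal to the separation", {
  j <- make_joint(fixture_spec("flat_congruent", gap = 2, resolution = 200))
  m <- cast_springs(j$talus, j$tibia)
  present <- m$status != "absent"
  expect_true(all(present))
  expect_lt(max(abs(m$length[present] - 2)), 1e-12)
})

test_that("concentric cylinder sectors give the radial gap, converging with the mesh", {
  # continuum value: constant radial gap of 1.5 mm; faceting perturbs it by
  # the chordal sag, which shrinks ~4x per 4x refinement
  errs <- vapply(c(800, 3200), function(res) {
    j <- make_joint(fixture_spec("cylinder_congruent", gap = 1.5,
                                 resolution = res))
    m <- cast_springs(j$talus, j$tibia)
    max(abs(m$length[m$status != "absent"] - 1.5))
  }, numeric(1))
  expect_lt(errs[1], 0.01)
  expect_lt(errs[2], 0.0033)
  expect_lt(errs[2], errs[1] / 2)
})

test_that("a laterally offset tibia leaves exactly the uncovered half absent", {
  xs <- seq(-10, 10, length.out = 11)
  zs <- seq(-10, 10, length.out = 11)
  flat <- function(x, z) rep(0, length(x))
  talus <- edem:::.plate_surface(xs, zs, flat, up = TRUE)
  tibia <- edem:::.plate_surface(xs + 10, zs, function(x, z) rep(2, length(x)),
                                 up = FALSE)
  m <- cast_springs(talus, tibia)
  hit <- m$status != "absent"
  expect_equal(sum(hit), nrow(talus$faces) / 2)
  expect_true(all(talus$centroids[hit, 1] > 0))
  expect_true(all(talus$centroids[!hit, 1] < 0))
})

test_that("cast lengths agree with the brute-force intersection oracle", {
  for (kind in c("cylinder_incongruent", "flat_with_depressions")) {
    j <- make_joint(fixture_spec(kind, resolution = 150, radius_tibia = 26))
    m <- cast_springs(j$talus, j$tibia)
    oracle <- oracle_ray_lengths(j$talus, j$tibia)
    expect_identical(is.na(oracle), m$status == "absent")
    ok <- !is.na(oracle)
    expect_lt(max(abs(m$length[ok] - oracle[ok])), 1e-10)
  }
})

test_that("disjoint surfaces raise a casting error", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 50))
  far <- translate_surface(j$tibia, c(500, 0, 0))
  expect_error(cast_springs(j$talus, far), "disjoint|mis-oriented")
})

test_that("spring count is invariant under a common rigid transform", {
  j <- make_joint(fixture_spec("cylinder_incongruent", radius_tibia = 40,
                               resolution = 300))
  m0 <- apply_length_threshold(cast_springs(j$talus, j$tibia))
  pose <- rigid_pose(edem:::.rodrigues(c(1, 1, 1) / sqrt(3), 1.1), c(5, 6, -7))
  m1 <- apply_length_threshold(cast_springs(apply_pose(j$talus, pose),
                                            apply_pose(j$tibia, pose)))
  expect_identical(m0$status, m1$status)
  ok <- m0$status != "absent"
  expect_lt(max(abs(m0$length[ok] - m1$length[ok])), 1e-9)
})

test_that("the length threshold keeps the boundary and filters monotonically", {
  j <- make_joint(fixture_spec("flat_congruent", gap = 2, resolution = 50))
  m <- cast_springs(j$talus, j$tibia, material_params(h_threshold = 3.5))
  m$length <- rep(c(2.0, 3.5, 3.6), length.out = m$n)
  m <- apply_length_threshold(m)
  expect_identical(unname(m$status[1:3]), c("nominal", "nominal", "over_threshold"))
  # idempotent
  expect_identical(apply_length_threshold(m)$status, m$status)

  # nominal count non-decreasing in the threshold on a graded-gap fixture
  ji <- make_joint(fixture_spec("cylinder_incongruent", radius_tibia = 40,
                                resolution = 300))
  counts <- vapply(seq(2.5, 4.5, by = 0.5), function(hT) {
    mi <- apply_length_threshold(cast_springs(ji$talus, ji$tibia,
                                              material_params(h_threshold = hT)))
    sum(mi$status == "nominal")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("stiffness follows s(nu) E A / h", {
  # one pair of triangles with A = 0.15 mm^2 at gap 3.5 mm
  side <- sqrt(0.3)
  xs <- c(-side / 2, side / 2)
  talus <- edem:::.plate_surface(xs, xs, function(x, z) rep(0, length(x)),
                                 up = TRUE)
  tibia <- edem:::.plate_surface(xs, xs, function(x, z) rep(3.5, length(x)),
                                 up = FALSE)
  expect_equal(talus$areas, c(0.15, 0.15), tolerance = 1e-12)
  m <- compute_stiffnesses(apply_length_threshold(cast_springs(talus, tibia)))
  expect_true(all(m$status == "nominal"))  # boundary gap is kept
  expect_equal(m$stiffness[1], 1.1894, tolerance = 1e-3)

  # k scales as A and 1/h, spring by spring
  m2 <- m
  m2$length <- m$length * 2
  m2 <- compute_stiffnesses(m2)
  expect_equal(m2$stiffness, m$stiffness / 2, tolerance = 1e-12)
  m3 <- m
  m3$area <- m$area * 2
  m3 <- compute_stiffnesses(m3)
  expect_equal(m3$stiffness, m$stiffness * 2, tolerance = 1e-12)
  # and linearly in E
  m4 <- cast_springs(talus, tibia, material_params(E_cartilage = 20.70))
  m4 <- compute_stiffnesses(apply_length_threshold(m4))
  expect_equal(m4$stiffness, m$stiffness * 2, tolerance = 1e-12)
})

test_that("near-zero gaps are reported as interpenetration", {
  j <- make_joint(fixture_spec("flat_congruent", gap = 2, resolution = 50))
  m <- cast_springs(j$talus, j$tibia)
  m$length[5] <- 5e-4
  expect_error(compute_stiffnesses(m), "triangle 5.*interpenetrate")
})

test_that("the gap map exports one row per talar triangle", {
  j <- make_joint(fixture_spec("flat_congruent", gap = 2, resolution = 50))
  m <- apply_length_threshold(cast_springs(j$talus, j$tibia))
  p <- tempfile(fileext = ".csv")
  write_gap_map(m, p)
  df <- read.csv(p)
  expect_equal(nrow(df), m$n)
  expect_named(df, c("triangle_id", "length", "area", "status"))
})
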