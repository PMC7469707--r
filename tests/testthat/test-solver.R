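# Contact equilibrium solver: EDEM/DEM variants, tension release, pressures,
# state advancement.

test_that("a single spring follows the scalar Hooke law", {
  m <- synth_mattress(matrix(c(0, 1, 0), 1, 3), k = 10, areas = 2)
  sol <- solve_equilibrium_dem(m, NULL, c(0, 5, 0))
  expect_equal(sol$u_step, c(0, 0.5, 0), tolerance = 1e-12)
  expect_equal(as.numeric(sol$spring_forces), 5, tolerance = 1e-12)
  expect_equal(as.numeric(sol$pressures), 2.5, tolerance = 1e-12)

  # two symmetric oblique flankers keep the axial result on the axis
  s30 <- sin(pi / 6); c30 <- cos(pi / 6)
  nrm <- rbind(c(0, 1, 0), c(s30, c30, 0), c(-s30, c30, 0))
  m3 <- synth_mattress(nrm, k = c(10, 1, 1))
  sol3 <- solve_equilibrium_dem(m3, NULL, c(0, 5, 0))
  expect_equal(sol3$u_step[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_balanced(sol3, m3, NULL, c(0, 5, 0))
})

test_that("the flat congruent plate reproduces the analytic solution", {
  j <- make_joint(fixture_spec("flat_congruent", extent = c(20, 20), gap = 2,
                               resolution = 800))
  mat <- material_params()  # E = 10.35, nu = 0.4247
  m <- prepared_mattress(j, mat)
  F_applied <- c(0, 1000, 0)
  sol <- solve_equilibrium_dem(m, NULL, F_applied)
  pm <- pressure_map(sol, m)
  p <- as.numeric(sol$pressures)
  expect_lt(max(abs(p - 2.5)) / 2.5, 1e-9)
  u_exact <- 1000 * 2 / (poisson_factor(mat$nu) * mat$E_cartilage * 400)
  expect_lt(abs(sol$u_step[2] - u_exact) / u_exact, 1e-6)
  expect_equal(pm$active_area_cm2, 4.00, tolerance = 1e-9)
  expect_equal(pm$peak_mpa, 2.5, tolerance = 1e-9)
  expect_balanced(sol, m, NULL, F_applied)
})

test_that("DEM equals the first EDEM step from a zero state", {
  j <- make_joint(fixture_spec("cylinder_incongruent", radius_tibia = 40,
                               resolution = 300))
  m <- prepared_mattress(j)
  b <- make_bundles(j$attachments)
  F_applied <- c(100, 1500, 0)
  dem <- solve_equilibrium_dem(m, b, F_applied)
  ed <- solve_equilibrium_edem(m, b, F_applied, solver_state(m$n))
  expect_identical(ed$solution$active_ids, dem$active_ids)
  expect_lt(max(abs(as.numeric(ed$solution$spring_forces) -
                      as.numeric(dem$spring_forces))), 1e-12)
  expect_equal(ed$state$u_cum, dem$u_step, tolerance = 1e-15)
})

test_that("zero load returns the zero solution without iterating", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 100))
  m <- prepared_mattress(j)
  sol <- solve_equilibrium_dem(m, NULL, c(0, 0, 0))
  expect_equal(sol$u_step, c(0, 0, 0))
  expect_length(sol$active_ids, 0L)
  expect_identical(sol$iterations, 0L)
})

test_that("solver matches the naive brute-force oracle on random systems", {
  set.seed(101)
  for (rep in 1:40) {
    sys <- random_spring_system(sample(4:12, 1), with_state = rep %% 2 == 0)
    m <- synth_mattress(sys$normals, sys$k)
    st <- solver_state(m$n)
    st$stored_forces <- sys$fprev
    got <- tryCatch(solve_equilibrium_edem(m, NULL, sys$F_applied, st),
                    error = function(e) e)
    want <- oracle_contact(sys$normals, sys$k, sys$fprev, sys$F_applied)
    if (want$liftoff || want$ill_posed) {
      expect_true(inherits(got, "error"))
    } else {
      expect_false(inherits(got, "error"))
      expect_identical(got$solution$active_ids, want$active)
      expect_lt(max(abs(as.numeric(got$solution$spring_forces) - want$forces)),
                1e-10)
      expect_balanced(got$solution, m, NULL, sys$F_applied)
    }
  }
})

test_that("removal rules agree and iteration counts respect the cap", {
  set.seed(202)
  for (rep in 1:10) {
    sys <- random_spring_system(10)
    m <- synth_mattress(sys$normals, sys$k)
    a <- solve_equilibrium_dem(m, NULL, sys$F_applied)
    b <- solve_equilibrium_dem(m, NULL, sys$F_applied,
                               solver_params(removal_rule = "most_tensile_only"))
    expect_identical(sort(a$active_ids), sort(b$active_ids))
    expect_lt(max(abs(as.numeric(a$spring_forces[order(a$active_ids)]) -
                        as.numeric(b$spring_forces[order(b$active_ids)]))), 1e-10)
    expect_lte(a$iterations, a$n_nominal)
  }
  expect_error(
    solve_equilibrium_dem(synth_mattress(rbind(c(0.6, 0.8, 0), c(-0.6, 0.8, 0)),
                                         c(5, 5)),
                          NULL, c(0, 10, 0),
                          solver_params(max_active_set_iterations = 1,
                                        removal_rule = "most_tensile_only")) ,
    NA)  # converges in one iteration when nothing is tensile
})

test_that("E-scaling leaves DEM pressures unchanged and scales displacement", {
  j <- make_joint(fixture_spec("cylinder_incongruent", radius_tibia = 40,
                               resolution = 300))
  F_applied <- c(0, 2000, 0)
  base_mat <- material_params()
  base <- solve_equilibrium_dem(prepared_mattress(j, base_mat), NULL, F_applied)
  for (c_scale in c(0.5, 2, 10)) {
    mat <- material_params(E_cartilage = base_mat$E_cartilage * c_scale)
    sol <- solve_equilibrium_dem(prepared_mattress(j, mat), NULL, F_applied)
    expect_identical(sol$active_ids, base$active_ids)
    expect_lt(max(abs(as.numeric(sol$pressures) - as.numeric(base$pressures))),
              1e-10)
    expect_lt(max(abs(sol$u_step - base$u_step / c_scale)), 1e-10)
  }
})

test_that("a transverse load on parallel springs is under-constrained", {
  m <- synth_mattress(rbind(c(0, 1, 0), c(0, 1, 0)), c(5, 5))
  expect_error(solve_equilibrium_dem(m, NULL, c(10, 0, 0)),
               "under-constrained")
})

test_that("full unloading releases all springs and restores the pose", {
  # uniform parallel bed with stored forces and F = 0: every spring crosses
  # zero simultaneously and the talus moves back by f_prev / k
  n <- 5
  m <- synth_mattress(matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE),
                      k = rep(4, n))
  st <- solver_state(n)
  st$u_cum <- c(0, 0.5, 0)
  st$stored_forces <- rep(2, n)
  r <- solve_equilibrium_edem(m, NULL, c(0, 0, 0), st)
  expect_length(r$solution$active_ids, 0L)
  expect_equal(r$solution$u_step, c(0, -0.5, 0), tolerance = 1e-12)
  expect_equal(r$state$u_cum, c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(r$state$stored_forces == 0))

  # but an unbalanced residual load with no springs left is a lift-off error
  expect_error(solve_equilibrium_dem(m, NULL, c(0, -10, 0)), "lift-off")
})

test_that("pressure_map reports zero off the active set and areas in cm^2", {
  j <- make_joint(fixture_spec("flat_congruent", resolution = 200))
  m <- prepared_mattress(j)
  sol <- solve_equilibrium_dem(m, NULL, c(0, 500, 0))
  pm <- pressure_map(sol, m)
  expect_length(pm$pressure, m$n)
  expect_true(all(pm$pressure[setdiff(seq_len(m$n), sol$active_ids)] == 0))
  expect_equal(pm$active_area_cm2, surface_area(j$talus) / 100,
               tolerance = 1e-9)
  z <- pressure_map(solve_equilibrium_dem(m, NULL, c(0, 0, 0)), m)
  expect_equal(z$peak_mpa, 0)
  expect_equal(z$active_area_cm2, 0)
})

test_that("advance_state stores active forces and zeros the rest", {
  j <- make_joint(fixture_spec("flat_congruent", extent = c(20, 20), gap = 2,
                               resolution = 200))
  m <- prepared_mattress(j)
  r <- solve_equilibrium_edem(m, NULL, c(0, 1000, 0), solver_state(m$n))
  st <- advance_state(r$state, r$solution, m)
  # every stored force equals p * A = 2.5 A_i
  expect_equal(st$stored_forces, 2.5 * m$area, tolerance = 1e-9)
  expect_identical(st$u_cum, r$state$u_cum)
  # zero-load solve leaves the state unchanged
  r0 <- solve_equilibrium_edem(m, NULL, c(0, 0, 0), solver_state(m$n))
  expect_equal(advance_state(r0$state, r0$solution, m)$stored_forces,
               numeric(m$n))
})

test_that("within-step stiffness update softens the bed consistently", {
  j <- make_joint(fixture_spec("flat_congruent", extent = c(20, 20), gap = 2,
                               resolution = 200))
  m <- prepared_mattress(j)
  F_applied <- c(0, 1000, 0)
  lagged <- solve_equilibrium_dem(m, NULL, F_applied)
  within <- solve_equilibrium_dem(m, NULL, F_applied,
                                  solver_params(stiffness_update = "within_step"))
  expect_balanced(within, m, NULL, F_applied)
  # stiffer at the compressed gap -> smaller displacement than the lagged solve
  expect_lt(within$u_step[2], lagged$u_step[2])
  expect_identical(within$active_ids, lagged$active_ids)
})

test_that("active contact grows with load on the incongruent cylinder", {
  j <- make_joint(fixture_spec("cylinder_incongruent", radius_tibia = 40,
                               resolution = 300))
  mat <- material_params()
  areas <- vapply(c(500, 2000), function(Fy) {
    m <- prepared_mattress(j, mat)
    st <- solver_state(m$n)
    # EDEM settles the talus, recruiting springs through the threshold
    r <- solve_equilibrium_edem(m, NULL, c(0, Fy, 0), st)
    m2 <- compute_stiffnesses(apply_length_threshold(cast_springs(
      translate_surface(j$talus, r$state$u_cum), j$tibia, mat)))
    sum(m2$status == "nominal")
  }, numeric(1))
  expect_lte(areas[1], areas[2])
})
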