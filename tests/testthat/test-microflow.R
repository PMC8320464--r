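test_that("empty structure gives uniform flow with zero pressure drop", {
  st <- mkstruct(array(FALSE, c(8, 8, 12)), 5e-6)
  f <- solve_stokes(st, 0.1, pad = 4L)
  expect_true(f$converged)
  expect_lt(abs(pressure_drop(f)), 1e-8)
  expect_equal(max(abs(plane_mean_w(f) - 0.1)), 0, tolerance = 1e-10)
  expect_lt(max(abs(f$wcc - 0.1)), 1e-10)
})

test_that("plane-channel flow matches the Poiseuille closed form", {
  st <- channel_structure(nx = 32, wall = 6, nzs = 60, h = 5e-6)
  f <- solve_stokes(st, 0.1, pad = 0L)
  pp <- pressure_profile(f)
  # interior gradient (fully developed region) vs 12 mu v / h^2
  gap <- (32 - 12) * 5e-6
  grad <- (pp[20] - pp[40]) / (20 * 5e-6)
  grad_theory <- 12 * 1.834e-5 * 0.1 / gap^2
  expect_lt(abs(grad / grad_theory - 1), 0.05)
})

test_that("pressure drop is linear in face velocity (Stokes linearity)", {
  lay <- generate_layer(fiber_layer_spec(12, 0.12, 60), c(6e-5, 6e-5), 3e-6,
                        seed = 4)
  f1 <- solve_stokes(lay, 0.05, pad = 6L)
  f2 <- solve_stokes(lay, 0.10, pad = 6L)
  expect_lt(abs(pressure_drop(f2) / pressure_drop(f1) - 2), 0.01 * 2)
  k1 <- darcy_permeability(0.05, pressure_drop(f1), thickness(lay))
  k2 <- darcy_permeability(0.10, pressure_drop(f2), thickness(lay))
  expect_lt(abs(k1 / k2 - 1), 0.01)
})

test_that("mass is conserved slice by slice", {
  lay <- generate_layer(fiber_layer_spec(12, 0.15, 60), c(6e-5, 6e-5), 3e-6,
                        seed = 8)
  f <- solve_stokes(lay, 0.1, pad = 6L)
  expect_true(f$converged)
  expect_lt(max(abs(plane_mean_w(f) - 0.1)) / 0.1, 1e-5)
})

test_that("permeability decreases with solidity", {
  ks <- vapply(c(0.05, 0.10, 0.20), function(a) {
    lay <- generate_layer(fiber_layer_spec(12, a, 60), c(6e-5, 6e-5), 3e-6,
                          seed = 21)
    f <- solve_stokes(lay, 0.1, pad = 6L)
    darcy_permeability(0.1, pressure_drop(f), thickness(lay))
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("Navier slip lowers the pressure drop relative to no-slip", {
  lay <- generate_layer(fiber_layer_spec(12, 0.12, 60), c(6e-5, 6e-5), 3e-6,
                        seed = 13)
  f0 <- solve_stokes(lay, 0.1, flow_params(slip_length = 0), pad = 6L)
  f1 <- solve_stokes(lay, 0.1, flow_params(slip_length = 1e-6), pad = 6L)
  expect_lt(pressure_drop(f1), pressure_drop(f0))
})

test_that("blocked media and unconverged fields are refused", {
  occ <- array(FALSE, c(6, 6, 10))
  occ[, , 5] <- TRUE # solid wall across the whole section
  expect_error(solve_stokes(mkstruct(occ, 5e-6), 0.1, pad = 2L), "percolating")

  st <- mkstruct(array(FALSE, c(4, 4, 6)), 5e-6)
  f <- solve_stokes(st, 0.1, pad = 2L)
  f$converged <- FALSE
  expect_error(pressure_drop(f), "residual")
})

test_that("Darcy permeability inverts the printed worked examples", {
  # v = 0.1 m/s, t_f = 0.5 mm, dP = 5.95 Pa -> k ~ 1.54e-10 m^2
  expect_equal(darcy_permeability(0.1, 5.95, 5e-4, 1.834e-5), 1.54e-10,
               tolerance = 0.002)
  # v = 0.1 m/s, t_f = 0.97 mm, dP = 61.1 Pa -> k ~ 2.91e-11 m^2
  expect_equal(darcy_permeability(0.1, 61.1, 9.7e-4, 1.834e-5), 2.91e-11,
               tolerance = 0.002)
  # homogeneity: scaling v and dP together leaves k unchanged
  expect_equal(darcy_permeability(0.2, 11.9, 5e-4),
               darcy_permeability(0.1, 5.95, 5e-4))
  expect_error(darcy_permeability(0.1, 0, 5e-4), "domain")
  expect_error(darcy_permeability(0.1, -1, 5e-4), "domain")
})
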