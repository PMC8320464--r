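test_that("tracking through an empty structure penetrates completely", {
  st <- mkstruct(array(FALSE, c(8, 8, 16)), 3e-6)
  f <- solve_stokes(st, 0.1, pad = 4L)
  cr <- track_particles(f, st, sizes = c(0.6, 2, 10), n_per_size = 200,
                        seed = 5)
  expect_true(all(cr$penetrated == cr$injected))
  expect_equal(penetration_curve(cr)$penetration, c(1, 1, 1))
})

test_that("particles larger than every pore are sieved out", {
  # perforated plate: 2-voxel-wide slit, particle wider than the slit
  occ <- array(FALSE, c(10, 10, 12))
  occ[, , 6:7] <- TRUE
  occ[5:6, 5:6, 6:7] <- FALSE       # 6 x 6 um opening at h = 3 um
  st <- mkstruct(occ, 3e-6)
  f <- solve_stokes(st, 0.1, pad = 4L)
  cr <- track_particles(f, st, sizes = 15, n_per_size = 150, seed = 5)
  expect_equal(cr$penetrated, 0)
  expect_equal(cr$captured, cr$injected)
})

test_that("capture counts conserve and are seed-reproducible", {
  lay <- generate_layer(fiber_layer_spec(12, 0.12, 60), c(6e-5, 6e-5), 3e-6,
                        seed = 4)
  f <- solve_stokes(lay, 0.1, pad = 6L)
  a <- track_particles(f, lay, sizes = c(0.6, 2, 5), n_per_size = 300,
                       seed = 17)
  b <- track_particles(f, lay, sizes = c(0.6, 2, 5), n_per_size = 300,
                       seed = 17)
  expect_identical(a$penetrated, b$penetrated)
  expect_true(all(a$injected == a$captured + a$penetrated))
  # penetration monotone non-increasing for d >= 1 um (mechanical regime)
  cv <- penetration_curve(a)
  pen_mech <- cv$penetration[cv$diameter_um >= 1]
  expect_true(all(diff(pen_mech) <= 0))
})

test_that("penetration_curve arithmetic and error contracts", {
  cr <- data.frame(diameter_um = c(0.6, 2), injected = c(1000, 1482),
                   captured = c(93, 1482), penetrated = c(907, 0))
  class(cr) <- c("capture_result", "data.frame")
  cv <- penetration_curve(cr)
  expect_equal(cv$penetration, c(0.907, 0))
  expect_equal(cv$se[2], 0)
  expect_gt(cv$se[1], 0)

  bad <- cr; bad$injected <- c(0, 10)
  expect_error(penetration_curve(bad), "domain")
})

test_that("penetration interpolation clamps below and zeroes above", {
  cv <- data.frame(diameter_um = c(1, 10), penetration = c(0.8, 0.1),
                   se = 0, n_injected = 100, n_penetrated = c(80, 10))
  class(cv) <- c("penetration_curve", "data.frame")
  expect_equal(penetration_at(cv, 0.5), 0.8)
  expect_equal(penetration_at(cv, 20), 0)
  # log-linear midpoint
  expect_equal(penetration_at(cv, sqrt(10)), 0.45, tolerance = 1e-9)
})

test_that("stacking multiplies penetrations and commutes", {
  mk <- function(p) {
    cv <- data.frame(diameter_um = c(0.6, 2, 13), penetration = p, se = 0,
                     n_injected = 1000, n_penetrated = round(1000 * p))
    class(cv) <- c("penetration_curve", "data.frame")
    cv
  }
  one <- mk(c(0.9, 0.5, 0))
  expect_equal(stack_penetration(list(one))$penetration, one$penetration)

  # two spunbond layers at P = 0.907: stack efficiency 1 - 0.907^2 = 17.7%
  sb <- mk(c(0.907, 0.907, 0))
  two <- stack_penetration(list(sb, sb))
  expect_equal(1 - two$penetration[1], 1 - 0.907^2, tolerance = 1e-9)

  ab <- stack_penetration(list(mk(c(0.9, 0.5, 0)), mk(c(0.8, 0.2, 0.1))))
  ba <- stack_penetration(list(mk(c(0.8, 0.2, 0.1)), mk(c(0.9, 0.5, 0))))
  expect_equal(ab$penetration, ba$penetration)
  expect_error(stack_penetration(list()), "domain")
})

test_that("thickness rescaling is the depth-filtration power law", {
  cv <- data.frame(diameter_um = c(1, 5), penetration = c(0.5, 0), se = 0,
                   n_injected = 100, n_penetrated = c(50, 0))
  class(cv) <- c("penetration_curve", "data.frame")
  sc <- scale_penetration(cv, 3)
  expect_equal(sc$penetration, c(0.125, 0))
})

test_that("penetration curves round-trip through CSV", {
  cv <- data.frame(diameter_um = c(0.6, 2, 13), penetration = c(0.9, 0.3, 0),
                   se = 0, n_injected = 1000,
                   n_penetrated = c(900, 300, 0))
  class(cv) <- c("penetration_curve", "data.frame")
  path <- tempfile(fileext = ".csv")
  write_penetration_curve(cv, path)
  back <- read_penetration_curve(path)
  expect_equal(back$penetration, cv$penetration)
  expect_equal(back$diameter_um, cv$diameter_um)
  expect_s3_class(back, "penetration_curve")
  unlink(path)
})

test_that("analytic single-fiber model behaves and guards its domain", {
  # interception alone with a vanishing particle: no capture
  e0 <- single_fiber_efficiency(1e-4, 12, 0.1, 0.1,
                                mechanisms = "interception")
  expect_lt(e0, 1e-6)
  # efficiency strictly increases with thickness
  e1 <- single_fiber_efficiency(2, 12, 0.1, 0.1, thickness_um = 100)
  e2 <- single_fiber_efficiency(2, 12, 0.1, 0.1, thickness_um = 300)
  expect_gt(e2, e1)
  expect_error(single_fiber_efficiency(2, 12, 0.35, 0.1), "domain")
  expect_error(single_fiber_efficiency(2, 12, 0, 0.1), "domain")
})

test_that("test-rig face velocity equals 60 L/min over 100 cm^2", {
  expect_equal((60 / 1000 / 60) / (100 / 1e4), 0.1)
})

test_that("calibration is a fixed point and converges on a monotone model", {
  sp <- spunbond_spec(0.10)
  # fixed point: evaluator already returns the target
  fixed <- calibrate_layer(0.093, 0.6, sp,
                           evaluator = function(s) 0.093)
  expect_equal(fixed$solidity, 0.10)

  # synthetic monotone evaluator: converges within the call budget
  calls <- 0
  ev <- function(s) { calls <<- calls + 1; 0.5 * s$solidity }
  out <- calibrate_layer(0.093, 0.6, sp, evaluator = ev)
  expect_lt(abs(0.5 * out$solidity - 0.093), 0.01)
  expect_lte(calls, 12)

  # unreachable target -> calibration error
  expect_error(calibrate_layer(0.9, 0.6, sp,
                               evaluator = function(s) 0.01 * s$solidity),
               "calibration")
})

test_that("tracked efficiency agrees with single-fiber theory within 2x", {
  fx <- micro_fixture()
  sb <- fx$lib$spunbond
  cv <- sb$curve_layer
  for (d in c(0.6, 2, 5)) {
    e_track <- 1 - penetration_at(cv, d)
    e_theory <- single_fiber_efficiency(
      d, sb$spec$fiber_diameter_um, sb$spec$solidity, 0.1,
      thickness_um = sb$spec$thickness_um)
    expect_lt(e_track / e_theory, 2)
    expect_gt(e_track / e_theory, 0.5)
  }
})

test_that("calibrated layers reproduce the measured single-layer efficiencies", {
  fx <- micro_fixture()
  # the calibration targets 1 pp; web-realization wiggle between solidity
  # iterates can leave the best iterate up to ~2 pp off on some seeds
  expect_lt(abs(attr(fx$lib$spunbond$spec, "achieved") - 0.093), 0.02)
  expect_lt(abs(attr(fx$lib$meltblown$spec, "achieved") - 0.950), 0.02)
  # the independently tracked curves agree to binomial/realization noise;
  # the slab-to-layer depth scaling amplifies the binomial error by the
  # thickness ratio, so bound by 4x the propagated standard error
  band <- function(l) {
    cv <- l$curve_layer
    max(0.025, 4 * cv$se[cv$diameter_um == 0.6])
  }
  e_sb <- 1 - penetration_at(fx$lib$spunbond$curve_layer, 0.6)
  e_mb <- 1 - penetration_at(fx$lib$meltblown$curve_layer, 0.6)
  expect_lt(abs(e_sb - 0.093), band(fx$lib$spunbond))
  expect_lt(abs(e_mb - 0.950), band(fx$lib$meltblown))
})
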