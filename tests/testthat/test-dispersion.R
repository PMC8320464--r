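still_air <- ambient_conditions(wind_speed = 0)
no_flow <- carrier_flow_model(list(), wind = c(0, 0, 0), intensity = 0)

test_that("Schiller-Naumann drag coefficient matches its closed form", {
  expect_equal(drag_coefficient(1), 24 * 1.15)
  expect_equal(drag_coefficient(2000), 0.44)
  # continuity at the branch point within 1%
  expect_lt(abs(drag_coefficient(1000) / 0.44 - 1), 0.01)
  # Stokes limit: C_D Re / 24 -> 1
  expect_equal(drag_coefficient(1e-4) * 1e-4 / 24, 1, tolerance = 1e-2)
  expect_error(drag_coefficient(-1), "domain")
})

test_that("droplet acceleration reduces to gravity when slip vanishes", {
  st <- list(d_um = c(100, 500), ux = c(1, 2), uy = 0, uz = 0)
  a <- droplet_acceleration(st, cbind(c(1, 2), 0, 0), still_air)
  expect_equal(a[, 1], c(0, 0))
  expect_equal(a[, 3], rep(-9.81 * (1 - 1.204 / 1000), 2))
  a0 <- droplet_acceleration(st, cbind(c(1, 2), 0, 0), still_air,
                             gravity = FALSE)
  expect_true(all(a0 == 0))
})

test_that("settling reaches the drag-gravity terminal velocity", {
  # independent oracle: fixed point of the drag-gravity balance
  vt <- terminal_velocity_oracle(100e-6)
  expect_equal(vt, 0.25, tolerance = 0.1) # the classical ~0.25 m/s value

  b <- make_batch(100, t_inject = 0)
  b$ux <- 0
  ctrl <- dispersion_control(evaporation = FALSE, floor_z = -100)
  st <- maskflow:::init_states(b)
  t <- 0
  while (t < 2) { st <- step_droplets(st, no_flow, still_air, 1e-3, t, ctrl); t <- t + 1e-3 }
  expect_lt(abs(abs(st$uz) / vt - 1), 0.02)
})

test_that("velocity relaxes to the carrier on the Stokes time scale", {
  # 20 um droplet, small slip -> Stokes regime; x-velocity is an exponential
  d <- 20e-6
  tau <- cunningham_slip(d) * 1000 * d^2 / (18 * 1.834e-5)
  b <- make_batch(20, t_inject = 0)
  b$ux <- 0.01
  ctrl <- dispersion_control(evaporation = FALSE, gravity = FALSE)
  st <- maskflow:::init_states(b)
  dt <- 2e-4
  nstep <- 10
  for (i in seq_len(nstep)) {
    st <- step_droplets(st, no_flow, still_air, dt, (i - 1) * dt, ctrl)
  }
  expect_lt(abs(st$ux / (0.01 * exp(-nstep * dt / tau)) - 1), 0.02)
})

test_that("halving the time step barely moves a reference trajectory", {
  run_dt <- function(dt) {
    b <- make_batch(200, t_inject = 0)
    b$ux <- 4.5
    ctrl <- dispersion_control(dt_fine = dt, dt_coarse = dt,
                               evaporation = FALSE)
    run_dispersion(b, no_flow, still_air, t_max = 1.5, seed = 1,
                   control = ctrl)$max_forward_m
  }
  expect_lt(abs(run_dt(5e-4) / run_dt(1e-3) - 1), 0.01)
})

test_that("evaporation vanishes at saturation and uses Sh = 2 when quiescent", {
  sat <- ambient_conditions(rh = 1, wind_speed = 0)
  expect_equal(evaporation_rate(list(d_um = 10), sat, 0), 0)

  amb <- ambient_conditions(wind_speed = 0)
  d <- 10e-6
  Ys <- vapor_mass_fraction(saturation_pressure(20))
  Yi <- vapor_mass_fraction(0.7 * saturation_pressure(20))
  B <- (Ys - Yi) / (1 - Ys)
  expect_equal(evaporation_rate(list(d_um = 10), amb, 0),
               -pi * d * 1.204 * 2.42e-5 * 2 * log(1 + B), tolerance = 1e-12)
  # convection increases the magnitude
  expect_lt(evaporation_rate(list(d_um = 10), amb, 2),
            evaporation_rate(list(d_um = 10), amb, 0))
})

test_that("d^2 shrinks linearly in time for a quiescent droplet", {
  K <- d2law_K()
  b <- make_batch(20, t_inject = 0)
  b$ux <- 0
  ctrl <- dispersion_control(gravity = FALSE, d_min_um = 0.5,
                             dt_fine = 1e-4, dt_coarse = 1e-4)
  st <- maskflow:::init_states(b)
  t <- 0; ts <- c(); d2 <- c()
  while (t < 2e-2) {
    st <- step_droplets(st, no_flow, still_air, 1e-4, t, ctrl)
    t <- t + 1e-4
    ts <- c(ts, t); d2 <- c(d2, (st$d_um * 1e-6)^2)
  }
  pred <- (20e-6)^2 - K * ts
  expect_lt(max(abs(d2 - pred)) / (20e-6)^2, 0.01)
  # full-evaporation time of a 10 um droplet ~ d^2-law tau ~ 0.1 s
  tau10 <- (10e-6)^2 / K
  expect_equal(tau10, 0.1, tolerance = 0.1)
})

test_that("temperature rate honours the isothermal contract and signs", {
  amb <- ambient_conditions(wind_speed = 0)
  expect_equal(temperature_rate(list(d_um = 10, T_C = 20), amb, 0), 0)
  # non-isothermal: evaporation at equal temperatures cools the droplet
  r <- temperature_rate(list(d_um = 10, T_C = 20), amb, 0, isothermal = FALSE)
  expect_lt(r, 0)
  # saturated and in equilibrium: no heat flow
  sat <- ambient_conditions(rh = 1, wind_speed = 0)
  expect_equal(temperature_rate(list(d_um = 10, T_C = 20), sat, 0,
                                isothermal = FALSE), 0)
})

test_that("carrier jet reproduces its construction", {
  prof <- sneeze_profile()
  br <- jet_branch(c(1, 0, 0), 0.0226, function(t) flow_velocity(t, prof))
  cm <- carrier_flow_model(list(br), wind = c(0, 0, 0))
  # mouth plane at the peak: the exit velocity
  v0 <- carrier_velocity(matrix(c(1e-4, 0, 0), 1), 0.1, cm)
  expect_equal(v0$mean[1, 1], 4.5, tolerance = 1e-3)
  # far field before the front arrives: exactly zero
  vf <- carrier_velocity(matrix(c(6, 0, 0), 1), 0.5, cm)
  expect_equal(vf$mean[1, ], c(0, 0, 0))
  # one Gaussian width off axis: e^-1/2 of the local centreline
  s <- 0.05 # inside the potential core
  sig <- max(0.0226 / 2, 0.11 * s)
  von <- carrier_velocity(matrix(c(s, 0, 0), 1), 0.1, cm)$mean[1, 1]
  voff <- carrier_velocity(matrix(c(s, sig, 0), 1), 0.1, cm)$mean[1, 1]
  expect_equal(voff / von, exp(-0.5), tolerance = 1e-6)
  # wind adds uniformly
  cmw <- carrier_flow_model(list(br), wind = c(1.96, 0, 0))
  expect_equal(carrier_velocity(matrix(c(6, 0, 0), 1), 0.5, cmw)$mean[1, 1],
               1.96)
})

test_that("dispersion conserves fates and weights and is seed-deterministic", {
  b <- sample_droplets(n = 400, seed = 5)
  prof <- attr(b, "profile")
  br <- jet_branch(c(1, 0, 0), attr(b, "mouth")$diameter,
                   function(t) flow_velocity(t, prof))
  cm <- carrier_flow_model(list(br))
  r1 <- run_dispersion(b, cm, still_air, t_max = 4, seed = 31)
  r2 <- run_dispersion(b, cm, still_air, t_max = 4, seed = 31)
  expect_identical(r1$droplets, r2$droplets)
  expect_equal(sum(r1$fate_counts), sum(b$weight))
  expect_true(all(r1$droplets$fate %in% c("airborne", "evaporated",
                                          "deposited", "captured")))
  expect_gte(r1$max_forward_m, 0)
  # empty batch: zero distances, empty tallies
  r0 <- run_dispersion(sample_droplets(n = 0), cm, still_air, t_max = 1,
                       seed = 1)
  expect_equal(r0$max_forward_m, 0)
  expect_equal(sum(r0$fate_counts), 0)
})

test_that("small droplets evaporate before reaching the floor", {
  b <- sample_droplets(n = 600, seed = 8)
  prof <- attr(b, "profile")
  br <- jet_branch(c(1, 0, 0), attr(b, "mouth")$diameter,
                   function(t) flow_velocity(t, prof))
  cm <- carrier_flow_model(list(br))
  r <- run_dispersion(b, cm, still_air, t_max = 10, seed = 21)
  small <- r$droplets$d0_um < 50
  expect_true(all(r$droplets$fate[small] %in% c("evaporated", "airborne")))
  expect_gt(mean(r$droplets$fate[small] == "evaporated"), 0.95)
})
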