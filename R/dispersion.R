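#' Ambient air and wind conditions
#'
#' @param temperature_C air temperature (default 20 C).
#' @param rh relative humidity fraction (default 0.70).
#' @param wind_speed uniform wind speed (m/s; default 1.96, an annual-mean
#'   outdoor wind).
#' @param wind_direction `"none"`, `"head"` (toward the face, -x),
#'   `"tail"` (+x) or `"side"` (left to right, +y).
#' @param rho_air,mu_air air properties.
#' @param pressure ambient pressure (Pa).
#' @return object of class `ambient_conditions` (includes the resolved
#'   `wind` vector).
#' @export
ambient_conditions <- function(temperature_C = 20, rh = 0.70,
                               wind_speed = 1.96,
                               wind_direction = c("none", "head", "tail",
                                                  "side"),
                               rho_air = 1.204, mu_air = 1.834e-5,
                               pressure = 101325) {
  wind_direction <- match.arg(wind_direction)
  stopifnot(rh >= 0, rh <= 1, wind_speed >= 0)
  wvec <- switch(wind_direction,
                 none = c(0, 0, 0),
                 head = c(-1, 0, 0),
                 tail = c(1, 0, 0),
                 side = c(0, 1, 0)) * wind_speed
  if (wind_direction == "none") wvec <- c(0, 0, 0)
  structure(list(temperature_C = temperature_C, rh = rh,
                 wind_speed = wind_speed, wind_direction = wind_direction,
                 wind = wvec, rho_air = rho_air, mu_air = mu_air,
                 pressure = pressure),
            class = "ambient_conditions")
}

#' One jet branch of the carrier-flow surrogate
#' @param direction unit axis vector.
#' @param d_eff effective orifice diameter (m).
#' @param ue_fun vectorized function of time giving the exit velocity (m/s).
#' @param label branch label.
#' @return list describing the branch.
#' @export
jet_branch <- function(direction, d_eff, ue_fun, label = "jet") {
  e <- direction / sqrt(sum(direction^2))
  tg <- seq(0, 2, length.out = 801)
  peak <- max(ue_fun(tg))
  list(e = e, d = d_eff, ue = ue_fun, label = label,
       c_adv = max(peak / 2, 0.1))
}

#' Parametric carrier-flow model: transient round jets + wind + turbulence
#'
#' A desk-scale surrogate for the room-scale turbulent flow: each exhalation
#' branch is a self-similar round jet (centreline decay constant `B_j`,
#' spreading rate `S`, Gaussian radial profile) whose source strength
#' follows the exhalation profile, with the shut-off front advected
#' downstream at half the peak exit speed; a uniform wind is superposed; and
#' a discrete-random-walk eddy velocity (intensity times the local mean jet
#' speed, integral time `t_int`) provides turbulent dispersion. The
#' decomposition into mean and fluctuating carrier velocity mirrors Reynolds
#' averaging.
#'
#' @param branches list of [jet_branch()]es.
#' @param wind length-3 wind vector (m/s).
#' @param intensity turbulent fluctuation intensity (fraction of the local
#'   mean jet speed).
#' @param t_int eddy integral time scale (s).
#' @param B_j round-jet centreline decay constant.
#' @param S jet spreading rate.
#' @return object of class `carrier_flow_model`.
#' @export
carrier_flow_model <- function(branches, wind = c(0, 0, 0), intensity = 0.15,
                               t_int = 0.05, B_j = 6.0, S = 0.11) {
  structure(list(branches = branches, wind = wind, intensity = intensity,
                 t_int = t_int, B_j = B_j, S = S),
            class = "carrier_flow_model")
}

#' Mean carrier velocity (and local fluctuation scale) at given points
#'
#' @param X n x 3 matrix of positions (m, mouth at origin).
#' @param t time (s).
#' @param model a [carrier_flow_model()].
#' @return list with `mean` (n x 3 m/s) and `sigma` (n, the turbulent
#'   fluctuation standard deviation = intensity x local mean jet speed).
#' @export
carrier_velocity <- function(X, t, model) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  n <- nrow(X)
  jet <- matrix(0, n, 3)
  for (br in model$branches) {
    s <- as.numeric(X %*% br$e)
    rv <- X - outer(s, br$e)
    r <- sqrt(rowSums(rv^2))
    tret <- t - s / br$c_adv
    ue <- br$ue(pmax(tret, 0))
    ue[tret < 0 | s < 0] <- 0
    fac <- pmin(1, model$B_j * br$d / pmax(s, 1e-9))
    sig_r <- pmax(br$d / 2, model$S * s)
    amp <- ue * fac * exp(-r^2 / (2 * sig_r^2))
    jet <- jet + outer(amp, br$e)
  }
  jetmag <- sqrt(rowSums(jet^2))
  list(mean = sweep(jet, 2, model$wind, "+"),
       sigma = model$intensity * jetmag)
}

#' Schiller-Naumann drag coefficient
#'
#' `C_D = 24/Re (1 + 0.15 Re^0.687)` for `Re <= 1000`, `0.44` above;
#' continuous at the branch point to within 1%.
#' @param Re_p droplet Reynolds number (>= 0; vectorized).
#' @return drag coefficient (Inf at Re = 0, the Stokes limit 24/Re).
#' @export
drag_coefficient <- function(Re_p) {
  if (any(Re_p < 0)) stop("domain error: negative Reynolds number")
  ifelse(Re_p <= 1000, 24 / Re_p * (1 + 0.15 * Re_p^0.687), 0.44)
}

# drag correction factor phi = C_D Re / 24 (1 in the Stokes limit)
drag_factor <- function(Re_p) {
  ifelse(Re_p <= 1000, 1 + 0.15 * Re_p^0.687, 0.44 * Re_p / 24)
}

#' Acceleration of droplets in a carrier flow
#'
#' Gravity + buoyancy and Schiller-Naumann drag (projected area
#' `pi d^2 / 4`); optional added-mass and pressure-gradient terms are
#' available as flags but default off since the droplet/air density ratio
#' (~830) makes them negligible (with a steady, slowly varying carrier the
#' pressure-gradient force is effectively zero and added mass only augments
#' the inertia).
#'
#' @param state list/data.frame with `d_um`, `ux`, `uy`, `uz` (and
#'   optionally `T_C`).
#' @param u_carrier n x 3 carrier velocity (m/s).
#' @param ambient an [ambient_conditions()].
#' @param gravity include gravity + buoyancy.
#' @param added_mass include the added-mass inertia augmentation.
#' @param rho_droplet liquid density (kg/m^3).
#' @return n x 3 acceleration matrix (m/s^2).
#' @export
droplet_acceleration <- function(state, u_carrier, ambient =
                                   ambient_conditions(wind_speed = 0),
                                 gravity = TRUE, added_mass = FALSE,
                                 rho_droplet = 1000) {
  if (is.null(dim(u_carrier))) u_carrier <- matrix(u_carrier, ncol = 3)
  d <- state$d_um * 1e-6
  stopifnot(all(d > 0))
  up <- cbind(state$ux, state$uy, state$uz)
  du <- u_carrier - up
  slip <- sqrt(rowSums(du^2))
  Re <- ambient$rho_air * slip * d / ambient$mu_air
  cd <- ifelse(slip > 0, drag_coefficient(pmax(Re, 1e-12)), 0)
  Ap <- pi * d^2 / 4
  m <- rho_droplet * pi * d^3 / 6
  FD <- 0.5 * cd * Ap * ambient$rho_air * slip * du
  FD[slip == 0, ] <- 0
  a <- FD / m
  if (gravity) {
    a[, 3] <- a[, 3] - .const$g * (1 - ambient$rho_air / rho_droplet)
  }
  if (added_mass) a <- a / (1 + 0.5 * ambient$rho_air / rho_droplet)
  a
}

#' Droplet evaporation rate (Spalding law with Ranz-Marshall convection)
#'
#' `mdot = -pi d rho_a D_v Sh ln(1 + B)` with the Spalding transfer number
#' `B = (Y_s - Y_inf)/(1 - Y_s)` built from the saturation mass fraction at
#' the droplet temperature and the ambient humidity, and
#' `Sh = 2 (1 + 0.3 Re^1/2 Sc^1/3)` (exactly 2 for a quiescent droplet).
#' Supersaturated surroundings are clamped to zero rate (condensation and
#' growth are not modelled).
#'
#' @param state list with `d_um` and optionally `T_C` (droplet temperature;
#'   defaults to the ambient temperature, the isothermal closure).
#' @param ambient an [ambient_conditions()].
#' @param slip_speed relative droplet-air speed (m/s; vectorized).
#' @return evaporation rate in kg/s (<= 0).
#' @export
evaporation_rate <- function(state, ambient = ambient_conditions(),
                             slip_speed = 0) {
  d <- state$d_um * 1e-6
  stopifnot(all(d > 0))
  T_p <- if (!is.null(state$T_C)) state$T_C else ambient$temperature_C
  Y_s <- vapor_mass_fraction(saturation_pressure(T_p), ambient$pressure)
  Y_inf <- vapor_mass_fraction(ambient$rh *
                                 saturation_pressure(ambient$temperature_C),
                               ambient$pressure)
  B <- pmax((Y_s - Y_inf) / (1 - Y_s), 0)
  Re <- ambient$rho_air * slip_speed * d / ambient$mu_air
  Sc <- ambient$mu_air / (ambient$rho_air * .const$D_vapor)
  Sh <- 2 * (1 + 0.3 * sqrt(Re) * Sc^(1 / 3))
  -pi * d * ambient$rho_air * .const$D_vapor * Sh * log(1 + B)
}

#' Droplet temperature rate from the enthalpy balance
#'
#' Convective heating (Ranz-Marshall Nusselt analogue) minus the latent-heat
#' sink of evaporation, divided by the droplet heat capacity. In
#' `isothermal` mode (the default) the rate is identically zero, honouring
#' the reference finding that the droplet temperature change is negligible
#' (< 1 C).
#'
#' @param state list with `d_um` and `T_C`.
#' @param ambient an [ambient_conditions()].
#' @param slip_speed relative speed (m/s).
#' @param isothermal freeze the droplet temperature.
#' @param rho_droplet,c_p liquid properties.
#' @return temperature rate (C/s).
#' @export
temperature_rate <- function(state, ambient = ambient_conditions(),
                             slip_speed = 0, isothermal = TRUE,
                             rho_droplet = 1000, c_p = 4186) {
  d <- state$d_um * 1e-6
  if (isothermal) return(rep(0, length(d)))
  m <- rho_droplet * pi * d^3 / 6
  stopifnot(all(m > 0))
  Re <- ambient$rho_air * slip_speed * d / ambient$mu_air
  Pr <- 0.71
  Nu <- 2 * (1 + 0.3 * sqrt(Re) * Pr^(1 / 3))
  mdot <- evaporation_rate(state, ambient, slip_speed)
  (pi * d * .const$k_air * Nu * (ambient$temperature_C - state$T_C) +
      .const$L_vap * mdot) / (m * c_p)
}

#' Integration controls for the dispersion stage
#' @param dt_fine,dt_coarse time steps (s) before/after `t_switch`.
#' @param t_switch time (s) after which the coarse step is used.
#' @param d_min_um evaporation endpoint diameter (um); droplets below it are
#'   removed as fully evaporated (no solid nucleus retained).
#' @param floor_z floor height relative to the mouth (m).
#' @param wall_x,wall_y,ceiling_z absorbing room boundaries relative to the
#'   mouth (8 x 8 x 4 m room, mouth at 1.6 m).
#' @param isothermal freeze droplet temperature (see [temperature_rate()]).
#' @param rho_droplet liquid density (kg/m^3).
#' @param gravity include gravity + buoyancy (disable only for closed-form
#'   oracle checks).
#' @param evaporation include evaporation.
#' @export
dispersion_control <- function(dt_fine = 1e-3, dt_coarse = 5e-3,
                               t_switch = 1.2, d_min_um = 1,
                               floor_z = -1.6, wall_x = 4, wall_y = 4,
                               ceiling_z = 2.4, isothermal = TRUE,
                               rho_droplet = 1000, gravity = TRUE,
                               evaporation = TRUE) {
  list(dt_fine = dt_fine, dt_coarse = dt_coarse, t_switch = t_switch,
       d_min_um = d_min_um, floor_z = floor_z, wall_x = wall_x,
       wall_y = wall_y, ceiling_z = ceiling_z, isothermal = isothermal,
       rho_droplet = rho_droplet, gravity = gravity,
       evaporation = evaporation)
}

# internal state container built from an injection batch
init_states <- function(batch) {
  n <- nrow(batch)
  fate <- rep(0L, n) # 0 airborne, 1 evaporated, 2 deposited, 3 captured
  if (!is.null(batch$route)) fate[batch$route == "captured"] <- 3L
  list(id = batch$id, x = batch$x, y = batch$y, z = batch$z,
       ux = batch$ux, uy = batch$uy, uz = batch$uz,
       d_um = batch$d_um, d0_um = batch$d_um, T_C = batch$T_C,
       weight = batch$weight, t_inject = batch$t_inject, fate = fate,
       maxx = pmax(batch$x, 0), maxy = abs(batch$y),
       ex = rep(0, n), ey = rep(0, n), ez = rep(0, n))
}

#' Advance droplet states by one time step
#'
#' Semi-implicit update: drag by an exponential integrator over the
#' (Schiller-Naumann-corrected) relaxation time, so the scheme is stable
#' when the relaxation time is much smaller than the step; trapezoidal
#' position update; diameter from the Spalding evaporation rate integrated
#' on d^2; discrete-random-walk eddy velocities refreshed with an
#' Ornstein-Uhlenbeck step. Fates: `deposited` on reaching the floor or a
#' wall, `evaporated` below the endpoint diameter.
#'
#' @param st state list from `init_states` (or a previous step).
#' @param carrier a [carrier_flow_model()].
#' @param ambient an [ambient_conditions()].
#' @param dt time step (s).
#' @param t current time (s).
#' @param control a [dispersion_control()].
#' @return the advanced state list.
#' @export
step_droplets <- function(st, carrier, ambient, dt, t,
                          control = dispersion_control()) {
  act <- which(st$fate == 0L & st$t_inject <= t)
  if (length(act) == 0) return(st)
  X <- cbind(st$x[act], st$y[act], st$z[act])
  cv <- carrier_velocity(X, t, carrier)

  # eddy velocity OU refresh
  aa <- exp(-dt / carrier$t_int)
  sg <- cv$sigma
  nb <- length(act)
  st$ex[act] <- aa * st$ex[act] + sqrt(1 - aa^2) * sg * stats::rnorm(nb)
  st$ey[act] <- aa * st$ey[act] + sqrt(1 - aa^2) * sg * stats::rnorm(nb)
  st$ez[act] <- aa * st$ez[act] + sqrt(1 - aa^2) * sg * stats::rnorm(nb)
  uc <- cv$mean + cbind(st$ex[act], st$ey[act], st$ez[act])

  d <- st$d_um[act] * 1e-6
  up <- cbind(st$ux[act], st$uy[act], st$uz[act])
  du <- uc - up
  slip <- sqrt(rowSums(du^2))
  Re <- ambient$rho_air * slip * d / ambient$mu_air
  phi <- drag_factor(Re)
  tau <- relaxation_time(d, control$rho_droplet, ambient$mu_air) / phi
  gz <- if (isTRUE(control$gravity)) {
    -.const$g * (1 - ambient$rho_air / control$rho_droplet)
  } else 0
  ut <- uc
  ut[, 3] <- ut[, 3] + tau * gz
  ef <- exp(-dt / tau)
  un <- ut + (up - ut) * ef
  Xn <- X + dt * (un + up) / 2

  # evaporation on d^2 (isothermal closure by default)
  stt <- list(d_um = st$d_um[act],
              T_C = if (control$isothermal) NULL else st$T_C[act])
  mdot <- if (isTRUE(control$evaporation)) {
    evaporation_rate(stt, ambient, slip)
  } else rep(0, length(d))
  # mdot = (pi/4) rho_l d (d(d^2)/dt)  =>  d(d^2)/dt = 4 mdot / (pi rho_l d)
  d2 <- d^2 + dt * 4 * mdot / (pi * control$rho_droplet * d)
  dn <- sqrt(pmax(d2, 0))
  if (!control$isothermal) {
    st$T_C[act] <- st$T_C[act] +
      dt * temperature_rate(list(d_um = st$d_um[act], T_C = st$T_C[act]),
                            ambient, slip, isothermal = FALSE,
                            rho_droplet = control$rho_droplet)
  }

  st$x[act] <- Xn[, 1]; st$y[act] <- Xn[, 2]; st$z[act] <- Xn[, 3]
  st$ux[act] <- un[, 1]; st$uy[act] <- un[, 2]; st$uz[act] <- un[, 3]
  st$d_um[act] <- dn * 1e6
  st$maxx[act] <- pmax(st$maxx[act], Xn[, 1])
  st$maxy[act] <- pmax(st$maxy[act], abs(Xn[, 2]))

  evap <- dn * 1e6 < control$d_min_um
  dep <- Xn[, 3] <= control$floor_z | Xn[, 3] >= control$ceiling_z |
    abs(Xn[, 1]) >= control$wall_x | abs(Xn[, 2]) >= control$wall_y
  st$fate[act[evap & !dep]] <- 1L
  st$fate[act[dep]] <- 2L
  st
}

#' Integrate a droplet batch to its fate and report transmission distances
#'
#' Runs all droplets of the batch from injection to evaporation, deposition
#' or the time horizon, recording each droplet's maximum forward (x) and
#' lateral (|y|) displacement achieved while liquid, and aggregates the
#' population maxima.
#'
#' @param batch an `injection_batch` (optionally routed by [transmit()]).
#' @param carrier a [carrier_flow_model()].
#' @param ambient an [ambient_conditions()].
#' @param t_max time horizon (s).
#' @param seed integer seed (turbulent dispersion).
#' @param control a [dispersion_control()].
#' @return object of class `dispersion_result`: per-droplet summary
#'   (`droplets`), weighted `fate_counts`, `max_forward_m`, `max_lateral_m`.
#' @export
run_dispersion <- function(batch, carrier, ambient, t_max = 10, seed = 1,
                           control = dispersion_control()) {
  st <- init_states(batch)
  if (nrow(batch) > 0) {
    st <- with_seed(seed, {
      t <- 0
      while (t < t_max) {
        dt <- if (t < control$t_switch) control$dt_fine else control$dt_coarse
        st <- step_droplets(st, carrier, ambient, dt, t, control)
        t <- t + dt
        if (!any(st$fate == 0L) && t > max(st$t_inject)) break
      }
      st
    })
  }
  fate_lab <- c("airborne", "evaporated", "deposited", "captured")
  fl <- factor(fate_lab[st$fate + 1L], levels = fate_lab)
  drops <- data.frame(id = st$id, d0_um = st$d0_um, d_um = st$d_um,
                      fate = fl, x = st$x, y = st$y, z = st$z,
                      max_forward = st$maxx, max_lateral = st$maxy,
                      weight = st$weight)
  tracked <- st$fate != 3L
  structure(list(
    droplets = drops,
    fate_counts = tapply(st$weight, fl, sum, default = 0),
    max_forward_m = if (any(tracked)) max(0, st$maxx[tracked]) else 0,
    max_lateral_m = if (any(tracked)) max(0, st$maxy[tracked]) else 0,
    t_max = t_max, n = nrow(batch), seed = seed),
    class = "dispersion_result")
}

#' @method print dispersion_result
#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> n = %d: max forward %.3f m, max lateral %.3f m\n",
              x$n, x$max_forward_m, x$max_lateral_m))
  fc <- x$fate_counts
  cat("  fate weights:", paste(names(fc), round(fc), sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Quick look at where the droplets ended up
#'
#' Scatter of final droplet positions in the side (x-z) plane, coloured by
#' fate; a plain diagnostic, not a publication figure.
#' @param x a `dispersion_result`.
#' @param ... passed to [graphics::plot()].
#' @method plot dispersion_result
#' @export
plot.dispersion_result <- function(x, ...) {
  d <- x$droplets
  cols <- c(airborne = "grey40", evaporated = "steelblue",
            deposited = "firebrick", captured = "black")
  graphics::plot(d$x, d$z, col = cols[as.character(d$fate)],
                 pch = 16, cex = 0.5, xlab = "forward x (m)",
                 ylab = "height above mouth z (m)", ...)
  graphics::abline(h = -1.6, lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8)
  invisible(x)
}

#' Build the carrier-flow model for a (routed) batch
#'
#' Unmasked batches drive a single mouth jet with the sneeze profile;
#' masked batches drive one broad low-speed branch for the filter face plus
#' one branch per leak port with the capped orifice exit velocity.
#'
#' @param batch an `injection_batch`, routed by [transmit()] when masked.
#' @param ambient an [ambient_conditions()] (supplies the wind vector).
#' @param v_cap port jet velocity cap (m/s).
#' @param ... passed to [carrier_flow_model()] (turbulence and jet
#'   constants).
#' @return a [carrier_flow_model()].
#' @export
carrier_for_batch <- function(batch, ambient, v_cap = 10, ...) {
  mouth <- attr(batch, "mouth")
  profile <- attr(batch, "profile")
  mask <- attr(batch, "mask")
  split <- attr(batch, "split")
  if (is.null(mask)) {
    br <- list(jet_branch(c(1, 0, 0), mouth$diameter,
                          function(t) flow_velocity(pmax(t, 0), profile),
                          "mouth"))
  } else {
    d_filter <- sqrt(4 * mask$filter_area / pi)
    uf <- stats::approxfun(split$time, split$Q_mask / mask$filter_area,
                           yleft = 0, yright = 0)
    br <- list(jet_branch(c(1, 0, 0), d_filter, uf, "filter"))
    for (i in seq_len(nrow(mask$ports))) {
      if (mask$ports$area[i] <= 0) next
      vo <- pmin(mask$ports$discharge[i] * sqrt(2 * split$dp / split$rho_air),
                 v_cap)
      uo <- stats::approxfun(split$time, vo, yleft = 0, yright = 0)
      dir <- c(mask$ports$dx[i], mask$ports$dy[i], mask$ports$dz[i])
      br <- c(br, list(jet_branch(dir, sqrt(4 * mask$ports$area[i] / pi),
                                  uo, mask$ports$label[i])))
    }
  }
  carrier_flow_model(br, wind = ambient$wind, ...)
}
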