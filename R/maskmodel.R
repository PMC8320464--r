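#' Default face-seal leak ports
#'
#' Leakage occurs through the mask periphery at the nose bridge and the two
#' cheeks. Default geometry: the nose gap vents upward at 60 degrees from
#' the forward axis, cheek gaps vent laterally with a 20 degree downward
#' tilt, and the nose:cheek:cheek area ratio is 2:1:1. Areas are placeholders
#' until [calibrate_ports()] scales them to the target leakage rate.
#'
#' @param total_area initial total gap area (m^2).
#' @param discharge_coefficient orifice discharge coefficient.
#' @return data.frame with one row per port.
#' @export
default_leak_ports <- function(total_area = 2e-5, discharge_coefficient = 0.61) {
  s60 <- sin(pi / 3); c60 <- cos(pi / 3)
  s20 <- sin(pi / 9); c20 <- cos(pi / 9)
  data.frame(
    label = c("nose", "cheek_left", "cheek_right"),
    area = total_area * c(0.5, 0.25, 0.25),
    dx = c(c60, 0, 0),
    dy = c(0, -c20, c20),
    dz = c(s60, -s20, -s20),
    discharge = discharge_coefficient)
}

#' Macroscopic mask model
#'
#' Bundles the micro-scale results (size-resolved penetration curve, Darcy
#' permeability, thickness) with the macroscopic boundary data (filter area,
#' leak ports, target leakage rate) needed by the dispersion stage.
#'
#' @param penetration a `penetration_curve` for the full layer stack.
#' @param permeability Darcy permeability k (m^2).
#' @param thickness_m total media thickness t_f (m).
#' @param filter_area effective exposed filter area (m^2); 150 cm^2 default.
#' @param ports leak-port data.frame as in [default_leak_ports()].
#' @param target_leakage target average leakage rate (fraction, e.g. 0.11 for
#'   a KF94-class fit or 0.25 for KF80).
#' @param type label ("A", "B", or free text).
#' @return object of class `mask_model`.
#' @export
mask_model <- function(penetration, permeability, thickness_m,
                       filter_area = 0.015, ports = default_leak_ports(),
                       target_leakage = 0.11, type = "custom") {
  stopifnot(permeability > 0, thickness_m > 0,
            target_leakage >= 0, target_leakage < 1)
  structure(list(penetration = penetration, k = permeability,
                 t_f = thickness_m, filter_area = filter_area,
                 ports = ports, target_leakage = target_leakage,
                 type = type),
            class = "mask_model")
}

#' @method print mask_model
#' @export
print.mask_model <- function(x, ...) {
  cat(sprintf("<mask_model Type %s> k = %.3g m^2, t_f = %.3g m, target leakage %.0f%%, gap area %.2f cm^2\n",
              x$type, x$k, x$t_f, 100 * x$target_leakage,
              1e4 * sum(x$ports$area)))
  invisible(x)
}

#' Split the exhaled flow between the filter medium and the leak gaps
#'
#' At each instant a common driving pressure difference dp satisfies the
#' Darcy law through the medium, `Q_mask = k A dp / (mu t_f)`, and the
#' orifice law through the gaps, `Q_leak = sum(C A_port) sqrt(2 dp / rho)`,
#' with `Q_mask + Q_leak` equal to the mouth flow. The quadratic in
#' sqrt(dp) is solved in closed form. The average leakage rate is the
#' time-integrated leak flow over the time-integrated total flow.
#'
#' @param mask a [mask_model()].
#' @param mouth_flow data.frame with columns `time` (s) and `Q` (m^3/s).
#' @param rho_air air density (kg/m^3).
#' @param mu_air air viscosity (kg/(m s)).
#' @return object of class `flow_split` with time series `Q_total`,
#'   `Q_mask`, `Q_leak`, `dp` and the scalar `avg_leakage`.
#' @export
flow_split <- function(mask, mouth_flow, rho_air = 1.204,
                       mu_air = 1.834e-5) {
  stopifnot(all(mouth_flow$Q >= 0))
  b <- mask$k * mask$filter_area / (mu_air * mask$t_f)
  a <- sum(mask$ports$discharge * mask$ports$area) * sqrt(2 / rho_air)
  Q <- mouth_flow$Q
  x <- if (a > 0) (-a + sqrt(a^2 + 4 * b * Q)) / (2 * b) else sqrt(Q / b)
  dp <- x^2
  Qleak <- a * x
  Qmask <- Q - Qleak
  avg <- if (sum(Q) > 0) {
    pracma::trapz(mouth_flow$time, Qleak) / pracma::trapz(mouth_flow$time, Q)
  } else 0
  structure(list(time = mouth_flow$time, Q_total = Q, Q_mask = Qmask,
                 Q_leak = Qleak, dp = dp, avg_leakage = avg,
                 rho_air = rho_air),
            class = "flow_split")
}

#' Mouth volumetric flow series for a sneeze profile
#' @param profile a [sneeze_profile()].
#' @param mouth a [mouth_geometry()].
#' @param dt time resolution (s).
#' @return data.frame with `time` and `Q`.
#' @export
mouth_flow_series <- function(profile = sneeze_profile(),
                              mouth = mouth_geometry(), dt = 1e-3) {
  tg <- seq(0, profile$duration, by = dt)
  data.frame(time = tg, Q = flow_velocity(tg, profile) * mouth$area)
}

#' Calibrate leak-port areas to a target average leakage rate
#'
#' Scales all port areas by a common factor (nose:cheek ratio preserved)
#' by bisection until the 0.4 s average leakage matches the mask's
#' `target_leakage` within +/- 0.5 percentage points.
#'
#' @param mask a [mask_model()] with `target_leakage` set.
#' @param mouth_flow as in [flow_split()].
#' @param tol leakage tolerance (fraction).
#' @return the mask with scaled port areas; achieved leakage in attribute
#'   `"achieved_leakage"`.
#' @export
calibrate_ports <- function(mask, mouth_flow = mouth_flow_series(),
                            tol = 0.005) {
  target <- mask$target_leakage
  if (target <= 0) {
    mask$ports$area <- 0
    attr(mask, "achieved_leakage") <- 0
    return(mask)
  }
  base <- mask$ports
  leak_at <- function(s) {
    m <- mask
    m$ports$area <- base$area * s
    flow_split(m, mouth_flow)$avg_leakage
  }
  # fixed point: already-calibrated ports are returned unchanged
  cur <- leak_at(1)
  if (abs(cur - target) <= tol * 0.2) {
    attr(mask, "achieved_leakage") <- cur
    return(mask)
  }
  lo <- 0; hi <- 1
  while (leak_at(hi) < target && hi < 1e6) hi <- hi * 2
  if (leak_at(hi) < target) stop("calibration error: target leakage unreachable")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    lm <- leak_at(mid)
    if (abs(lm - target) <= tol * 0.2) { lo <- hi <- mid; break }
    if (lm < target) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  mask$ports$area <- base$area * s
  ach <- leak_at(s)
  if (abs(ach - target) > tol) {
    stop(sprintf("calibration error: achieved leakage %.3f vs target %.3f",
                 ach, target))
  }
  attr(mask, "achieved_leakage") <- ach
  mask
}

#' Route an injected droplet batch through the mask
#'
#' Each droplet is routed to the filter medium or a leak gap with
#' probability proportional to the instantaneous flow fractions at its
#' injection time. Reaching a gap requires following the sharp bend of the
#' leak path along the face, so gap admission carries a bend-impaction
#' cutoff: droplets whose momentum relaxation time exceeds
#' `stk_crit * tau_gap` cannot make the turn and are routed to the filter
#' (set `inertial_admission = FALSE` to route purely by flow fraction).
#' Filter-routed droplets survive with the size-resolved penetration
#' probability and exit forward with the filter face velocity; gap-routed
#' droplets exit along the port direction with the orifice velocity (capped
#' at `v_cap`). Statistical weights are preserved and
#' injected = captured + routed survivors exactly.
#'
#' @param batch an `injection_batch`.
#' @param mask a calibrated [mask_model()].
#' @param split the [flow_split()] for the same sneeze profile.
#' @param seed integer seed.
#' @param inertial_admission logical, see above.
#' @param tau_gap characteristic turning time of the gap flow (s).
#' @param stk_crit critical Stokes number for bend impaction.
#' @param v_cap exit-jet velocity cap (m/s).
#' @param rho_droplet liquid density (kg/m^3).
#' @return the batch with a `route` column (`"filter"`, `"nose"`,
#'   `"cheek_left"`, `"cheek_right"` or `"captured"`) and exit velocities
#'   replacing the mouth velocities for survivors.
#' @export
transmit <- function(batch, mask, split, seed = 1,
                     inertial_admission = TRUE, tau_gap = 2e-4,
                     stk_crit = 0.25, v_cap = 10,
                     rho_droplet = 1000) {
  n <- nrow(batch)
  if (n == 0) { batch$route <- character(0); return(batch) }
  fr_leak <- stats::approx(split$time,
                           ifelse(split$Q_total > 0,
                                  split$Q_leak / pmax(split$Q_total, 1e-30), 0),
                           xout = batch$t_inject, rule = 2)$y
  u_filter <- stats::approx(split$time, split$Q_mask / mask$filter_area,
                            xout = batch$t_inject, rule = 2)$y
  dp_t <- stats::approx(split$time, split$dp, xout = batch$t_inject,
                        rule = 2)$y
  v_orifice <- pmin(mask$ports$discharge[1] * sqrt(2 * dp_t / split$rho_air),
                    v_cap)

  dpm <- batch$d_um * 1e-6
  tau_p <- relaxation_time(dpm, rho_droplet)
  eligible <- if (inertial_admission) tau_p <= stk_crit * tau_gap else
    rep(TRUE, n)

  out <- with_seed(seed, {
    u1 <- stats::runif(n)
    to_leak <- eligible & (u1 < fr_leak)
    pw <- mask$ports$area * mask$ports$discharge
    port_idx <- if (sum(pw) > 0) {
      sample.int(nrow(mask$ports), n, replace = TRUE, prob = pw / sum(pw))
    } else rep(1L, n)
    u2 <- stats::runif(n)
    pen <- penetration_at(mask$penetration, batch$d_um)
    survive_filter <- !to_leak & (u2 < pen)
    route <- rep("captured", n)
    route[survive_filter] <- "filter"
    route[to_leak] <- mask$ports$label[port_idx[to_leak]]
    list(route = route, port_idx = port_idx)
  })
  route <- out$route
  b <- batch
  b$route <- route
  # survivors get branch exit velocities; captured droplets keep zeros
  b$ux <- 0; b$uy <- 0; b$uz <- 0
  fsel <- route == "filter"
  b$ux[fsel] <- u_filter[fsel]
  for (pi_ in seq_len(nrow(mask$ports))) {
    sel <- route == mask$ports$label[pi_]
    if (any(sel)) {
      b$ux[sel] <- v_orifice[sel] * mask$ports$dx[pi_]
      b$uy[sel] <- v_orifice[sel] * mask$ports$dy[pi_]
      b$uz[sel] <- v_orifice[sel] * mask$ports$dz[pi_]
    }
  }
  attr(b, "mask") <- mask
  attr(b, "split") <- split
  b
}

#' Assemble a mask model from the micro-scale pipeline
#'
#' Runs the full micro chain for one mask type: calibrates the layer specs
#' against the measured single-layer efficiencies (spunbond 9.3%, meltblown
#' 95.0% at the 0.6 um test size), generates representative slabs of each
#' calibrated layer, solves Stokes flow at the 0.1 m/s face velocity,
#' tracks the size-resolved penetration, composes layers in series
#' (pressure drop) and product (penetration), and calibrates the leak ports
#' to the target leakage rate.
#'
#' @param type `"A"` (two spunbond layers) or `"B"`
#'   (spunbond/meltblown/spunbond).
#' @param target_leakage average leakage rate target (0.11 or 0.25).
#' @param seed integer seed.
#' @param control a [micro_control()].
#' @param face_velocity filtration face velocity (m/s).
#' @param measured single-layer efficiencies used for calibration.
#' @param calibrated optional named list of pre-calibrated layer specs
#'   (`spunbond`, `meltblown`) to skip the calibration stage.
#' @param mouth_flow flow series for the port calibration.
#' @return a calibrated [mask_model()]; layer diagnostics (per-layer
#'   permeabilities, calibrated specs) in attribute `"micro"`.
#' @export
build_mask_model <- function(type = c("A", "B"), target_leakage = 0.11,
                             seed = 1, control = micro_control(),
                             face_velocity = 0.1,
                             measured = c(spunbond = 0.093, meltblown = 0.95),
                             calibrated = NULL,
                             mouth_flow = mouth_flow_series()) {
  type <- match.arg(type)
  layers <- layer_micro_library(
    need_meltblown = (type == "B"), seed = seed, control = control,
    face_velocity = face_velocity, measured = measured,
    calibrated = calibrated)
  mask_from_library(layers, type, target_leakage,
                    face_velocity = face_velocity, mouth_flow = mouth_flow)
}

#' Assemble a mask model from an existing layer micro library
#'
#' Composes the per-layer results of [layer_micro_library()] into a Type A
#' (spunbond x2) or Type B (spunbond/meltblown/spunbond) mask: pressure
#' drops add in series, penetrations multiply, and the leak ports are
#' calibrated to the target leakage rate. Splitting this from
#' [build_mask_model()] lets one micro computation serve both mask types
#' and several leakage targets.
#'
#' @param layers result of [layer_micro_library()].
#' @param type `"A"` or `"B"`.
#' @param target_leakage average leakage rate target.
#' @param face_velocity filtration face velocity (m/s).
#' @param mouth_flow flow series for the port calibration.
#' @return a calibrated [mask_model()] with the layer diagnostics in
#'   attribute `"micro"`.
#' @export
mask_from_library <- function(layers, type = c("A", "B"),
                              target_leakage = 0.11, face_velocity = 0.1,
                              mouth_flow = mouth_flow_series()) {
  type <- match.arg(type)
  sb <- layers$spunbond
  if (type == "A") {
    t_f <- 2 * sb$spec$thickness_um * 1e-6
    dP <- 2 * sb$dP_layer
    curve <- stack_penetration(list(sb$curve_layer, sb$curve_layer))
  } else {
    mb <- layers$meltblown
    if (is.null(mb)) stop("meltblown layer missing from the micro library")
    t_f <- (2 * sb$spec$thickness_um + mb$spec$thickness_um) * 1e-6
    dP <- 2 * sb$dP_layer + mb$dP_layer
    curve <- stack_penetration(list(sb$curve_layer, mb$curve_layer,
                                    sb$curve_layer))
  }
  k <- darcy_permeability(face_velocity, dP, t_f)
  m <- mask_model(curve, k, t_f, target_leakage = target_leakage, type = type)
  m <- calibrate_ports(m, mouth_flow)
  attr(m, "micro") <- layers
  m
}

#' Calibrate and characterize the constituent layers
#'
#' Shared stage of [build_mask_model()]: per-layer calibration plus
#' representative-slab penetration curves and pressure drops, averaged over
#' `control$n_realizations` web realizations. Exposed so Type A and Type B
#' masks (and repeated leakage variants) can reuse one micro computation.
#'
#' @inheritParams build_mask_model
#' @param need_meltblown include the meltblown layer.
#' @return named list of per-layer results (`spec`, `curve_layer` scaled to
#'   the full layer thickness, `dP_layer` in Pa, `k_layer` in m^2).
#' @export
layer_micro_library <- function(need_meltblown = TRUE, seed = 1,
                                control = micro_control(),
                                face_velocity = 0.1,
                                measured = c(spunbond = 0.093,
                                             meltblown = 0.95),
                                calibrated = NULL) {
  out <- list()
  specs <- list(spunbond = spunbond_spec(), meltblown = meltblown_spec())
  wanted <- c("spunbond", if (need_meltblown) "meltblown")
  for (nm in wanted) {
    sp0 <- if (!is.null(calibrated[[nm]])) calibrated[[nm]] else {
      calibrate_layer(measured[[nm]], at_diameter = 0.6, spec = specs[[nm]],
                      control = control, seed = seed)
    }
    g <- slab_geometry(sp0, control)
    scale_f <- sp0$thickness_um / g$slab_um
    dPs <- numeric(0)
    counts <- NULL
    for (r in seq_len(control$n_realizations)) {
      slab <- sp0
      slab$thickness_um <- g$slab_um
      lay <- generate_layer(slab, c(g$lateral_m, g$lateral_m), g$h,
                            seed = seed + 100L * r)
      fld <- solve_stokes(lay, face_velocity, flow_params(),
                          pad = control$pad)
      dPs <- c(dPs, pressure_drop(fld))
      cr <- track_particles(fld, lay, sizes = control$sizes,
                            n_per_size = control$n_per_size,
                            seed = seed + 100L * r + 13L)
      counts <- if (is.null(counts)) cr else {
        agg <- counts
        for (col in c("injected", "captured", "penetrated", "unresolved",
                      "mech_diffusion", "mech_interception",
                      "mech_impaction")) {
          agg[[col]] <- agg[[col]] + cr[[col]]
        }
        agg
      }
    }
    dP_slab <- mean(dPs)
    curve_slab <- penetration_curve(counts)
    out[[nm]] <- list(
      spec = sp0,
      dP_slab = dP_slab,
      dP_layer = dP_slab * scale_f,
      k_layer = darcy_permeability(face_velocity, dP_slab,
                                   g$slab_um * 1e-6),
      curve_slab = curve_slab,
      curve_layer = scale_penetration(curve_slab, scale_f))
  }
  out
}
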