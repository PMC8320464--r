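#' Sneeze flow-velocity profile
#'
#' The expiratory jet rises to its peak (4.5 m/s at 0.1 s) and returns to
#' zero at the end of the 0.4 s event. The rise/decay shape is not tabulated
#' in the reference data, so it is configurable: piecewise-linear
#' (triangular) or a half-sine over the event.
#'
#' @param peak_velocity peak air speed (m/s).
#' @param ramp_time time of the peak (s).
#' @param duration event duration (s).
#' @param shape `"piecewise_linear"` or `"half_sine"`.
#' @return object of class `sneeze_profile`.
#' @export
sneeze_profile <- function(peak_velocity = 4.5, ramp_time = 0.1,
                           duration = 0.4,
                           shape = c("piecewise_linear", "half_sine")) {
  shape <- match.arg(shape)
  stopifnot(peak_velocity > 0, ramp_time > 0, duration > ramp_time)
  structure(list(peak_velocity = peak_velocity, ramp_time = ramp_time,
                 duration = duration, shape = shape),
            class = "sneeze_profile")
}

#' Instantaneous sneeze flow velocity
#' @param t time since sneeze onset (s), >= 0; vectorized.
#' @param profile a [sneeze_profile()].
#' @return velocity (m/s); zero outside `[0, duration]`.
#' @export
flow_velocity <- function(t, profile = sneeze_profile()) {
  if (any(t < 0)) stop("domain error: negative time")
  p <- profile
  v <- if (p$shape == "piecewise_linear") {
    ifelse(t <= p$ramp_time,
           p$peak_velocity * t / p$ramp_time,
           p$peak_velocity * pmax(0, (p$duration - t) / (p$duration - p$ramp_time)))
  } else {
    ifelse(t <= p$duration, p$peak_velocity * sin(pi * t / p$duration)^1, 0)
  }
  ifelse(t > p$duration, 0, pmax(v, 0))
}

#' Droplet size distribution of a sneeze
#'
#' Bimodal lognormal number distribution truncated to [0.4, 1500] um. The
#' default modes (12 um with sigma_g 1.8; coarse mode 120 um with sigma_g
#' 2.3 and number weight 0.04) mimic the accumulated sneeze size
#' distributions used in the literature: most droplets (>= 95% by number)
#' are below 50 um, while the coarse tail still contains a handful of
#' millimetre-class ballistic droplets per 40 000 — the droplets observed to
#' carry the maximum forward distance.
#'
#' @param modes_um lognormal number-mode medians (um).
#' @param sigma_g geometric standard deviations.
#' @param weights number weights (sum to 1).
#' @param support truncation range (um).
#' @return object of class `droplet_size_distribution`.
#' @export
droplet_size_distribution <- function(modes_um = c(12, 120),
                                      sigma_g = c(1.8, 2.3),
                                      weights = c(0.96, 0.04),
                                      support = c(0.4, 1500)) {
  stopifnot(length(modes_um) == length(sigma_g),
            length(modes_um) == length(weights),
            all(weights >= 0), sum(weights) > 0)
  structure(list(modes_um = modes_um, sigma_g = sigma_g,
                 weights = weights / sum(weights), support = support),
            class = "droplet_size_distribution")
}

#' CDF of the (truncated) droplet size distribution
#' @param d_um diameters (um).
#' @param dist a [droplet_size_distribution()].
#' @return cumulative probability.
#' @export
droplet_size_cdf <- function(d_um, dist = droplet_size_distribution()) {
  raw <- function(x) {
    out <- 0
    for (i in seq_along(dist$modes_um)) {
      out <- out + dist$weights[i] *
        stats::pnorm(log(x), log(dist$modes_um[i]), log(dist$sigma_g[i]))
    }
    out
  }
  lo <- raw(dist$support[1]); hi <- raw(dist$support[2])
  pmin(pmax((raw(d_um) - lo) / (hi - lo), 0), 1)
}

#' Mouth opening geometry
#'
#' @param area opening area (m^2); default a 4 cm^2 circular mouth.
#' @param height mouth height above the floor (m); default 1.60 m for a
#'   1.72 m tall person.
#' @param direction unit emission direction (forward = +x).
#' @return object of class `mouth_geometry`.
#' @export
mouth_geometry <- function(area = 4e-4, height = 1.60,
                           direction = c(1, 0, 0)) {
  stopifnot(area > 0, height > 0)
  structure(list(area = area, height = height,
                 direction = direction / sqrt(sum(direction^2)),
                 diameter = sqrt(4 * area / pi)),
            class = "mouth_geometry")
}

#' Sample the injected droplet population of one sneeze
#'
#' Draws `n` droplet parcels, each representing `total_count_represented/n`
#' physical droplets, with diameters from the size distribution, injection
#' times proportional to the instantaneous flow rate, initial velocity equal
#' to the air profile at the injection time (along +x), and positions on the
#' mouth disc.
#'
#' @param dist a [droplet_size_distribution()].
#' @param n number of parcels (0 allowed).
#' @param total_count_represented physical droplet count carried by the
#'   batch (default the literature sneeze count of 40 000).
#' @param seed integer seed.
#' @param profile a [sneeze_profile()].
#' @param mouth a [mouth_geometry()].
#' @param temperature_C initial droplet temperature.
#' @return object of class `injection_batch` (a data.frame: id, d_um, x, y,
#'   z, ux, uy, uz, T_C, weight, t_inject) with the inputs attached as
#'   attributes.
#' @export
sample_droplets <- function(dist = droplet_size_distribution(), n = 5000,
                            total_count_represented = 40000, seed = 1,
                            profile = sneeze_profile(),
                            mouth = mouth_geometry(), temperature_C = 34) {
  n <- as.integer(n)
  if (n == 0) {
    out <- data.frame(id = integer(0), d_um = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), ux = numeric(0),
                      uy = numeric(0), uz = numeric(0), T_C = numeric(0),
                      weight = numeric(0), t_inject = numeric(0))
    class(out) <- c("injection_batch", "data.frame")
    attr(out, "profile") <- profile; attr(out, "mouth") <- mouth
    return(out)
  }
  out <- with_seed(seed, {
    # diameters: mixture lognormal, truncated by rejection
    comp <- sample.int(length(dist$weights), n, replace = TRUE,
                       prob = dist$weights)
    d <- stats::rlnorm(n, log(dist$modes_um[comp]), log(dist$sigma_g[comp]))
    bad <- d < dist$support[1] | d > dist$support[2]
    while (any(bad)) {
      nb <- sum(bad)
      comp2 <- sample.int(length(dist$weights), nb, replace = TRUE,
                          prob = dist$weights)
      d[bad] <- stats::rlnorm(nb, log(dist$modes_um[comp2]),
                              log(dist$sigma_g[comp2]))
      bad <- d < dist$support[1] | d > dist$support[2]
    }
    # injection times ~ instantaneous flow rate (inverse-CDF on a fine grid)
    tg <- seq(0, profile$duration, length.out = 2001)
    q <- flow_velocity(tg, profile)
    cdf <- cumsum(q); cdf <- cdf / cdf[length(cdf)]
    ti <- stats::approx(cdf, tg, xout = stats::runif(n), rule = 2,
                        ties = "ordered")$y
    # positions on the mouth disc (x forward, so the disc spans y-z)
    rr <- mouth$diameter / 2 * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    u0 <- flow_velocity(ti, profile)
    data.frame(id = seq_len(n), d_um = d, x = 0, y = rr * cos(th),
               z = rr * sin(th), ux = u0, uy = 0, uz = 0,
               T_C = temperature_C, weight = total_count_represented / n,
               t_inject = ti)
  })
  class(out) <- c("injection_batch", "data.frame")
  attr(out, "profile") <- profile
  attr(out, "mouth") <- mouth
  attr(out, "total_count") <- total_count_represented
  out
}
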