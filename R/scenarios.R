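.case_table <- data.frame(
  id = 1:8,
  mask = c("none", "A", "A", "B", "B", "B", "B", "B"),
  leakage = c(NA, 0.11, 0.25, 0.11, 0.25, 0.11, 0.11, 0.11),
  wind = c("none", "none", "none", "none", "none", "head", "tail", "side"),
  stringsAsFactors = FALSE)

#' Build one of the eight mask-wearing scenarios
#'
#' Case 1: no mask; Cases 2/3: Type A at 11%/25% leakage; Cases 4/5: Type B
#' at 11%/25%; Cases 6/7/8: Type B at 11% with head/tail/side wind
#' (1.96 m/s). Still-air room 8 x 8 x 4 m, person 1.72 m tall (mouth at
#' 1.60 m), 20 C / 70% RH.
#'
#' @param id case number 1-8.
#' @param n parcels to inject.
#' @param seeds integer vector of ensemble seeds (the reported distance is
#'   the ensemble maximum).
#' @param t_max integration horizon (s).
#' @param overrides named list of component overrides (`profile`, `mouth`,
#'   `dist`, `ambient`, `control`, `total_count`).
#' @return object of class `scenario_config`.
#' @export
build_case <- function(id, n = 2000, seeds = 101:105, t_max = 10,
                       overrides = list()) {
  if (!is.numeric(id) || length(id) != 1 || !(id %in% 1:8)) {
    stop("argument error: case id must be one of 1..8")
  }
  row <- .case_table[.case_table$id == id, ]
  amb <- if (!is.null(overrides$ambient)) overrides$ambient else {
    ambient_conditions(wind_speed = if (row$wind == "none") 0 else 1.96,
                       wind_direction = row$wind)
  }
  structure(list(
    id = as.integer(id),
    mask_type = row$mask,
    leakage = row$leakage,
    wind = row$wind,
    ambient = amb,
    profile = overrides$profile %||% sneeze_profile(),
    mouth = overrides$mouth %||% mouth_geometry(),
    dist = overrides$dist %||% droplet_size_distribution(),
    control = overrides$control %||% dispersion_control(),
    total_count = overrides$total_count %||% 40000,
    n = as.integer(n), seeds = as.integer(seeds), t_max = t_max),
    class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print scenario_config
#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config Case %d> mask %s%s, wind %s, n = %d, %d seed(s)\n",
              x$id, x$mask_type,
              if (!is.na(x$leakage)) sprintf(" (leakage %.0f%%)", 100 * x$leakage) else "",
              x$wind, x$n, length(x$seeds)))
  invisible(x)
}

#' Run one scenario end to end
#'
#' Chains droplet sampling, mask routing (for masked cases) and Lagrangian
#' dispersion for every ensemble seed; reports per-seed and ensemble-maximum
#' transmission distances.
#'
#' @param config a [build_case()] configuration.
#' @param masks named list of calibrated [mask_model()]s (`A`, `B`) as built
#'   by [build_mask_model()]; required for masked cases.
#' @return object of class `case_result` with `per_seed` (data.frame),
#'   `max_forward_m`, `max_lateral_m` and the configuration.
#' @export
run_case <- function(config, masks = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  mask <- NULL
  if (config$mask_type != "none") {
    mask <- masks[[config$mask_type]]
    if (is.null(mask)) {
      stop("missing penetration curve / mask model for Type ",
           config$mask_type,
           ": build it first with build_mask_model(type = \"",
           config$mask_type, "\", target_leakage = ", config$leakage, ")")
    }
    if (abs(mask$target_leakage - config$leakage) > 1e-9) {
      mask$target_leakage <- config$leakage
      mask <- calibrate_ports(mask, mouth_flow_series(config$profile,
                                                      config$mouth))
    }
    split <- flow_split(mask, mouth_flow_series(config$profile, config$mouth))
  }
  rows <- list()
  results <- list()
  for (sd in config$seeds) {
    batch <- sample_droplets(config$dist, n = config$n,
                             total_count_represented = config$total_count,
                             seed = sd, profile = config$profile,
                             mouth = config$mouth)
    if (!is.null(mask)) {
      batch <- transmit(batch, mask, split, seed = sd + 500L)
    }
    carrier <- carrier_for_batch(batch, config$ambient)
    res <- run_dispersion(batch, carrier, config$ambient,
                          t_max = config$t_max, seed = sd + 900L,
                          control = config$control)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = sd, max_forward_m = res$max_forward_m,
      max_lateral_m = res$max_lateral_m,
      w_captured = unname(res$fate_counts["captured"]),
      w_evaporated = unname(res$fate_counts["evaporated"]),
      w_deposited = unname(res$fate_counts["deposited"]),
      w_airborne = unname(res$fate_counts["airborne"]))
    results[[length(results) + 1L]] <- res
  }
  per_seed <- do.call(rbind, rows)
  structure(list(config = config, per_seed = per_seed, results = results,
                 max_forward_m = max(per_seed$max_forward_m),
                 max_lateral_m = max(per_seed$max_lateral_m)),
            class = "case_result")
}

#' @method print case_result
#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result Case %d> max forward %.3f m, max lateral %.3f m over %d seed(s)\n",
              x$config$id, x$max_forward_m, x$max_lateral_m,
              nrow(x$per_seed)))
  invisible(x)
}

#' Compare scenario results against the unmasked baseline
#'
#' @param reports list of `case_result`s including Case 1.
#' @return object of class `case_report`: a table of maximum distances and
#'   percent reductions relative to Case 1.
#' @export
compare_cases <- function(reports) {
  ids <- vapply(reports, function(r) r$config$id, integer(1))
  if (!1L %in% ids) stop("argument error: Case 1 baseline required")
  base <- reports[[which(ids == 1L)[1]]]
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(case = r$config$id, mask = r$config$mask_type,
               leakage = r$config$leakage, wind = r$config$wind,
               max_forward_m = r$max_forward_m,
               max_lateral_m = r$max_lateral_m,
               reduction_forward_pct =
                 100 * (base$max_forward_m - r$max_forward_m) /
                 base$max_forward_m)
  }))
  tab <- tab[order(tab$case), ]
  rownames(tab) <- NULL
  class(tab) <- c("case_report", "data.frame")
  tab
}

#' Read scenario overrides from a YAML configuration file
#'
#' Recognized blocks: `source` (peak, ramp, duration, total_count,
#' modes_um, sigma_g, weights), `ambient` (temperature_C, rh, wind_speed,
#' wind_direction), `scenario` (case, n_parcels, seeds, t_max). The parcel
#' count key is `n_parcels` because a bare `n` is a YAML 1.1 boolean.
#' @param path YAML file path.
#' @return a [build_case()] configuration.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scenario %||% list()
  ov <- list()
  if (!is.null(cfg$source)) {
    s <- cfg$source
    ov$profile <- sneeze_profile(
      peak_velocity = s$peak %||% 4.5, ramp_time = s$ramp %||% 0.1,
      duration = s$duration %||% 0.4)
    if (!is.null(s$modes_um)) {
      ov$dist <- droplet_size_distribution(
        modes_um = s$modes_um, sigma_g = s$sigma_g,
        weights = s$weights)
    }
    if (!is.null(s$total_count)) ov$total_count <- s$total_count
  }
  if (!is.null(cfg$ambient)) {
    a <- cfg$ambient
    ov$ambient <- ambient_conditions(
      temperature_C = a$temperature_C %||% 20, rh = a$rh %||% 0.70,
      wind_speed = a$wind_speed %||% 1.96,
      wind_direction = a$wind_direction %||% "none")
  }
  build_case(sc$case %||% 1, n = sc$n_parcels %||% 2000,
             seeds = sc$seeds %||% 101:105, t_max = sc$t_max %||% 10,
             overrides = ov)
}
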