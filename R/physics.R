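#' Physical constants and moist-air property helpers
#'
#' Ambient-air defaults follow the filtration test conditions: density
#' 1.204 kg/m^3 and dynamic viscosity 1.834e-5 kg/(m s) at 20 C.
#' @name physics
#' @keywords internal
NULL

.const <- list(
  rho_air   = 1.204,        # kg/m^3
  mu_air    = 1.834e-5,     # kg/(m s)
  rho_water = 1000,         # kg/m^3 (liquid droplet)
  cp_water  = 4186,         # J/(kg C)
  rho_nacl  = 2650,         # kg/m^3 (filtration test aerosol)
  D_vapor   = 2.42e-5,      # m^2/s, water vapour in air at 20 C
  k_air     = 0.0257,       # W/(m C)
  L_vap     = 2.45e6,       # J/kg latent heat of vaporisation
  M_ratio   = 0.622,        # Mw/Ma for water vapour in air
  P_atm     = 101325,       # Pa
  g         = 9.81,         # m/s^2
  kB        = 1.380649e-23, # J/K
  mfp_air   = 67.3e-9       # m, air mean free path at 20 C, 1 atm
)

#' Saturation vapour pressure of water
#'
#' Arden Buck equation, accurate to <0.1% over 0-50 C.
#' @param T_C temperature in degrees Celsius.
#' @return saturation pressure in Pa.
#' @export
saturation_pressure <- function(T_C) {
  611.21 * exp((18.678 - T_C / 234.5) * T_C / (257.14 + T_C))
}

#' Water-vapour mass fraction at a given partial pressure
#' @param p_v vapour partial pressure (Pa).
#' @param P total pressure (Pa).
#' @return mass fraction (kg water / kg moist air).
#' @export
vapor_mass_fraction <- function(p_v, P = .const$P_atm) {
  .const$M_ratio * p_v / (P - (1 - .const$M_ratio) * p_v)
}

#' Cunningham slip correction factor
#'
#' Standard three-parameter form; matters for sub-micron aerosol transport.
#' @param d_m particle diameter in metres.
#' @param mfp gas mean free path in metres.
#' @return dimensionless correction >= 1.
#' @export
cunningham_slip <- function(d_m, mfp = .const$mfp_air) {
  Kn <- 2 * mfp / d_m
  1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
}

#' Brownian diffusivity of an aerosol particle (Stokes-Einstein)
#' @param d_m particle diameter (m).
#' @param T_K absolute temperature (K).
#' @param mu gas viscosity (kg/(m s)).
#' @return diffusivity in m^2/s.
#' @export
brownian_diffusivity <- function(d_m, T_K = 293.15, mu = .const$mu_air) {
  .const$kB * T_K * cunningham_slip(d_m) / (3 * pi * mu * d_m)
}

# particle momentum relaxation time (Stokes regime, slip-corrected)
relaxation_time <- function(d_m, rho_p, mu = .const$mu_air, slip = TRUE) {
  cc <- if (slip) cunningham_slip(d_m) else 1
  cc * rho_p * d_m^2 / (18 * mu)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
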