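#' Physics configuration for coherent X-ray imaging
#'
#' Bundles the beam and geometry constants used throughout the forward model:
#' wavelength (derived from the beam energy unless given explicitly), the
#' classical electron radius, the specimen-to-detector propagation distance,
#' the detector pixel size and the expected photon count per pixel.
#'
#' Defaults correspond to a synchrotron-style setup: a 13 keV monochromatic
#' beam (wavelength close to 0.954 angstrom), 0.85 m free-space propagation
#' and 9 micrometre pixels.
#'
#' @param energy_kev Beam energy in keV; sets the wavelength via
#'   lambda = hc / E when `wavelength` is NULL.
#' @param wavelength X-ray wavelength in metres; overrides `energy_kev`.
#' @param propagation_distance Specimen-to-detector distance z in metres.
#' @param pixel_size Detector pixel size in metres.
#' @param photon_count Expected photons per pixel for an empty beam.
#' @param electron_radius Classical electron radius in metres.
#' @return An object of class `physics_config`.
#' @examples
#' cfg <- physics_config()
#' cfg$wavelength # ~9.54e-11 m at 13 keV
#' @export
physics_config <- function(energy_kev = 13,
                           wavelength = NULL,
                           propagation_distance = 0.85,
                           pixel_size = 9e-6,
                           photon_count = 1e4,
                           electron_radius = 2.8179403262e-15) {
  if (is.null(wavelength)) {
    stopifnot(is.numeric(energy_kev), length(energy_kev) == 1, energy_kev > 0)
    # hc = 1.23984193 eV um  =>  lambda[m] = 1.23984193e-9 / E[keV]
    wavelength <- 1.23984193e-9 / energy_kev
  }
  vals <- c(
    wavelength = wavelength, propagation_distance = propagation_distance,
    pixel_size = pixel_size, photon_count = photon_count,
    electron_radius = electron_radius
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("physics_config: all parameters must be finite and strictly positive")
  }
  structure(
    list(
      energy_kev = energy_kev,
      wavelength = wavelength,
      electron_radius = electron_radius,
      propagation_distance = propagation_distance,
      pixel_size = pixel_size,
      photon_count = photon_count
    ),
    class = "physics_config"
  )
}

#' Phase decrement delta from electron density
#'
#' The real part of the refractive index n = 1 - delta - i*beta for a
#' material of electron density rho_e is delta = rho_e * r_e * lambda^2 / (2*pi).
#'
#' @param rho_e Electron density in electrons per cubic metre (>= 0).
#' @param cfg A [physics_config()].
#' @return delta (dimensionless), same length as `rho_e`.
#' @export
delta_from_electron_density <- function(rho_e, cfg = physics_config()) {
  stopifnot(inherits(cfg, "physics_config"))
  if (any(rho_e < 0)) {
    stop("delta_from_electron_density: electron density must be non-negative")
  }
  rho_e * cfg$electron_radius * cfg$wavelength^2 / (2 * pi)
}

#' Linear attenuation coefficient from the absorption index beta
#'
#' beta relates to the linear attenuation coefficient as mu = 4*pi*beta / lambda;
#' the transmitted intensity through thickness t is I0 * exp(-mu * t).
#'
#' @param beta Imaginary refractive-index decrement (>= 0).
#' @param cfg A [physics_config()].
#' @return mu in 1/m.
#' @seealso [phase_per_length()] for the companion P = 2*pi*delta / lambda.
#' @export
mu_from_beta <- function(beta, cfg = physics_config()) {
  stopifnot(inherits(cfg, "physics_config"))
  if (any(beta < 0)) {
    stop("mu_from_beta: beta must be non-negative")
  }
  4 * pi * beta / cfg$wavelength
}

#' Phase shift per unit length from delta
#'
#' P = 2*pi*delta / lambda, the rate of phase accumulation (rad/m) of a wave
#' traversing material with phase decrement delta.
#'
#' @inheritParams mu_from_beta
#' @param delta Real refractive-index decrement (>= 0).
#' @return P in rad/m.
#' @export
phase_per_length <- function(delta, cfg = physics_config()) {
  stopifnot(inherits(cfg, "physics_config"))
  if (any(delta < 0)) {
    stop("phase_per_length: delta must be non-negative")
  }
  2 * pi * delta / cfg$wavelength
}
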