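#' @include AllClasses.R
NULL

#' Create a medium/particle configuration
#'
#' Defaults describe 200 nm diameter polystyrene spheres in water at room
#' temperature at the equilibrium concentration of the trapping experiments
#' (5e9 particles/mL, a volume fraction of about 2.1e-5). The
#' `glycerol40` preset raises the viscosity 4-fold (40 % glycerol/water).
#'
#' @param eta Dynamic viscosity, Pa s.
#' @param radius Particle radius, m.
#' @param temperature Temperature, K.
#' @param cEq Equilibrium number concentration, particles per mL.
#' @param nParticle Particle refractive index.
#' @param preset `"water"` or `"glycerol40"`.
#' @return A [MediumParticleConfig-class].
#' @examples
#' diffusionCoefficient(mediumParticleConfig())  # ~2.18e-12 m^2/s
#' @export
mediumParticleConfig <- function(eta = NULL, radius = 100e-9,
                                 temperature = 298, cEq = 5e9,
                                 nParticle = 1.59,
                                 preset = c("water", "glycerol40")) {
  preset <- match.arg(preset)
  if (is.null(eta)) eta <- switch(preset, water = 1.0e-3, glycerol40 = 4.0e-3)
  new("MediumParticleConfig", eta = eta, radius = radius,
      temperature = temperature, cEq = cEq, nParticle = nParticle)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T / (6 pi eta R)` for a sphere of radius R.
#'
#' @param cfg A [MediumParticleConfig-class].
#' @return Diffusion coefficient, m^2/s.
#' @export
diffusionCoefficient <- function(cfg) {
  stopifnot(is(cfg, "MediumParticleConfig"))
  .kB * cfg@temperature / (6 * pi * cfg@eta * cfg@radius)
}

#' Particle volume fraction of a number concentration
#'
#' @param concentration Number concentration in particles per mL.
#' @param radius Particle radius, m.
#' @return Dimensionless volume fraction `c * (4/3) pi R^3`.
#' @examples
#' volumeFraction(5e9, 100e-9)   # ~2.1e-5
#' volumeFraction(5e10, 100e-9)  # ~2e-4 (typical of the incorporation paths)
#' @export
volumeFraction <- function(concentration, radius = 100e-9) {
  stopifnot(all(concentration >= 0), all(radius >= 0))
  cPerM3 <- concentration * 1e6      # 1/mL -> 1/m^3
  cPerM3 * (4 / 3) * pi * radius^3
}

#' Stokes drag force for a velocity
#'
#' `F = 6 pi eta R v`, the force balance used to infer optical forces from
#' measured particle velocities. Only valid for an isolated sphere in the
#' dilute limit; hydrodynamic coupling between neighbouring particles is
#' neglected.
#'
#' @param v Velocity (m/s); scalar, vector or matrix (componentwise).
#' @param eta Dynamic viscosity, Pa s.
#' @param radius Particle radius, m.
#' @return Force in newtons, same shape as `v`.
#' @examples
#' stokesForce(100e-6)  # 100 um/s -> ~1.9e-13 N
#' @export
stokesForce <- function(v, eta = 1.0e-3, radius = 100e-9) {
  6 * pi * eta * radius * v
}

setMethod("show", "MediumParticleConfig", function(object) {
  cat(sprintf(paste0(
    "MediumParticleConfig: R = %.0f nm, eta = %.2g Pa s, T = %.0f K\n",
    "  c_eq = %.2g /mL (volume fraction %.2g), D = %.3g m^2/s\n"),
    object@radius * 1e9, object@eta, object@temperature, object@cEq,
    volumeFraction(object@cEq, object@radius), diffusionCoefficient(object)))
})
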