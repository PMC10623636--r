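#' @include AllClasses.R AllGenerics.R
NULL

#' Create an optical train configuration
#'
#' Defaults describe the trapping arm used throughout: a 1064 nm continuous
#' wave beam expanded to fill the 7 mm back aperture of an NA 1.20, 60x
#' water-immersion objective, circularly polarized, delivering 36 mW after
#' the objective. Reducing `beamDiameter` emulates closing the iris
#' diaphragm (presets 7.0, 4.5 and 3.0 mm); `power` presets are 36, 60, 120
#' and 240 mW.
#'
#' The incident profile is modelled as a TEM00 Gaussian whose 1/e^2
#' intensity diameter equals the beam diameter (`apodization = "gaussian"`,
#' `fillingFactor = 1`), truncated at the iris edge; an ideal flat-top beam
#' is available with `apodization = "uniform"`.
#'
#' @param wavelength Vacuum wavelength, m.
#' @param na Objective numerical aperture.
#' @param n1,n2 Refractive indices before/after the reference sphere.
#' @param focalLength Objective focal length, m.
#' @param backApertureDiameter Back aperture diameter, m.
#' @param beamDiameter Beam (iris) diameter, m.
#' @param polarization `"circular"`, `"linear_x"` or `"linear_y"`.
#' @param power Laser power after the objective, W.
#' @param apodization `"gaussian"` or `"uniform"`.
#' @param fillingFactor Gaussian 1/e^2 diameter over beam diameter.
#' @return An [OpticalTrainConfig-class].
#' @examples
#' cfg <- opticalTrainConfig()
#' thetaMax(cfg, degrees = TRUE)  # about 64 degrees
#' @export
opticalTrainConfig <- function(wavelength = 1064e-9, na = 1.20, n1 = 1.0,
                               n2 = 1.33, focalLength = 3.3e-3,
                               backApertureDiameter = 7e-3,
                               beamDiameter = 7e-3,
                               polarization = c("circular", "linear_x", "linear_y"),
                               power = 36e-3,
                               apodization = c("gaussian", "uniform"),
                               fillingFactor = 1.0) {
  new("OpticalTrainConfig", wavelength = wavelength, na = na, n1 = n1,
      n2 = n2, focalLength = focalLength,
      backApertureDiameter = backApertureDiameter, beamDiameter = beamDiameter,
      polarization = match.arg(polarization), power = power,
      apodization = match.arg(apodization), fillingFactor = fillingFactor)
}

#' Effective numerical aperture after aperture underfilling
#' @param config An [OpticalTrainConfig-class].
#' @return `na * min(1, beamDiameter / backApertureDiameter)`.
#' @export
effectiveNA <- function(config) {
  stopifnot(is(config, "OpticalTrainConfig"))
  config@na * min(1, config@beamDiameter / config@backApertureDiameter)
}

#' @describeIn thetaMax marginal-ray half-angle from the configuration
#' @export
setMethod("thetaMax", "OpticalTrainConfig", function(config, degrees = FALSE) {
  s <- effectiveNA(config) / config@n2
  if (s > 1) stop("invalid configuration: effective NA exceeds n2")
  th <- asin(s)
  if (degrees) th * 180 / pi else th
})

## Amplitude apodization of the incident beam over the aperture, as a
## function of sin(theta) (proportional to radial position at the aperture).
.apodization <- function(config, sinTheta) {
  smax <- effectiveNA(config) / config@n2
  a <- switch(config@apodization,
    uniform  = rep(1, length(sinTheta)),
    gaussian = {
      # 1/e^2 intensity radius = fillingFactor * beam radius -> amplitude
      # exp(-(rho/w0)^2) with rho/w0 = sinTheta / (fillingFactor * smax)
      exp(-(sinTheta / (config@fillingFactor * smax))^2)
    })
  a[sinTheta > smax * (1 + 1e-12)] <- 0  # hard iris edge
  a
}

#' Refract the incident beam through the objective's reference sphere
#'
#' Decomposes the incident polarization into s and p components at each
#' aperture point, applies the Fresnel transmission coefficients (unity
#' here: the trap is focused deep in an index-matched sample, no interface
#' stratification) and the aplanatic energy-conservation apodization
#' `sqrt(n1/n2) * sqrt(cos(theta))`, and rotates the p component onto the
#' converging ray direction. The resulting far field on the reference
#' sphere is what the Debye-Wolf integral propagates to the focus.
#'
#' @param config An [OpticalTrainConfig-class].
#' @param nTheta Number of Gauss-Legendre polar nodes on (0, thetaMax).
#' @param nPhi Number of uniform azimuthal nodes on [0, 2*pi).
#' @return A [FarField-class].
#' @export
refractFarfield <- function(config, nTheta = 256, nPhi = 256) {
  stopifnot(is(config, "OpticalTrainConfig"))
  thmax <- thetaMax(config)
  gl <- pracma::gaussLegendre(nTheta, 0, thmax)
  theta <- gl$x
  phi <- seq(0, 2 * pi, length.out = nPhi + 1)[-(nPhi + 1)]
  if (any(theta > pi / 2)) stop("focusing angle above 90 degrees")

  st <- sin(theta); ct <- cos(theta)
  amp <- .E0(config) * sqrt(config@n1 / config@n2) * sqrt(ct) *
    .apodization(config, st)

  # incident Jones vector(s): circular = (x + i y)/sqrt(2)
  jones <- switch(config@polarization,
    linear_x = c(1, 0),
    linear_y = c(0, 1),
    circular = c(1, 1i) / sqrt(2))

  E <- array(0i, dim = c(nTheta, nPhi, 3))
  ts <- 1; tp <- 1  # index-matched Fresnel coefficients
  for (j in seq_along(phi)) {
    cp <- cos(phi[j]); sp <- sin(phi[j])
    Es <- jones[1] * (-sp) + jones[2] * cp        # E_inc . n_phi
    Ep <- jones[1] * cp    + jones[2] * sp        # E_inc . n_rho
    # n_phi = (-sp, cp, 0); refracted p unit vector n_theta = (ct*cp, ct*sp, -st)
    E[, j, 1] <- amp * (ts * Es * (-sp) + tp * Ep * ct * cp)
    E[, j, 2] <- amp * (ts * Es * cp    + tp * Ep * ct * sp)
    E[, j, 3] <- amp * (tp * Ep * (-st))
  }
  new("FarField", theta = theta, thetaWeights = gl$w, phi = phi, E = E,
      config = config)
}

## Incident-field amplitude E0 (V/m) such that the power carried through the
## reference sphere equals config@power. For unit E0 the far-field power is
## P1 = pi * f^2 * (n1 / Z0) * Int apod(theta)^2 cos(theta) sin(theta) dtheta.
.E0 <- function(config) {
  thmax <- thetaMax(config)
  gl <- pracma::gaussLegendre(512, 0, thmax)
  A <- sum(gl$w * .apodization(config, sin(gl$x))^2 * cos(gl$x) * sin(gl$x))
  P1 <- pi * config@focalLength^2 * config@n1 / .Z0 * A
  sqrt(config@power / P1)
}

setMethod("show", "OpticalTrainConfig", function(object) {
  cat(sprintf(paste0(
    "OpticalTrainConfig: %.0f nm, NA %.2f (effective %.3f), n1 %.2f, n2 %.2f\n",
    "  beam %.1f / aperture %.1f mm, %s, %s apodization, %.0f mW\n",
    "  focusing half-angle %.1f deg\n"),
    object@wavelength * 1e9, object@na, effectiveNA(object), object@n1,
    object@n2, object@beamDiameter * 1e3, object@backApertureDiameter * 1e3,
    object@polarization, object@apodization, object@power * 1e3,
    thetaMax(object, degrees = TRUE)))
})
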