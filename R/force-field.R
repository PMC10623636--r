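#' @include AllClasses.R AllGenerics.R focal-field.R
NULL

## Azimuthally averaged |E|^2 and axial Poynting flux from the stored radial
## integrals. The phi average of the total intensity is identical for the
## three supported polarizations.
.esqRZ <- function(field) {
  Mod(field@I0[, , 1])^2 + Mod(field@I0[, , 3])^2 + Mod(field@I0[, , 2])^2 / 2
}
.szRZ <- function(field) {
  Z <- .Z0 / field@config@n2
  (Mod(field@I0[, , 1])^2 - Mod(field@I0[, , 3])^2) / (2 * Z)
}

#' Dipole (Rayleigh) optical force field of a focused beam
#'
#' Computes the optical force on a small dielectric sphere in the dipole
#' approximation. The gradient force is `(1/4) Re(alpha) grad|E|^2` with the
#' Clausius-Mossotti polarizability
#' `alpha = 4 pi eps0 n_m^2 R^3 (m^2 - 1)/(m^2 + 2)`, `m = n_p/n_m`; it pulls
#' the particle towards intensity maxima. The scattering force is radiation
#' pressure along the propagation direction,
#' `F = (n_m / c) sigma_s S_z` with `sigma_s = (8 pi / 3) k^4 a^2`,
#' `a = R^3 (m^2-1)/(m^2+2)`, and `S_z` the local axial Poynting flux.
#'
#' The force is tabulated on the axisymmetric (r, z) grid of the input field
#' (exact for circular polarization, whose time-averaged intensity carries
#' no azimuthal structure) and evaluated at arbitrary positions by bilinear
#' interpolation via [forceAt()].
#'
#' @param field A [FocalField-class], power-normalized.
#' @param radius Particle radius, m. A warning is issued outside
#'   (0, lambda/2], where the dipole approximation degrades.
#' @param nParticle Particle refractive index (1.59 for polystyrene).
#' @param nMedium Medium refractive index (defaults to the field's n2).
#' @return A [ForceField-class].
#' @export
rayleighForceField <- function(field, radius = 100e-9, nParticle = 1.59,
                               nMedium = NULL) {
  stopifnot(is(field, "FocalField"))
  cfg <- field@config
  if (is.null(nMedium)) nMedium <- cfg@n2
  if (radius <= 0 || radius > cfg@wavelength / 2)
    warning("particle radius outside (0, lambda/2]: dipole approximation degrades")

  m2 <- (nParticle / nMedium)^2
  aVol <- radius^3 * (m2 - 1) / (m2 + 2)                 # m^3
  alphaRe <- 4 * pi * .eps0 * nMedium^2 * aVol           # SI polarizability
  k <- 2 * pi * nMedium / cfg@wavelength
  sigmaS <- (8 * pi / 3) * k^4 * aVol^2                  # m^2

  esq <- .esqRZ(field)                                   # (V/m)^2, [nr, nz]
  sz <- .szRZ(field)                                     # W/m^2

  dr <- field@r * .um; dz <- field@z * .um
  gr <- .gradAxis(esq, dr, 1)
  gz <- .gradAxis(esq, dz, 2)
  if (abs(field@r[1]) < 1e-12) gr[1, ] <- 0              # symmetry on the axis

  new("ForceField", r = field@r, z = field@z,
      Fr = 0.25 * alphaRe * gr,
      FzGrad = 0.25 * alphaRe * gz,
      FzScat = pmax(nMedium / .c0 * sigmaS * sz, 0),
      particleRadius = radius, nParticle = nParticle, nMedium = nMedium,
      power = cfg@power)
}

## central finite differences along one margin of a matrix
.gradAxis <- function(M, coord, margin) {
  n <- dim(M)[margin]
  if (n < 3) stop("grid too small for finite differences")
  G <- M * 0
  idx <- function(i) if (margin == 1) M[i, , drop = FALSE] else M[, i, drop = FALSE]
  set <- function(i, v) if (margin == 1) G[i, ] <<- v else G[, i] <<- v
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    set(i, (idx(hi) - idx(lo)) / (coord[hi] - coord[lo]))
  }
  G
}

#' Rescale a force field to a different laser power
#'
#' Dipole forces are linear in the intensity, hence in the delivered power;
#' this avoids recomputing the diffraction integral across a power sweep.
#'
#' @param field A [ForceField-class].
#' @param power New laser power, W.
#' @return A [ForceField-class] at the new power.
#' @export
scaleForceField <- function(field, power) {
  stopifnot(is(field, "ForceField"), power > 0)
  s <- power / field@power
  initialize(field, Fr = field@Fr * s, FzGrad = field@FzGrad * s,
             FzScat = field@FzScat * s, power = power)
}

#' @describeIn forceAt bilinear interpolation on the (r, z) grid
#' @export
setMethod("forceAt", "ForceField", function(field, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  x <- positions[, 1] / .um; y <- positions[, 2] / .um
  zz <- positions[, 3] / .um
  rr <- sqrt(x^2 + y^2)
  Fr <- .bilin(field@Fr, field@r, field@z, rr, zz)
  Fz <- .bilin(field@FzGrad + field@FzScat, field@r, field@z, rr, zz)
  out <- matrix(0, nrow(positions), 3)
  nz <- rr > 1e-12
  out[nz, 1] <- Fr[nz] * x[nz] / rr[nz]
  out[nz, 2] <- Fr[nz] * y[nz] / rr[nz]
  out[, 3] <- Fz
  out
})

## vectorized bilinear interpolation; zero outside the tabulated grid
.bilin <- function(M, gx, gy, px, py) {
  out <- numeric(length(px))
  ok <- px >= gx[1] & px <= gx[length(gx)] & py >= gy[1] & py <= gy[length(gy)]
  if (!any(ok)) return(out)
  ix <- pmin(pmax(findInterval(px[ok], gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(py[ok], gy), 1L), length(gy) - 1L)
  tx <- (px[ok] - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (py[ok] - gy[iy]) / (gy[iy + 1] - gy[iy])
  v <- (1 - tx) * (1 - ty) * M[cbind(ix, iy)] +
       tx * (1 - ty)       * M[cbind(ix + 1, iy)] +
       (1 - tx) * ty       * M[cbind(ix, iy + 1)] +
       tx * ty             * M[cbind(ix + 1, iy + 1)]
  out[ok] <- v
  out
}

setMethod("show", "ForceField", function(object) {
  Ftot <- sqrt(object@Fr^2 + (object@FzGrad + object@FzScat)^2)
  cat(sprintf(paste0(
    "ForceField: %d r x %d z grid, R = %.0f nm (n %.2f in n %.2f), %.0f mW\n",
    "  peak |F| = %.3g N (gradient peak %.3g N, scattering peak %.3g N)\n"),
    length(object@r), length(object@z), object@particleRadius * 1e9,
    object@nParticle, object@nMedium, object@power * 1e3,
    max(Ftot), max(abs(object@Fr), abs(object@FzGrad)), max(object@FzScat)))
})
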