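#' @include AllClasses.R AllGenerics.R optical-train.R
NULL

## Radial diffraction integrals of the Debye-Wolf representation.
##
## For the three standard polarizations the azimuthal integral reduces to
## Bessel functions, leaving three one-dimensional integrals over the
## focusing angle (Gauss-Legendre nodes):
##   I00 = Int amp(th) sin(th) (1+cos th)/2 J0(k r sin th) e^{i k z cos th} dth
##   I01 = Int amp(th) sin(th)^2          J1(k r sin th) e^{i k z cos th} dth
##   I02 = Int amp(th) sin(th) (1-cos th)/2 J2(k r sin th) e^{i k z cos th} dth
## where amp includes the incident amplitude, sqrt(n1/n2) sqrt(cos th) and
## the aperture apodization. The returned integrals carry the full Debye
## prefactor i k f e^{-i k f}, so fields assembled from them are in V/m.
.focalIntegrals <- function(config, r, z, nTheta = 512) {
  thmax <- thetaMax(config)
  gl <- pracma::gaussLegendre(nTheta, 0, thmax)
  th <- gl$x; w <- gl$w
  st <- sin(th); ct <- cos(th)
  amp <- .E0(config) * sqrt(config@n1 / config@n2) * sqrt(ct) *
    .apodization(config, st)

  kum <- 2 * pi * config@n2 / (config@wavelength * 1e6)   # 1/um
  ksi <- 2 * pi * config@n2 / config@wavelength           # 1/m
  C <- 1i * ksi * config@focalLength * exp(-1i * ksi * config@focalLength)

  x <- outer(r, st, function(rr, ss) kum * rr * ss)       # [nr, ntheta]
  bj <- function(nu) matrix(besselJ(as.vector(x), nu), nrow = length(r))
  J0 <- bj(0); J1 <- bj(1); J2 <- bj(2)
  w0 <- w * amp * st * (1 + ct) / 2
  w1 <- w * amp * st^2
  w2 <- w * amp * st * (1 - ct) / 2

  nr <- length(r); nz <- length(z)
  I0 <- array(0i, dim = c(nr, nz, 3))
  for (j in seq_len(nz)) {
    ph <- exp(1i * kum * z[j] * ct)
    I0[, j, 1] <- C * (J0 %*% (w0 * ph))
    I0[, j, 2] <- C * (J1 %*% (w1 * ph))
    I0[, j, 3] <- C * (J2 %*% (w2 * ph))
  }
  I0
}

## Assemble the three Cartesian field components from the radial integrals
## for the configured polarization. I0: [nr, nz, 3]; phi scalar.
.assembleE <- function(I0, phi, polarization) {
  I00 <- I0[, , 1, drop = FALSE]; I01 <- I0[, , 2, drop = FALSE]
  I02 <- I0[, , 3, drop = FALSE]
  xpol <- function(p) list(
    Ex = I00 + I02 * cos(2 * p),
    Ey = I02 * sin(2 * p),
    Ez = -1i * I01 * cos(p))
  ypol <- function(p) list(
    Ex = I02 * sin(2 * p),
    Ey = I00 - I02 * cos(2 * p),
    Ez = -1i * I01 * sin(p))
  switch(polarization,
    linear_x = xpol(phi),
    linear_y = ypol(phi),
    circular = {
      a <- xpol(phi); b <- ypol(phi)
      list(Ex = (a$Ex + 1i * b$Ex) / sqrt(2),
           Ey = (a$Ey + 1i * b$Ey) / sqrt(2),
           Ez = (a$Ez + 1i * b$Ez) / sqrt(2))
    })
}

#' Compute the tightly focused vector field near the trap
#'
#' Evaluates the Debye-Wolf diffraction integral of the refracted far field
#' on a cylindrical grid around the focus. The azimuthal integral is reduced
#' to Bessel functions for the three supported polarizations
#' (`method = "bessel"`, fast and spectrally accurate); direct
#' two-dimensional quadrature over the aperture (`method = "quadrature"`)
#' evaluates the same integral from a sampled [FarField-class] and is
#' retained as an independent cross-check.
#'
#' The field is normalized so the power transported through the reference
#' sphere (and hence through the focal region) equals `config@power`.
#'
#' @param config An [OpticalTrainConfig-class].
#' @param r Radial grid, um (must be non-negative, strictly increasing).
#' @param z Axial grid, um (focus at 0; imaged volume at negative z).
#' @param phi Azimuthal grid, radians.
#' @param nTheta Gauss-Legendre nodes over the focusing angle.
#' @param nPhi Azimuthal nodes (quadrature method only).
#' @param method `"bessel"` or `"quadrature"`.
#' @return A [FocalField-class].
#' @examples
#' cfg <- opticalTrainConfig()
#' ff <- computeFocalField(cfg, r = seq(0, 2, by = 0.05),
#'                         z = seq(-1, 1, by = 0.1), nTheta = 128)
#' @export
computeFocalField <- function(config, r, z, phi = 0, nTheta = 512,
                              nPhi = 256, method = c("bessel", "quadrature")) {
  stopifnot(is(config, "OpticalTrainConfig"), all(r >= 0))
  method <- match.arg(method)
  lamUm <- config@wavelength * 1e6
  if (length(r) > 1) {
    dr <- max(diff(r))
    if (dr > lamUm / (8 * effectiveNA(config)))
      warning(sprintf(
        "lateral grid spacing %.3f um exceeds lambda/(8 NA_eff) = %.3f um",
        dr, lamUm / (8 * effectiveNA(config))))
  }
  I0 <- .focalIntegrals(config, r, z, nTheta)
  nr <- length(r); nz <- length(z); np <- length(phi)
  E <- array(0i, dim = c(nr, np, nz, 3))
  if (method == "bessel") {
    for (j in seq_len(np)) {
      cmp <- .assembleE(I0, phi[j], config@polarization)
      E[, j, , 1] <- cmp$Ex; E[, j, , 2] <- cmp$Ey; E[, j, , 3] <- cmp$Ez
    }
  } else {
    far <- refractFarfield(config, nTheta = nTheta, nPhi = nPhi)
    E <- .quadratureFocalField(far, r, phi, z)
  }
  new("FocalField", r = r, phi = phi, z = z, E = E, I0 = I0, config = config)
}

## Direct 2D quadrature of the Debye-Wolf integral from a FarField:
## E(r,phi,z) = (i k f e^{-ikf} / 2 pi) Int Int E_inf e^{i k z cos th}
##              e^{i k r sin th cos(vphi - phi)} sin th dth dvphi
.quadratureFocalField <- function(far, r, phi, z) {
  cfg <- far@config
  th <- far@theta; w <- far@thetaWeights; vphi <- far@phi
  st <- sin(th); ct <- cos(th)
  dphi <- 2 * pi / length(vphi)
  kum <- 2 * pi * cfg@n2 / (cfg@wavelength * 1e6)
  ksi <- 2 * pi * cfg@n2 / cfg@wavelength
  C <- 1i * ksi * cfg@focalLength * exp(-1i * ksi * cfg@focalLength) / (2 * pi)

  E <- array(0i, dim = c(length(r), length(phi), length(z), 3))
  wst <- w * st * dphi
  for (iz in seq_along(z)) {
    axial <- exp(1i * kum * z[iz] * ct)       # [ntheta]
    for (ip in seq_along(phi)) {
      # lateral phase for all (theta, vphi) at each r
      cosdv <- cos(outer(vphi, phi[ip], "-"))[, 1]     # [nphi]
      for (ir in seq_along(r)) {
        lat <- exp(1i * kum * r[ir] * outer(st, cosdv))  # [ntheta, nphi]
        core <- lat * (wst * axial)
        for (cc in 1:3)
          E[ir, ip, iz, cc] <- C * sum(far@E[, , cc] * core)
      }
    }
  }
  E
}

#' @describeIn intensityMap total electric energy density |E|^2 on the grid
#' @export
setMethod("intensityMap", "FocalField", function(field, perPlane = FALSE) {
  I <- apply(Mod(field@E)^2, c(1, 2, 3), sum)
  if (perPlane) {
    for (j in seq_along(field@z)) {
      m <- max(I[, , j])
      if (m > 0) I[, , j] <- I[, , j] / m
    }
  }
  I
})

#' On-axis intensity profile of the focused beam
#'
#' Evaluates |E|^2 on the optical axis directly from the axial diffraction
#' integral (only the J0 term survives at r = 0), which is much cheaper than
#' computing a full field when only the axial structure is needed.
#'
#' @param config An [OpticalTrainConfig-class].
#' @param z Axial positions, um.
#' @param nTheta Gauss-Legendre nodes.
#' @return data.frame with columns `z` and `intensity` (|E|^2, (V/m)^2).
#' @export
onAxisIntensity <- function(config, z = seq(-4.5, 1, by = 0.025),
                            nTheta = 512) {
  I0 <- .focalIntegrals(config, 0, z, nTheta)
  data.frame(z = z, intensity = Mod(I0[1, , 1])^2)
}

.localMaxima <- function(y) {
  d <- diff(y)
  which(diff(sign(d)) < 0) + 1L
}

#' @describeIn axialMaxima from a focused field sampled at r = 0
#' @export
setMethod("axialMaxima", "FocalField", function(x, minRelIntensity = 0.05) {
  i0 <- which.min(abs(x@r))
  if (x@r[i0] > 1e-9)
    stop("radial grid must include r = 0 for an on-axis profile")
  I <- apply(Mod(x@E[i0, , , , drop = FALSE])^2, 3, sum)
  axialMaxima(data.frame(z = x@z, intensity = I), minRelIntensity)
})

#' @describeIn axialMaxima from a tabulated on-axis profile
#' @export
setMethod("axialMaxima", "data.frame", function(x, minRelIntensity = 0.05) {
  stopifnot(all(c("z", "intensity") %in% names(x)))
  x <- x[order(x$z), ]
  if (max(diff(x$z)) > 0.0501)
    warning("axial sampling coarser than 50 nm; maxima positions are approximate")
  idx <- .localMaxima(x$intensity)
  # endpoints can be maxima of a monotone profile; treat interior only but
  # fall back to the global max if nothing interior exists
  if (!length(idx)) idx <- which.max(x$intensity)
  rel <- x$intensity[idx] / max(x$intensity)
  keep <- rel >= minRelIntensity
  if (!any(keep)) stop("degenerate profile: no local maxima found")
  out <- data.frame(z = x$z[idx][keep], relIntensity = rel[keep])
  out[order(out$z), , drop = FALSE]
})

#' @describeIn contourHalfAngle radially averaged intensity of a focused field
#' @export
setMethod("contourHalfAngle", "FocalField",
  function(x, level = 0.2, zRange = c(-4, -1), ...) {
  I <- intensityMap(x)
  Irz <- apply(I, c(1, 3), mean)     # average over phi
  contourHalfAngle(Irz, level = level, zRange = zRange, r = x@r, z = x@z)
})

#' @describeIn contourHalfAngle from an intensity matrix on an (r, z) grid
#' @export
setMethod("contourHalfAngle", "matrix",
  function(x, level = 0.2, zRange = c(-4, -1), r, z, ...) {
  stopifnot(nrow(x) == length(r), ncol(x) == length(z),
            level > 0, level < 1)
  sel <- which(z >= zRange[1] & z <= zRange[2])
  if (length(sel) < 2) stop("fewer than two planes inside zRange")
  rl <- rep(NA_real_, length(sel))
  for (j in seq_along(sel)) {
    v <- x[, sel[j]]
    m <- max(v)
    if (m <= 0) next
    v <- v / m
    idx <- which(v >= level)
    if (!length(idx)) next
    i2 <- max(idx)
    if (i2 == length(r)) next   # contour not closed within the grid
    # linear interpolation of the outermost downward crossing
    rl[j] <- r[i2] + (r[i2 + 1] - r[i2]) * (v[i2] - level) / (v[i2] - v[i2 + 1])
  }
  ok <- is.finite(rl)
  if (sum(ok) < 2)
    stop("contour level never crossed in the selected planes")
  if (any(!ok))
    warning(sprintf("%d plane(s) excluded: level not crossed", sum(!ok)))
  depth <- abs(z[sel][ok])
  fit <- stats::lm(rl[ok] ~ depth)
  ang <- atan(unname(stats::coef(fit)[2])) * 180 / pi
  list(angle = ang,
       radii = data.frame(z = z[sel][ok], radius = rl[ok]),
       fit = fit)
})

#' Optical power transported across transverse planes
#'
#' Integrates the axial Poynting flux over each z plane of a focused field.
#' For the supported polarizations the azimuthally averaged axial Poynting
#' component reduces to (|I00|^2 - |I02|^2) / (2 Z) with Z the medium wave
#' impedance, so the flux follows directly from the stored radial integrals.
#' With no absorption modelled, the flux must be independent of z and equal
#' to the configured laser power (checked by the package tests).
#'
#' @param field A [FocalField-class]. Its radial grid should extend to where
#'   the beam intensity is negligible at the evaluated planes, otherwise the
#'   reported power underestimates the total.
#' @return data.frame with columns `z` (um) and `power` (W).
#' @export
powerFlux <- function(field) {
  stopifnot(is(field, "FocalField"))
  Z <- .Z0 / field@config@n2
  rm <- field@r * .um
  p <- vapply(seq_along(field@z), function(j) {
    sz <- (Mod(field@I0[, j, 1])^2 - Mod(field@I0[, j, 3])^2) / (2 * Z)
    2 * pi * pracma::trapz(rm, sz * rm)
  }, numeric(1))
  data.frame(z = field@z, power = p)
}

setMethod("show", "FocalField", function(object) {
  cat(sprintf(paste0(
    "FocalField: %d r x %d phi x %d z samples (r <= %.2f um, z in [%.2f, %.2f] um)\n",
    "  polarization %s, %.0f mW, peak |E|^2 = %.3g (V/m)^2\n"),
    length(object@r), length(object@phi), length(object@z), max(object@r),
    min(object@z), max(object@z), object@config@polarization,
    object@config@power * 1e3, max(apply(Mod(object@E)^2, 1:3, sum))))
})
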