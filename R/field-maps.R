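#' @include AllClasses.R AllGenerics.R trajectory-set.R medium.R
NULL

.binMids <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

#' Bin trajectories into concentration maps
#'
#' Occupancy counts per voxel divided by (number of frames x voxel volume)
#' give the time-averaged number concentration in particles/um^3, both on a
#' Cartesian grid and radially averaged about the beam axis. The beam axis
#' is estimated as the occupancy-weighted centroid of the detections near
#' the focal plane (|z| < 0.5 um) unless given explicitly.
#'
#' @param traj A [TrajectorySet-class].
#' @param xBreaks,yBreaks,zBreaks Voxel edges, um. Defaults: 0.25 um lateral
#'   and 0.58 um axial bins (one imaging plane per axial bin) over the
#'   imaged volume.
#' @param rBreaks Radial bin edges, um.
#' @param axis Optional `c(x, y)` of the beam axis, um.
#' @return A [FieldMaps-class] with concentration slots filled.
#' @export
binConcentration <- function(traj,
                             xBreaks = seq(-5, 5, by = 0.25),
                             yBreaks = seq(-5, 5, by = 0.25),
                             zBreaks = seq(-4.06, 0, by = 0.58),
                             rBreaks = seq(0, 5, by = 0.25),
                             axis = NULL) {
  stopifnot(is(traj, "TrajectorySet"))
  tr <- traj@tracks
  if (!nrow(tr)) {
    warning("empty trajectory set: returning empty maps")
    tr <- tr[0, ]
  }
  nFrames <- max(1L, length(unique(tr$frame)))

  if (is.null(axis)) {
    nearFocus <- tr[abs(tr$z_um) < 0.5, , drop = FALSE]
    axis <- if (nrow(nearFocus) >= 10)
      c(mean(nearFocus$x_um), mean(nearFocus$y_um)) else c(0, 0)
  }

  ix <- findInterval(tr$x_um, xBreaks, rightmost.closed = TRUE)
  iy <- findInterval(tr$y_um, yBreaks, rightmost.closed = TRUE)
  iz <- findInterval(tr$z_um, zBreaks, rightmost.closed = TRUE)
  nx <- length(xBreaks) - 1L; ny <- length(yBreaks) - 1L
  nz <- length(zBreaks) - 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
  counts3d <- array(0, dim = c(nx, ny, nz))
  if (any(ok)) {
    tb <- table(factor(ix[ok], levels = 1:nx), factor(iy[ok], levels = 1:ny),
                factor(iz[ok], levels = 1:nz))
    counts3d[] <- as.numeric(tb)
  }
  voxVol <- diff(xBreaks)[1] * diff(yBreaks)[1] * diff(zBreaks)[1]
  c3d <- counts3d / (nFrames * voxVol)

  rr <- sqrt((tr$x_um - axis[1])^2 + (tr$y_um - axis[2])^2)
  ir <- findInterval(rr, rBreaks, rightmost.closed = TRUE)
  nr <- length(rBreaks) - 1L
  okr <- ir >= 1 & ir <= nr & iz >= 1 & iz <= nz
  countsrz <- matrix(0, nr, nz)
  if (any(okr)) {
    tb <- table(factor(ir[okr], levels = 1:nr), factor(iz[okr], levels = 1:nz))
    countsrz[] <- as.numeric(tb)
  }
  annulusVol <- pi * (rBreaks[-1]^2 - rBreaks[-length(rBreaks)]^2) *
    diff(zBreaks)[1]
  crz <- countsrz / (nFrames * annulusVol)

  new("FieldMaps", xMid = .binMids(xBreaks), yMid = .binMids(yBreaks),
      zMid = .binMids(zBreaks), rMid = .binMids(rBreaks), axis = axis,
      c3d = c3d, crz = crz, counts3d = counts3d, countsrz = countsrz,
      nFrames = nFrames, dt = traj@dt)
}

#' Reconstruct the velocity field from trajectory steps
#'
#' Single-frame forward differences: each per-particle displacement divided
#' by the frame interval is assigned to the (r, z) bin of the step
#' mid-point; per-bin means give the radial and axial velocity components
#' about the beam axis. Bins with fewer than `nMin` steps are masked (NA)
#' to suppress Brownian-noise artifacts. Bins whose mean displacement per
#' frame exceeds the bin size are flagged `underSampled`: there the speed
#' is likely underestimated.
#'
#' @param maps A [FieldMaps-class] from [binConcentration()] (provides the
#'   grid and beam axis).
#' @param traj The [TrajectorySet-class] to difference.
#' @param nMin Minimum steps per bin.
#' @return The input [FieldMaps-class] with velocity slots filled.
#' @export
velocityField <- function(maps, traj, nMin = 10) {
  stopifnot(is(maps, "FieldMaps"), is(traj, "TrajectorySet"))
  tr <- traj@tracks[order(traj@tracks$particle_id, traj@tracks$frame), ]
  n <- nrow(tr)
  if (n < 2) stop("need at least two detections")
  same <- tr$particle_id[-1] == tr$particle_id[-n] &
          tr$frame[-1] == tr$frame[-n] + 1L
  dt <- traj@dt
  i0 <- which(same); i1 <- i0 + 1L
  vx <- (tr$x_um[i1] - tr$x_um[i0]) / dt
  vy <- (tr$y_um[i1] - tr$y_um[i0]) / dt
  vz <- (tr$z_um[i1] - tr$z_um[i0]) / dt
  mx <- (tr$x_um[i1] + tr$x_um[i0]) / 2 - maps@axis[1]
  my <- (tr$y_um[i1] + tr$y_um[i0]) / 2 - maps@axis[2]
  mz <- (tr$z_um[i1] + tr$z_um[i0]) / 2
  rr <- sqrt(mx^2 + my^2)
  # radial unit vector at the mid-point
  ur <- cbind(mx / pmax(rr, 1e-12), my / pmax(rr, 1e-12))
  vr <- vx * ur[, 1] + vy * ur[, 2]
  vp <- -vx * ur[, 2] + vy * ur[, 1]

  rEdges <- c(maps@rMid - diff(maps@rMid)[1] / 2,
              maps@rMid[length(maps@rMid)] + diff(maps@rMid)[1] / 2)
  zEdges <- c(maps@zMid - diff(maps@zMid)[1] / 2,
              maps@zMid[length(maps@zMid)] + diff(maps@zMid)[1] / 2)
  ir <- findInterval(rr, rEdges, rightmost.closed = TRUE)
  iz <- findInterval(mz, zEdges, rightmost.closed = TRUE)
  nr <- length(maps@rMid); nz <- length(maps@zMid)
  ok <- ir >= 1 & ir <= nr & iz >= 1 & iz <= nz
  idx <- cbind(ir[ok], iz[ok])

  acc <- function(v) {
    M <- matrix(0, nr, nz)
    t <- tapply(v[ok], list(factor(idx[, 1], 1:nr), factor(idx[, 2], 1:nz)),
                sum)
    t[is.na(t)] <- 0
    M[] <- t
    M
  }
  cnt <- acc(rep(1, length(vr)))
  vrM <- acc(vr) / pmax(cnt, 1)
  vzM <- acc(vz) / pmax(cnt, 1)
  vpM <- acc(vp) / pmax(cnt, 1)
  spM <- acc(sqrt(vx^2 + vy^2 + vz^2)) / pmax(cnt, 1)
  mask <- cnt < nMin
  vrM[mask] <- NA; vzM[mask] <- NA; vpM[mask] <- NA; spM[mask] <- NA
  binSize <- min(diff(rEdges)[1], diff(zEdges)[1])
  under <- !mask & spM * dt > binSize
  under[is.na(under)] <- FALSE

  initialize(maps, vr = vrM, vz = vzM, vphi = vpM, vCounts = cnt,
             speed = spM, underSampled = under)
}

#' Stokes force and Peclet maps from a velocity field
#'
#' Applies the drag-balance `F = 6 pi eta R v` to the magnitude of the
#' per-bin mean velocity vector (using the vector mean rather than the mean
#' speed avoids the upward Brownian bias of |v|) and forms the Peclet
#' number `Pe = v R / D = F R / (kB T)` per bin.
#'
#' @param maps A [FieldMaps-class] with velocity slots filled.
#' @param medium A [MediumParticleConfig-class].
#' @return The input maps with `force` and `peclet` slots filled.
#' @export
forceMaps <- function(maps, medium) {
  stopifnot(is(maps, "FieldMaps"), length(maps@vr) > 0)
  vms <- sqrt(maps@vr^2 + maps@vphi^2 + maps@vz^2) * .um   # m/s
  FF <- stokesForce(vms, medium@eta, medium@radius)
  initialize(maps, force = FF,
             peclet = pecletNumber(v = vms, medium = medium))
}

#' Peclet number of optically driven transport
#'
#' Ratio of directed to diffusive transport over one particle radius,
#' computable from the velocity (`Pe = v R / D`) or from the force
#' (`Pe = F R / kB T`). The two routes are algebraically identical through
#' the Stokes drag and Stokes-Einstein relations, which also makes Pe
#' independent of the solvent viscosity at fixed force.
#'
#' @param v Speed, m/s (used if given).
#' @param force Force, N (used when `v` is missing).
#' @param medium A [MediumParticleConfig-class].
#' @return Peclet number, same shape as the input.
#' @export
pecletNumber <- function(v = NULL, force = NULL,
                         medium = mediumParticleConfig()) {
  R <- medium@radius
  if (!is.null(v)) {
    D <- diffusionCoefficient(medium)
    v * R / D
  } else if (!is.null(force)) {
    force * R / (.kB * medium@temperature)
  } else stop("give v or force")
}

#' Boltzmann trap free energy from concentration enhancement
#'
#' `U_trap = -ln(c / c_eq)` in units of kB T: the effective free energy a
#' steady-state concentration field implies under Boltzmann statistics.
#' Negative values mean attraction. Bins with zero concentration are
#' masked (NA).
#'
#' @param c Concentration (any array shape), same units as `cEq`.
#' @param cEq Equilibrium concentration.
#' @return Trap energy in kB T, same shape as `c`.
#' @examples
#' trapEnergy(10, 1)   # -2.3 kB T
#' trapEnergy(50, 1)   # -3.9 kB T
#' @export
trapEnergy <- function(c, cEq) {
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be non-negative")
  stopifnot(cEq > 0)
  u <- -log(c / cEq)
  u[c == 0] <- NA
  u
}

#' Add the trap-energy map to field maps
#' @param maps A [FieldMaps-class] with `crz` filled.
#' @param medium A [MediumParticleConfig-class] (supplies `cEq`).
#' @return Maps with `uTrap` filled (kB T units).
#' @export
trapEnergyMap <- function(maps, medium) {
  cEqUm3 <- medium@cEq * 1e-12        # per mL -> per um^3
  initialize(maps, uTrap = trapEnergy(maps@crz, cEqUm3))
}

#' Particle flux maps
#'
#' `j = c v` per bin: the local particle flux in particles/(um^2 s),
#' decomposed into radial and axial components plus the magnitude.
#'
#' @param maps A [FieldMaps-class] with concentration and velocity filled.
#' @return Maps with `jr`, `jz`, `jmag` filled.
#' @export
fluxMap <- function(maps) {
  stopifnot(length(maps@vr) > 0, length(maps@crz) > 0)
  jr <- maps@crz * maps@vr
  jz <- maps@crz * maps@vz
  initialize(maps, jr = jr, jz = jz, jmag = sqrt(jr^2 + jz^2))
}

#' @describeIn getMap named map accessor
#' @export
setMethod("getMap", "FieldMaps", function(object, name) {
  ok <- c("c3d", "crz", "counts3d", "countsrz", "vr", "vz", "vphi", "speed",
          "force", "peclet", "uTrap", "jr", "jz", "jmag", "vCounts",
          "underSampled")
  if (!name %in% ok)
    stop("unknown map '", name, "'; available: ", paste(ok, collapse = ", "))
  slot(object, name)
})

#' @export
setMethod("show", "FieldMaps", function(object) {
  filled <- Filter(function(s) length(slot(object, s)) > 0,
                   c("c3d", "crz", "vr", "vz", "force", "peclet", "uTrap",
                     "jr", "jz"))
  cat(sprintf(paste0(
    "FieldMaps: %d x %d x %d voxels, %d radial x %d axial bins, %d frames\n",
    "  beam axis at (%.2f, %.2f) um; filled maps: %s\n"),
    length(object@xMid), length(object@yMid), length(object@zMid),
    length(object@rMid), length(object@zMid), object@nFrames,
    object@axis[1], object@axis[2], paste(filled, collapse = ", ")))
})
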