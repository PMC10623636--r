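#' @include AllClasses.R AllGenerics.R medium.R force-field.R
NULL

#' Create Langevin simulation settings
#'
#' Defaults mirror the imaging experiments: 50 us integration steps with a
#' frame recorded every 100 steps (5 ms, i.e. 200 frames/s) in a
#' 50 x 50 x 120 um column of suspension with the trap near the top and the
#' imaged volume in the 4 um below it.
#'
#' @param dt Integration time step, s.
#' @param nSteps Number of steps.
#' @param nParticles Particle count; `NA` draws it from `cEq * volume`.
#' @param box `c(xmin, xmax, ymin, ymax, zmin, zmax)`, um, focus at origin.
#' @param seed RNG seed.
#' @param hydrodynamics Apply pairwise Oseen coupling.
#' @param outputStride Steps between recorded frames.
#' @param trapRadius Capture radius at the focus, m.
#' @return A [SimulationRun-class].
#' @export
simulationRun <- function(dt = 50e-6, nSteps = 2000, nParticles = NA,
                          box = c(-25, 25, -25, 25, -100, 20), seed = 1,
                          hydrodynamics = FALSE, outputStride = 100,
                          trapRadius = 150e-9) {
  new("SimulationRun", dt = dt, nSteps = nSteps, nParticles = nParticles,
      box = box, seed = seed, hydrodynamics = hydrodynamics,
      outputStride = outputStride, trapRadius = trapRadius)
}

#' One Euler-Maruyama step of overdamped Langevin dynamics
#'
#' `x <- x + (F / (6 pi eta R)) dt + xi`, with `xi` isotropic Gaussian of
#' per-axis variance `2 D dt`. The deterministic displacement is checked
#' against the particle radius: a drift of more than 5 R per step means the
#' time step is too large for the force field.
#'
#' @param positions N x 3 matrix, metres.
#' @param forces N x 3 matrix, newtons.
#' @param medium A [MediumParticleConfig-class].
#' @param dt Time step, s.
#' @param D Diffusion coefficient override (m^2/s); defaults to the
#'   Stokes-Einstein value, `D = 0` gives deterministic drift.
#' @return Updated N x 3 position matrix.
#' @export
langevinStep <- function(positions, forces, medium, dt, D = NULL) {
  if (is.null(D)) D <- diffusionCoefficient(medium)
  gamma <- 6 * pi * medium@eta * medium@radius
  drift <- forces / gamma * dt
  maxDrift <- sqrt(max(rowSums(drift^2)))
  if (maxDrift > 5 * medium@radius)
    stop(sprintf("time step too large: drift %.3g m exceeds 5 R = %.3g m",
                 maxDrift, 5 * medium@radius))
  noise <- if (D > 0)
    matrix(stats::rnorm(length(positions), sd = sqrt(2 * D * dt)),
           ncol = 3) else 0
  positions + drift + noise
}

#' Oseen hydrodynamic velocity perturbations
#'
#' The flow at particle i induced by the forces driving all other particles,
#' `sum_j T(r_ij) F_j` with the Oseen tensor
#' `T(r) = (1 / (8 pi eta r)) (I + r_hat r_hat)`. Pairs closer than the
#' regularization distance (particle contact, 2 R) use the contact value to
#' avoid the 1/r divergence; coincident pairs are excluded with a warning.
#'
#' @param positions N x 3 matrix, metres.
#' @param forces N x 3 matrix, newtons.
#' @param eta Dynamic viscosity, Pa s.
#' @param minDist Regularization distance, m.
#' @return N x 3 matrix of velocity perturbations, m/s.
#' @export
oseenCoupling <- function(positions, forces, eta, minDist = 2e-7) {
  n <- nrow(positions)
  if (n < 2) return(matrix(0, n, 3))
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  dz <- outer(positions[, 3], positions[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- Inf
  zero <- r2 < 1e-30
  if (any(zero)) {
    warning("coincident particle pair(s) excluded from Oseen coupling")
    r2[zero] <- Inf
  }
  r <- sqrt(r2)
  rc <- pmax(r, minDist)              # contact-regularized distance
  # dot_ij = (r_ij . F_j) / r_ij^2 ; forces broadcast along columns
  Fx <- matrix(forces[, 1], n, n, byrow = TRUE)
  Fy <- matrix(forces[, 2], n, n, byrow = TRUE)
  Fz <- matrix(forces[, 3], n, n, byrow = TRUE)
  dot <- (dx * Fx + dy * Fy + dz * Fz) / r2
  pre <- 1 / (8 * pi * eta * rc)
  pre[!is.finite(pre)] <- 0
  cbind(rowSums(pre * (Fx + dot * dx)),
        rowSums(pre * (Fy + dot * dy)),
        rowSums(pre * (Fz + dot * dz)))
}

#' Simulate optically driven Brownian nanoparticles
#'
#' Overdamped Langevin dynamics (Euler-Maruyama) of an ensemble of spheres
#' in an optical force field, with reflecting box walls and optional
#' pairwise Oseen coupling. Particles entering the capture radius around the
#' focus are flagged trapped and held there (they continue to exert
#' hydrodynamic forces on the others when coupling is on). Runs are
#' reproducible: identical seeds give bit-identical trajectories.
#'
#' @param force A [ForceField-class], a function mapping an N x 3 position
#'   matrix (metres) to an N x 3 force matrix (newtons), or `NULL` for free
#'   diffusion.
#' @param medium A [MediumParticleConfig-class].
#' @param run A [SimulationRun-class].
#' @param positions Optional N x 3 matrix of initial positions (um);
#'   defaults to uniform in the box.
#' @return A [TrajectorySet-class] (positions in um, times in s).
#' @export
simulateDynamics <- function(force = NULL, medium = mediumParticleConfig(),
                             run = simulationRun(), positions = NULL) {
  stopifnot(is(medium, "MediumParticleConfig"), is(run, "SimulationRun"))
  D <- diffusionCoefficient(medium)
  if (run@dt > medium@radius^2 / (50 * D))
    stop(sprintf("dt = %.2g s exceeds R^2/(50 D) = %.2g s", run@dt,
                 medium@radius^2 / (50 * D)))
  set.seed(run@seed)

  box <- run@box
  vol <- prod(box[c(2, 4, 6)] - box[c(1, 3, 5)])          # um^3
  nP <- if (is.na(run@nParticles))
    max(1L, round(medium@cEq * 1e-12 * vol)) else as.integer(run@nParticles)

  if (is.null(positions)) {
    positions <- cbind(stats::runif(nP, box[1], box[2]),
                       stats::runif(nP, box[3], box[4]),
                       stats::runif(nP, box[5], box[6]))
  } else {
    positions <- as.matrix(positions)
    nP <- nrow(positions)
  }
  pos <- positions * .um                                  # metres
  lo <- box[c(1, 3, 5)] * .um; hi <- box[c(2, 4, 6)] * .um

  forceFun <- if (is.null(force)) {
    function(p) matrix(0, nrow(p), 3)
  } else if (is(force, "ForceField")) {
    function(p) forceAt(force, p)
  } else force

  gamma <- 6 * pi * medium@eta * medium@radius
  trapped <- rep(FALSE, nP)
  nRec <- 1L + run@nSteps %/% run@outputStride
  rec <- array(NA_real_, dim = c(nRec, nP, 3))
  recTrap <- matrix(FALSE, nRec, nP)
  rec[1, , ] <- pos; recTrap[1, ] <- trapped

  iRec <- 1L
  for (s in seq_len(run@nSteps)) {
    Fm <- forceFun(pos)
    # held (trapped) particles sit at force equilibrium: no net force on
    # the fluid, so they drop out of the hydrodynamic coupling
    Fm[trapped, ] <- 0
    vel <- Fm / gamma
    if (run@hydrodynamics)
      vel <- vel + oseenCoupling(pos, Fm, medium@eta,
                                 minDist = 2 * medium@radius)
    noise <- matrix(stats::rnorm(3 * nP, sd = sqrt(2 * D * run@dt)), ncol = 3)
    step <- vel * run@dt + noise
    step[trapped, ] <- 0
    pos <- pos + step
    # reflecting walls
    for (ax in 1:3) {
      under <- pos[, ax] < lo[ax]; over <- pos[, ax] > hi[ax]
      pos[under, ax] <- 2 * lo[ax] - pos[under, ax]
      pos[over, ax] <- 2 * hi[ax] - pos[over, ax]
    }
    trapped <- trapped | sqrt(rowSums(pos^2)) < run@trapRadius
    if (s %% run@outputStride == 0) {
      iRec <- iRec + 1L
      rec[iRec, , ] <- pos
      recTrap[iRec, ] <- trapped
    }
  }

  dtFrame <- run@dt * run@outputStride
  tr <- data.frame(
    particle_id = rep(seq_len(nP), each = nRec),
    frame = rep(seq_len(nRec), nP),
    t_s = rep((seq_len(nRec) - 1) * dtFrame, nP),
    x_um = as.vector(rec[, , 1]) / .um,
    y_um = as.vector(rec[, , 2]) / .um,
    z_um = as.vector(rec[, , 3]) / .um,
    trapped = as.vector(recTrap))
  new("TrajectorySet", tracks = tr, dt = dtFrame, box = box,
      metadata = list(seed = run@seed, dtStep = run@dt, nSteps = run@nSteps,
                      hydrodynamics = run@hydrodynamics,
                      medium = medium, trapRadius = run@trapRadius))
}

#' Sample positions from a Boltzmann distribution
#'
#' Metropolis sampling of `density ~ exp(-U / kB T)` inside a box, used to
#' generate equilibrium ensembles and to validate the trap-energy
#' reconstruction. `n` independent walkers start uniformly and are swept
#' `nSweeps` times; the first half is discarded as burn-in.
#'
#' @param U Function mapping an N x 3 position matrix (um) to energies (J).
#' @param medium A [MediumParticleConfig-class] (provides kB T).
#' @param n Number of samples.
#' @param box `c(xmin, xmax, ymin, ymax, zmin, zmax)`, um.
#' @param seed RNG seed.
#' @param nSweeps Metropolis sweeps.
#' @param stepSize Proposal standard deviation, um; defaults to 5 % of the
#'   largest box edge.
#' @return N x 3 matrix of positions (um), with the acceptance rate in
#'   attribute `"acceptance"`.
#' @export
equilibriumSampler <- function(U, medium = mediumParticleConfig(), n = 1000,
                               box = c(-5, 5, -5, 5, -5, 5), seed = 1,
                               nSweeps = 300, stepSize = NULL) {
  set.seed(seed)
  kT <- .kB * medium@temperature
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  if (is.null(stepSize)) stepSize <- 0.05 * max(hi - lo)
  pos <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  u <- U(pos)
  if (any(!is.finite(u))) stop("U must be bounded below on the box")
  acc <- 0
  for (s in seq_len(nSweeps)) {
    prop <- pos + matrix(stats::rnorm(3 * n, sd = stepSize), ncol = 3)
    inside <- prop[, 1] >= lo[1] & prop[, 1] <= hi[1] &
              prop[, 2] >= lo[2] & prop[, 2] <= hi[2] &
              prop[, 3] >= lo[3] & prop[, 3] <= hi[3]
    uProp <- U(prop)
    a <- inside & stats::runif(n) < exp(-(uProp - u) / kT)
    pos[a, ] <- prop[a, ]
    u[a] <- uProp[a]
    acc <- acc + mean(a)
  }
  acc <- acc / nSweeps
  if (acc < 1e-3)
    stop(sprintf("Metropolis mixing failure: acceptance %.2g < 1e-3", acc))
  attr(pos, "acceptance") <- acc
  pos
}
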