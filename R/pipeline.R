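#' @include AllClasses.R focal-field.R force-field.R dynamics.R camera.R
#' @include localize.R field-maps.R traj-analysis.R
NULL

#' Default end-to-end pipeline configuration
#'
#' A nested configuration for [runPipeline()], scaled so a full run takes
#' seconds to minutes: the field is tabulated on a coarse (r, z) grid, the
#' simulation uses a reduced box around the trapping cone, and imaging is
#' rendered on a small field of view. All components can be replaced with
#' full-scale counterparts.
#'
#' @param optics An [OpticalTrainConfig-class].
#' @param medium A [MediumParticleConfig-class].
#' @param run A [SimulationRun-class].
#' @param camera A [CameraOpticsConfig-class].
#' @param tracking Render and track synthetic stacks (`TRUE`) or analyse
#'   the simulator's ground-truth trajectories directly (`FALSE`).
#' @param fieldR,fieldZ Grids (um) for the tabulated force field.
#' @param contourZRange Depth window for the contour half-angle.
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(optics = opticalTrainConfig(),
                           medium = mediumParticleConfig(),
                           run = simulationRun(
                             nSteps = 4000, nParticles = 150,
                             box = c(-8, 8, -8, 8, -10, 2)),
                           camera = cameraOpticsConfig(frameSize = c(160, 160)),
                           tracking = FALSE,
                           fieldR = seq(0, 6, by = 0.05),
                           fieldZ = seq(-6, 2, by = 0.1),
                           contourZRange = c(-4, -1)) {
  list(optics = optics, medium = medium, run = run, camera = camera,
       tracking = tracking, fieldR = fieldR, fieldZ = fieldZ,
       contourZRange = contourZRange)
}

#' Run the full simulation/analysis pipeline
#'
#' Executes the five stages end-to-end: focal-field calculation, force
#' field, Langevin dynamics, (optional) rendering + tracking, and field /
#' trajectory analysis. A manifest with the configuration hash, stage
#' seeds and output checksums is written alongside the outputs, making
#' reruns with identical configuration and seed bit-reproducible.
#'
#' @param config A [pipelineConfig()] list.
#' @param outDir Output directory (created if missing).
#' @param seed Global seed; per-stage seeds are derived as
#'   `seed * 100 + stage`.
#' @return Invisible list with `field`, `force`, `traj`, `maps`, `summary`,
#'   `dwells` and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("trapflow"),
                        seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(i) as.integer(seed * 100 + i)
  res <- list()

  withStage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    out
  }

  res$field <- withStage("simulate-field",
    computeFocalField(config$optics, r = config$fieldR, z = config$fieldZ))
  ax <- withStage("simulate-field",
    axialMaxima(onAxisIntensity(config$optics)))
  contour <- withStage("simulate-field",
    contourHalfAngle(res$field, zRange = config$contourZRange))
  res$force <- withStage("simulate-field",
    rayleighForceField(res$field, radius = config$medium@radius,
                       nParticle = config$medium@nParticle))

  run <- config$run
  run@seed <- stage(2)
  res$traj <- withStage("simulate-particles",
    simulateDynamics(res$force, config$medium, run))

  if (isTRUE(config$tracking)) {
    res$traj <- withStage("render-track", {
      set.seed(stage(3))
      tr <- res$traj@tracks
      dets <- do.call(rbind, lapply(sort(unique(tr$frame)), function(f) {
        p <- tr[tr$frame == f, c("x_um", "y_um", "z_um")]
        st <- renderFrame(as.matrix(p), config$camera, frame = f)
        localizeFrame(st, config$camera)
      }))
      linkTrajectories(dets,
                       maxDisp = linkingGate(config$medium, res$traj@dt),
                       dt = res$traj@dt)
    })
  }

  res$maps <- withStage("analyze", {
    m <- binConcentration(res$traj)
    m <- velocityField(m, res$traj)
    m <- forceMaps(m, config$medium)
    m <- trapEnergyMap(m, config$medium)
    fluxMap(m)
  })
  res$dwells <- withStage("traj-analyze",
    detectMetastableDwell(res$traj, config$medium))

  secondary <- ax[ax$relIntensity < 0.999 & ax$z < -0.5, , drop = FALSE]
  res$summary <- data.frame(
    quantity = c("secondary_focus_depth_um", "contour_half_angle_deg",
                 "u_trap_min_kbt", "peak_speed_um_s", "peak_force_N",
                 "n_trapped", "n_dwell_events"),
    value = c(if (nrow(secondary)) -secondary$z[which.max(secondary$relIntensity)]
              else NA_real_,
              contour$angle,
              suppressWarnings(min(res$maps@uTrap, na.rm = TRUE)),
              suppressWarnings(max(res$maps@speed, na.rm = TRUE)),
              suppressWarnings(max(res$maps@force, na.rm = TRUE)),
              sum(res$traj@tracks$trapped[res$traj@tracks$frame ==
                                            max(res$traj@tracks$frame)]),
              nrow(res$dwells)))

  trajPath <- file.path(outDir, "trajectories.csv")
  writeTrajectories(res$traj, trajPath)
  sumPath <- file.path(outDir, "summary.csv")
  utils::write.csv(res$summary, sumPath, row.names = FALSE)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(.configDigestible(config, seed), cfgPath,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = seed,
    stageSeeds = c(field = stage(1), particles = stage(2), imaging = stage(3)),
    configHash = unname(tools::md5sum(cfgPath)),
    files = as.list(tools::md5sum(c(trajPath, sumPath))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

## flatten S4 configs into plain lists for hashing/serialization
.configDigestible <- function(config, seed) {
  flat <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    sl <- lapply(slotNames(class(x)), function(s) slot(x, s))
    names(sl) <- slotNames(class(x))
    lapply(sl, function(v) if (isS4(v)) flat(v) else v)
  }
  c(lapply(config, flat), list(globalSeed = seed))
}

#' Deterministic miniature datasets for testing and demonstration
#'
#' @param kind One of `"cone-trajectories"` (trajectories descending along
#'   a 30 degree cone), `"helix"` (one helicoidal incorporation
#'   trajectory, x leading y by 90 degrees), `"boltzmann-box"` (positions
#'   sampled with a 10-fold concentration enhancement inside a subregion),
#'   `"bead-zstack"` (a calibration bead scan with 580 nm plane spacing
#'   ground truth) or `"crossing-pair"` (two trajectories passing close to
#'   each other).
#' @param seed RNG seed.
#' @return Kind-dependent: a [TrajectorySet-class], a positions matrix, or
#'   a list with stack data.
#' @export
generateFixtures <- function(kind, seed = 1) {
  kinds <- c("cone-trajectories", "helix", "boltzmann-box", "bead-zstack",
             "crossing-pair")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; valid kinds: ",
         paste(kinds, collapse = ", "))
  set.seed(seed)
  dt <- 0.005
  switch(kind,
    "cone-trajectories" = {
      n <- 40
      rows <- lapply(seq_len(n), function(id) {
        nf <- 60
        z <- seq(-4, -0.2, length.out = nf)
        phi0 <- stats::runif(1, 0, 2 * pi)
        r <- abs(z) * tan(30 * pi / 180)
        data.frame(particle_id = id, frame = seq_len(nf),
                   t_s = (seq_len(nf) - 1) * dt,
                   x_um = r * cos(phi0) + stats::rnorm(nf, sd = 0.02),
                   y_um = r * sin(phi0) + stats::rnorm(nf, sd = 0.02),
                   z_um = z + stats::rnorm(nf, sd = 0.02), trapped = FALSE)
      })
      trajectorySet(do.call(rbind, rows), dt = dt)
    },
    "helix" = {
      nf <- 200
      t <- (seq_len(nf) - 1) * dt
      A <- 0.15; period <- 0.1
      w <- 2 * pi / period
      data0 <- data.frame(
        particle_id = 1, frame = seq_len(nf), t_s = t,
        x_um = 1.5 - 0.8 * t + A * cos(w * t),
        y_um = 1.5 - 0.8 * t + A * sin(w * t),
        z_um = -3.5 + 0.9 * t, trapped = FALSE)
      trajectorySet(data0, dt = dt)
    },
    "boltzmann-box" = {
      kT <- .kB * 298
      U <- function(p) ifelse(abs(p[, 1]) < 2, -kT * log(10), 0)
      equilibriumSampler(U, mediumParticleConfig(), n = 4000,
                         box = c(-5, 5, -5, 5, -5, 5), seed = seed)
    },
    "bead-zstack" = {
      cfg <- cameraOpticsConfig(frameSize = c(64, 64), background = 2)
      beads <- cbind(stats::runif(6, -2.4, 2.4), stats::runif(6, -2.4, 2.4))
      stageZ <- seq(-4.8, 0.8, by = 0.1)
      stacks <- array(0, dim = c(64, 64, cfg@nPlanes, length(stageZ)))
      for (s in seq_along(stageZ)) {
        pos <- cbind(beads, stageZ[s])
        stacks[, , , s] <- renderFrame(pos, cfg, noise = TRUE)@images
      }
      list(stacks = stacks, stageZ = stageZ, truth = planePositions(cfg),
           cfg = cfg)
    },
    "crossing-pair" = {
      nf <- 40
      t <- (seq_len(nf) - 1) * dt
      sep <- 0.2    # closest approach, um
      mk <- function(id, dir) {
        x <- dir * (2 - 20 * t)            # crosses x = 0 mid-record
        data.frame(particle_id = id, frame = seq_len(nf), t_s = t,
                   x_um = x + stats::rnorm(nf, sd = 0.02),
                   y_um = (id - 1.5) * sep + stats::rnorm(nf, sd = 0.02),
                   z_um = -2 + stats::rnorm(nf, sd = 0.02), trapped = FALSE)
      }
      trajectorySet(rbind(mk(1, 1), mk(2, -1)), dt = dt)
    })
}
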