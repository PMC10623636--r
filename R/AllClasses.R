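#' @import methods
NULL

#' Optical train configuration
#'
#' Describes the trapping beam and focusing optics: an expanded laser beam,
#' optionally truncated by an iris diaphragm, entering the back aperture of a
#' high-NA water-immersion objective. The effective numerical aperture is
#' `na * min(1, beamDiameter / backApertureDiameter)`, so underfilling the
#' aperture lowers the focusing angle.
#'
#' @slot wavelength Vacuum wavelength of the trapping laser in metres.
#' @slot na Numerical aperture of the objective.
#' @slot n1 Refractive index on the incident side of the reference sphere.
#' @slot n2 Refractive index of the immersion/sample medium.
#' @slot focalLength Objective focal length in metres.
#' @slot backApertureDiameter Diameter of the objective back aperture, metres.
#' @slot beamDiameter Beam (iris) diameter at the back aperture, metres.
#' @slot polarization One of `"linear_x"`, `"linear_y"`, `"circular"`.
#' @slot power Laser power after the objective, watts.
#' @slot apodization `"gaussian"` (TEM00 beam whose 1/e^2 intensity diameter
#'   equals `fillingFactor * beamDiameter`, truncated at the iris edge) or
#'   `"uniform"` (ideal flat-top beam truncated at the iris edge).
#' @slot fillingFactor Ratio of the Gaussian 1/e^2 beam diameter to
#'   `beamDiameter`; ignored for uniform apodization.
#' @exportClass OpticalTrainConfig
setClass("OpticalTrainConfig",
  representation(
    wavelength = "numeric", na = "numeric", n1 = "numeric", n2 = "numeric",
    focalLength = "numeric", backApertureDiameter = "numeric",
    beamDiameter = "numeric", polarization = "character", power = "numeric",
    apodization = "character", fillingFactor = "numeric"))

setValidity("OpticalTrainConfig", function(object) {
  msg <- character()
  pos <- c(wavelength = object@wavelength, na = object@na, n1 = object@n1,
           n2 = object@n2, focalLength = object@focalLength,
           backAperture = object@backApertureDiameter,
           beamDiameter = object@beamDiameter, power = object@power)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all optical parameters must be finite and positive")
  if (object@beamDiameter > object@backApertureDiameter + 1e-12)
    msg <- c(msg, "beamDiameter must not exceed backApertureDiameter")
  naEff <- object@na * min(1, object@beamDiameter / object@backApertureDiameter)
  if (naEff / object@n2 > 1)
    msg <- c(msg, "effective NA exceeds n2: focusing angle undefined")
  if (!object@polarization %in% c("linear_x", "linear_y", "circular"))
    msg <- c(msg, "polarization must be linear_x, linear_y or circular")
  if (!object@apodization %in% c("gaussian", "uniform"))
    msg <- c(msg, "apodization must be gaussian or uniform")
  if (length(msg)) msg else TRUE
})

#' Far field on the Gaussian reference sphere
#'
#' Samples of the refracted far field after the objective's reference sphere,
#' on a (theta, phi) product grid. `E` holds the three Cartesian components;
#' theta nodes and weights come from Gauss-Legendre quadrature so the field
#' can be integrated directly to the focus.
#'
#' @slot theta Polar-angle nodes (radians), in (0, thetaMax].
#' @slot thetaWeights Gauss-Legendre weights for the theta nodes.
#' @slot phi Azimuthal nodes (radians), uniform on [0, 2*pi).
#' @slot E Complex array `[ntheta, nphi, 3]` of Ex, Ey, Ez (V/m).
#' @slot config The generating [OpticalTrainConfig-class].
#' @exportClass FarField
setClass("FarField",
  representation(theta = "numeric", thetaWeights = "numeric", phi = "numeric",
                 E = "array", config = "OpticalTrainConfig"))

setValidity("FarField", function(object) {
  d <- dim(object@E)
  if (length(d) != 3 || d[3] != 3)
    return("E must be an [ntheta, nphi, 3] array")
  if (d[1] != length(object@theta) || d[2] != length(object@phi))
    return("E dimensions must match theta/phi grids")
  if (any(!is.finite(Mod(object@E)))) return("far field contains non-finite values")
  TRUE
})

#' Focused vector field near the trap
#'
#' The complex electric field of the tightly focused beam on a cylindrical
#' grid (r, phi, z) centred on the focus. The beam propagates towards +z; the
#' imaged sample volume lies below the focus at negative z. The field is
#' scaled so the power transported through the focal region equals the
#' configured laser power.
#'
#' @slot r Radial grid in micrometres.
#' @slot phi Azimuthal grid in radians.
#' @slot z Axial grid in micrometres (focus at z = 0).
#' @slot E Complex array `[nr, nphi, nz, 3]` of Ex, Ey, Ez in V/m.
#' @slot I0 Complex array `[nr, nz, 3]` of the three radial diffraction
#'   integrals the field was assembled from (kept for flux computations).
#' @slot config The generating [OpticalTrainConfig-class].
#' @exportClass FocalField
setClass("FocalField",
  representation(r = "numeric", phi = "numeric", z = "numeric",
                 E = "array", I0 = "array", config = "OpticalTrainConfig"))

setValidity("FocalField", function(object) {
  d <- dim(object@E)
  if (length(d) != 4 || d[4] != 3) return("E must be [nr, nphi, nz, 3]")
  if (d[1] != length(object@r) || d[2] != length(object@phi) ||
      d[3] != length(object@z)) return("E dimensions must match r/phi/z grids")
  if (any(!is.finite(Mod(object@E)))) return("focal field contains non-finite values")
  if (any(diff(object@r) <= 0) || any(diff(object@z) <= 0))
    return("r and z grids must be strictly increasing")
  TRUE
})

#' Optical force field acting on a Rayleigh particle
#'
#' Dipole-approximation optical force derived from a focused field, split
#' into a (curl-free) gradient part and a scattering part directed along the
#' beam propagation (+z). Stored on an axisymmetric (r, z) grid; valid as a
#' 3D field for circularly polarized illumination, whose time-averaged
#' intensity is azimuthally invariant.
#'
#' @slot r Radial grid, micrometres.
#' @slot z Axial grid, micrometres.
#' @slot Fr Radial gradient-force component (N), matrix `[nr, nz]`;
#'   negative values point towards the axis.
#' @slot FzGrad Axial gradient-force component (N), matrix `[nr, nz]`.
#' @slot FzScat Axial scattering-force component (N), matrix `[nr, nz]`,
#'   non-negative.
#' @slot particleRadius Particle radius in metres.
#' @slot nParticle,nMedium Refractive indices of particle and medium.
#' @slot power Laser power (W) the field was normalized to.
#' @exportClass ForceField
setClass("ForceField",
  representation(r = "numeric", z = "numeric", Fr = "matrix",
                 FzGrad = "matrix", FzScat = "matrix",
                 particleRadius = "numeric", nParticle = "numeric",
                 nMedium = "numeric", power = "numeric"))

setValidity("ForceField", function(object) {
  dm <- c(length(object@r), length(object@z))
  for (s in c("Fr", "FzGrad", "FzScat"))
    if (!identical(dim(slot(object, s)), as.integer(dm)))
      return(sprintf("%s must be a [nr, nz] matrix", s))
  if (any(object@FzScat < -1e-30)) return("scattering force must point along +z")
  TRUE
})

#' Medium and particle properties
#'
#' @slot eta Dynamic viscosity of the medium, Pa s.
#' @slot radius Particle radius, metres.
#' @slot temperature Absolute temperature, kelvin.
#' @slot cEq Equilibrium number concentration, particles per mL.
#' @slot nParticle Particle refractive index.
#' @exportClass MediumParticleConfig
setClass("MediumParticleConfig",
  representation(eta = "numeric", radius = "numeric", temperature = "numeric",
                 cEq = "numeric", nParticle = "numeric"))

setValidity("MediumParticleConfig", function(object) {
  v <- c(object@eta, object@radius, object@temperature, object@cEq)
  if (any(!is.finite(v)) || any(v <= 0))
    return("eta, radius, temperature and cEq must be positive")
  TRUE
})

#' Langevin simulation settings
#'
#' @slot dt Integration time step, seconds.
#' @slot nSteps Number of integration steps.
#' @slot nParticles Number of particles (`NA` derives it from `cEq * volume`).
#' @slot box Simulation box `c(xmin, xmax, ymin, ymax, zmin, zmax)` in
#'   micrometres, focus at the origin.
#' @slot seed RNG seed.
#' @slot hydrodynamics Whether pairwise Oseen coupling is applied.
#' @slot outputStride Steps between recorded frames.
#' @slot trapRadius Capture radius around the focus (metres): particles
#'   closer than this are flagged trapped and held.
#' @exportClass SimulationRun
setClass("SimulationRun",
  representation(dt = "numeric", nSteps = "numeric", nParticles = "numeric",
                 box = "numeric", seed = "numeric", hydrodynamics = "logical",
                 outputStride = "numeric", trapRadius = "numeric"))

setValidity("SimulationRun", function(object) {
  if (length(object@box) != 6) return("box must have 6 entries")
  if (any(object@box[c(2, 4, 6)] <= object@box[c(1, 3, 5)]))
    return("box upper bounds must exceed lower bounds")
  if (object@dt <= 0 || object@nSteps < 1) return("dt and nSteps must be positive")
  if (object@outputStride < 1 || object@outputStride > object@nSteps)
    return("outputStride must be in [1, nSteps]")
  TRUE
})

#' Per-particle trajectories
#'
#' Time series of 3D positions, one row per particle per recorded frame.
#' Positions are in micrometres with the focus at the origin and the imaged
#' volume below it (negative z); times in seconds.
#'
#' @slot tracks data.frame with columns `particle_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `z_um`, `trapped`.
#' @slot dt Frame interval in seconds.
#' @slot box Simulation/imaging bounds (um), or `NA`.
#' @slot metadata Free-form list (seeds, configs, provenance).
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(tracks = "data.frame", dt = "numeric", box = "numeric",
                 metadata = "list"))

setValidity("TrajectorySet", function(object) {
  need <- c("particle_id", "frame", "t_s", "x_um", "y_um", "z_um", "trapped")
  if (!all(need %in% names(object@tracks)))
    return(paste("tracks must have columns:", paste(need, collapse = ", ")))
  tr <- object@tracks
  if (nrow(tr)) {
    o <- order(tr$particle_id, tr$t_s)
    tt <- tr$t_s[o]; id <- tr$particle_id[o]
    same <- id[-1] == id[-length(id)]
    if (any(diff(tt)[same] <= 0))
      return("t_s must be strictly increasing within each particle")
  }
  TRUE
})

#' Camera and detection-path configuration
#'
#' Geometry and noise model of the multiplane widefield detection: the
#' fluorescence is split into `nPlanes` simultaneously recorded images whose
#' focal planes are staggered by `planeSpacing`. Plane 1 is conjugate to the
#' trapping focus (z = 0) and deeper planes look below it.
#'
#' @slot nPlanes Number of simultaneously acquired planes.
#' @slot planeSpacing Axial distance between consecutive planes, micrometres.
#' @slot frameRate Acquisition rate, frames per second.
#' @slot pixelSize Pixel size in sample space, micrometres.
#' @slot frameSize `c(nx, ny)` pixels.
#' @slot psfSigma0 Lateral PSF standard deviation in focus, micrometres.
#' @slot psfZR Defocus range parameter: sigma(z) = psfSigma0 *
#'   sqrt(1 + (z/psfZR)^2), micrometres.
#' @slot photonBudget Detected photons per particle per frame (all planes).
#' @slot background Mean background, photons per pixel per plane.
#' @slot readNoise Gaussian read noise (rms electrons) added per pixel.
#' @exportClass CameraOpticsConfig
setClass("CameraOpticsConfig",
  representation(nPlanes = "numeric", planeSpacing = "numeric",
                 frameRate = "numeric", pixelSize = "numeric",
                 frameSize = "numeric", psfSigma0 = "numeric",
                 psfZR = "numeric", photonBudget = "numeric",
                 background = "numeric", readNoise = "numeric"))

setValidity("CameraOpticsConfig", function(object) {
  if (length(object@frameSize) != 2) return("frameSize must be c(nx, ny)")
  v <- c(object@nPlanes, object@planeSpacing, object@frameRate,
         object@pixelSize, object@frameSize, object@psfSigma0, object@psfZR,
         object@photonBudget)
  if (any(!is.finite(v)) || any(v <= 0))
    return("camera parameters must be positive")
  TRUE
})

#' One frame of simultaneous multiplane images
#'
#' @slot images Array `[ny, nx, nPlanes]` of photon counts.
#' @slot planeZ Axial positions of the planes, micrometres.
#' @slot frame Frame index.
#' @slot pixelSize Pixel size, micrometres.
#' @exportClass PlaneStack
setClass("PlaneStack",
  representation(images = "array", planeZ = "numeric", frame = "numeric",
                 pixelSize = "numeric"))

setValidity("PlaneStack", function(object) {
  d <- dim(object@images)
  if (length(d) != 3 || d[3] != length(object@planeZ))
    return("images must be [ny, nx, nPlanes] matching planeZ")
  if (any(object@images < 0)) return("pixel values must be non-negative")
  TRUE
})

#' Binned field maps reconstructed from trajectories
#'
#' Voxel-averaged concentration, velocity, force, Peclet, trap-energy and
#' flux maps, both on a Cartesian 3D grid and as radial averages about the
#' beam axis. Slots not yet computed hold zero-length arrays.
#'
#' @slot xMid,yMid,zMid,rMid Bin mid-points, micrometres.
#' @slot axis Estimated (x, y) of the beam axis, micrometres.
#' @slot c3d Concentration, particles/um^3, array `[nx, ny, nz]`.
#' @slot crz Radially averaged concentration, matrix `[nr, nz]`.
#' @slot counts3d,countsrz Occupancy counts behind the concentration maps.
#' @slot vr,vz,vphi Mean radial/axial/azimuthal velocity per (r, z) bin,
#'   um/s (vector means: Brownian displacements average out).
#' @slot vCounts Number of displacement steps per (r, z) bin.
#' @slot speed Mean 3D speed per (r, z) bin, um/s.
#' @slot force Stokes-inferred force magnitude per (r, z) bin, N.
#' @slot peclet Peclet number per (r, z) bin.
#' @slot uTrap Boltzmann trap energy per (r, z) bin, units of kB T.
#' @slot jr,jz,jmag Particle flux components/magnitude, particles/(um^2 s).
#' @slot underSampled Logical matrix flagging bins whose mean displacement
#'   per frame exceeds the bin size (velocity likely underestimated).
#' @slot nFrames Number of frames binned.
#' @slot dt Frame interval, seconds.
#' @exportClass FieldMaps
setClass("FieldMaps",
  representation(xMid = "numeric", yMid = "numeric", zMid = "numeric",
                 rMid = "numeric", axis = "numeric",
                 c3d = "array", crz = "matrix",
                 counts3d = "array", countsrz = "matrix",
                 vr = "matrix", vz = "matrix", vphi = "matrix",
                 vCounts = "matrix",
                 speed = "matrix", force = "matrix", peclet = "matrix",
                 uTrap = "matrix", jr = "matrix", jz = "matrix",
                 jmag = "matrix", underSampled = "matrix",
                 nFrames = "numeric", dt = "numeric"),
  prototype(vr = matrix(0, 0, 0), vz = matrix(0, 0, 0),
            vphi = matrix(0, 0, 0),
            vCounts = matrix(0, 0, 0), speed = matrix(0, 0, 0),
            force = matrix(0, 0, 0), peclet = matrix(0, 0, 0),
            uTrap = matrix(0, 0, 0), jr = matrix(0, 0, 0),
            jz = matrix(0, 0, 0), jmag = matrix(0, 0, 0),
            underSampled = matrix(FALSE, 0, 0)))

#' Helicoidal-residual report for one trajectory
#'
#' @slot residuals data.frame with columns `t_s`, `dx_um`, `dy_um` (tracked
#'   minus smoothed positions).
#' @slot period Dominant oscillation period, seconds.
#' @slot phaseDeg Phase of the x residual relative to the y residual at the
#'   dominant frequency, degrees in (-180, 180].
#' @slot handedness `"anticlockwise"`, `"clockwise"` or `"undetermined"`.
#' @slot amplitudeRatio Fitted oscillation amplitude over the residual
#'   (Brownian) noise level.
#' @slot lowConfidence TRUE when fewer than two full periods are observed.
#' @exportClass HelixReport
setClass("HelixReport",
  representation(residuals = "data.frame", period = "numeric",
                 phaseDeg = "numeric", handedness = "character",
                 amplitudeRatio = "numeric", lowConfidence = "logical"))

setValidity("HelixReport", function(object) {
  if (length(object@phaseDeg) == 1 && is.finite(object@phaseDeg) &&
      (object@phaseDeg <= -180 || object@phaseDeg > 180))
    return("phaseDeg must lie in (-180, 180]")
  if (!object@handedness %in% c("anticlockwise", "clockwise", "undetermined"))
    return("invalid handedness")
  TRUE
})
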