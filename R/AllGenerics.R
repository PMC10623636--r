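#' @include AllClasses.R
NULL

#' Maximum focusing half-angle of the optical train
#'
#' @param config An [OpticalTrainConfig-class].
#' @param degrees Return degrees instead of radians.
#' @return The marginal-ray half-angle `asin(naEff / n2)` where
#'   `naEff = na * min(1, beamDiameter / backApertureDiameter)`.
#' @export
setGeneric("thetaMax", function(config, degrees = FALSE) standardGeneric("thetaMax"))

#' Scalar intensity of a focused field
#'
#' @param field A [FocalField-class].
#' @param perPlane Normalize each z plane to its own maximum.
#' @return Array `[nr, nphi, nz]` of |Ex|^2 + |Ey|^2 + |Ez|^2 (arbitrary
#'   units proportional to W/m^2), optionally per-plane normalized.
#' @export
setGeneric("intensityMap", function(field, perPlane = FALSE) standardGeneric("intensityMap"))

#' Local maxima of the on-axis intensity profile
#'
#' @param x A [FocalField-class] whose radial grid includes r = 0, or a
#'   data.frame with columns `z` and `intensity`.
#' @param minRelIntensity Local maxima below this fraction of the principal
#'   maximum are discarded (suppresses quadrature ripple).
#' @return data.frame with columns `z` (um) and `relIntensity`, sorted by z;
#'   the principal focus is the global maximum.
#' @export
setGeneric("axialMaxima", function(x, minRelIntensity = 0.05) standardGeneric("axialMaxima"))

#' Half-angle of the intensity contour cone below the focus
#'
#' For each z plane the intensity is normalized to its own maximum and the
#' outermost radius at which it crosses `level` is located; a least-squares
#' line through these (radius, depth) points gives the half-angle of the
#' incorporation cone with respect to the optical axis.
#'
#' @param x A [FocalField-class], or a `[nr, nz]` intensity matrix.
#' @param level Contour level as a fraction of the per-plane maximum.
#' @param zRange `c(zmin, zmax)` in um selecting planes below the focus.
#' @param ... For the matrix method: `r` and `z` grids (um).
#' @return List with `angle` (degrees), `radii` (data.frame of per-plane
#'   contour radii) and `fit` (the lm object).
#' @export
setGeneric("contourHalfAngle",
  function(x, level = 0.2, zRange = c(-4, -1), ...) standardGeneric("contourHalfAngle"))

#' Trajectory table of a TrajectorySet
#'
#' @param object A [TrajectorySet-class].
#' @return The tracks data.frame.
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' Images of a PlaneStack
#' @param object A [PlaneStack-class].
#' @return Array `[ny, nx, nPlanes]`.
#' @export
setGeneric("planeImages", function(object) standardGeneric("planeImages"))

#' Plane depths of a PlaneStack
#' @param object A [PlaneStack-class].
#' @return Numeric vector of plane z positions (um).
#' @export
setGeneric("planeDepths", function(object) standardGeneric("planeDepths"))

#' Retrieve one map from a FieldMaps object
#'
#' @param object A [FieldMaps-class].
#' @param name One of `"c3d"`, `"crz"`, `"vr"`, `"vz"`, `"speed"`,
#'   `"force"`, `"peclet"`, `"uTrap"`, `"jr"`, `"jz"`, `"jmag"`.
#' @return The requested array/matrix.
#' @export
setGeneric("getMap", function(object, name) standardGeneric("getMap"))

#' Evaluate an optical force field at particle positions
#'
#' @param field A [ForceField-class].
#' @param positions N x 3 matrix of positions in metres (focus at origin).
#' @return N x 3 matrix of forces in newtons. Positions outside the tabulated
#'   grid receive zero force (the intensity there is negligible).
#' @export
setGeneric("forceAt", function(field, positions) standardGeneric("forceAt"))
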