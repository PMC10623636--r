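#' @include AllClasses.R AllGenerics.R
NULL

#' Build a TrajectorySet from a data frame
#'
#' @param tracks data.frame with columns `particle_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `z_um` and optionally `trapped`.
#' @param dt Frame interval, s (inferred from `t_s` when missing).
#' @param box Optional bounds `c(xmin, xmax, ymin, ymax, zmin, zmax)`, um.
#' @param metadata Free-form list.
#' @return A [TrajectorySet-class].
#' @export
trajectorySet <- function(tracks, dt = NULL, box = rep(NA_real_, 6),
                          metadata = list()) {
  if (!"trapped" %in% names(tracks)) tracks$trapped <- FALSE
  if (is.null(dt)) {
    dts <- unlist(tapply(tracks$t_s, tracks$particle_id,
                         function(t) diff(sort(t))))
    dt <- if (length(dts)) stats::median(dts) else NA_real_
  }
  new("TrajectorySet", tracks = tracks, dt = dt, box = box,
      metadata = metadata)
}

#' @describeIn tracks trajectory table accessor
#' @export
setMethod("tracks", "TrajectorySet", function(object) object@tracks)

#' Frame interval of a trajectory set
#' @param object A [TrajectorySet-class].
#' @return Frame interval in seconds.
#' @export
frameInterval <- function(object) {
  stopifnot(is(object, "TrajectorySet"))
  object@dt
}

#' @describeIn tracks number of particles
#' @export
setMethod("length", "TrajectorySet",
          function(x) length(unique(x@tracks$particle_id)))

#' @export
setMethod("show", "TrajectorySet", function(object) {
  tr <- object@tracks
  cat(sprintf(paste0(
    "TrajectorySet: %d particles, %d rows, dt = %.4g s\n",
    "  t in [%.3g, %.3g] s, %d rows flagged trapped\n"),
    length(object), nrow(tr), object@dt,
    if (nrow(tr)) min(tr$t_s) else NA, if (nrow(tr)) max(tr$t_s) else NA,
    sum(tr$trapped)))
})

#' @export
setMethod("as.data.frame", "TrajectorySet", function(x, ...) x@tracks)

#' Read / write trajectory tables
#'
#' Plain-CSV interchange format: columns `particle_id`, `frame`, `t_s`,
#' `x_um`, `y_um`, `z_um`, `trapped`.
#'
#' @param object A [TrajectorySet-class].
#' @param path CSV file path.
#' @return `readTrajectories` returns a [TrajectorySet-class];
#'   `writeTrajectories` returns `path` invisibly.
#' @export
writeTrajectories <- function(object, path) {
  stopifnot(is(object, "TrajectorySet"))
  utils::write.csv(object@tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  trajectorySet(utils::read.csv(path))
}
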