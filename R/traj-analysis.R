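#' @include AllClasses.R AllGenerics.R trajectory-set.R field-maps.R
NULL

#' Savitzky-Golay smoothing of a trajectory
#'
#' Third-order Savitzky-Golay polynomial smoothing applied per axis and per
#' particle. The filter reproduces polynomials up to its order exactly
#' (endpoints are handled by the least-squares fit on the truncated window),
#' so directed motion is preserved while Brownian jitter is attenuated.
#'
#' @param traj A [TrajectorySet-class] or a data.frame with trajectory
#'   columns.
#' @param window Odd window length in frames (default 11, i.e. 55 ms at
#'   200 fps).
#' @param order Polynomial order.
#' @return Same type as the input, with smoothed `x_um`, `y_um`, `z_um`.
#' @export
smoothTrajectory <- function(traj, window = 11, order = 3) {
  stopifnot(window %% 2 == 1, window > order)
  isSet <- is(traj, "TrajectorySet")
  tr <- if (isSet) traj@tracks else traj
  tr <- tr[base::order(tr$particle_id, tr$frame), ]
  short <- character()
  for (id in unique(tr$particle_id)) {
    sel <- which(tr$particle_id == id)
    if (length(sel) < window) {
      short <- c(short, format(id))
      next
    }
    for (col in c("x_um", "y_um", "z_um"))
      tr[sel, col] <- signal::sgolayfilt(tr[sel, col], p = order, n = window)
  }
  if (length(short))
    warning(sprintf("%d trajectory(ies) shorter than window: passed through (%s)",
                    length(short), paste(utils::head(short, 5), collapse = ", ")))
  if (isSet) initialize(traj, tracks = tr) else tr
}

#' Helicoidal residual analysis of an incorporation trajectory
#'
#' The distances between a tracked trajectory and its Savitzky-Golay
#' smoothed version oscillate sinusoidally in x and y when the particle
#' spirals about its incoming axis; x and y are then dephased by about 90
#' degrees and the sense of rotation follows the sign of the mean cross
#' product of the residuals. When the oscillation amplitude does not exceed
#' the Brownian residual level by at least `minAmplitudeRatio`, the
#' handedness is reported undetermined (as for roughly half the
#' experimental events).
#'
#' @param traj Original single-particle trajectory (data.frame or
#'   single-particle [TrajectorySet-class]).
#' @param smoothed Its smoothed counterpart (see [smoothTrajectory()]).
#' @param minAmplitudeRatio Detection threshold on fitted oscillation
#'   amplitude over residual noise.
#' @return A [HelixReport-class].
#' @export
helixResiduals <- function(traj, smoothed = NULL, minAmplitudeRatio = 2) {
  tr <- if (is(traj, "TrajectorySet")) traj@tracks else traj
  if (length(unique(tr$particle_id)) != 1)
    stop("helixResiduals analyses one trajectory at a time")
  if (is.null(smoothed)) smoothed <- smoothTrajectory(tr)
  sm <- if (is(smoothed, "TrajectorySet")) smoothed@tracks else smoothed
  stopifnot(nrow(sm) == nrow(tr))
  dtv <- diff(tr$t_s)
  dt <- stats::median(dtv)
  dx <- tr$x_um - sm$x_um
  dy <- tr$y_um - sm$y_um
  n <- length(dx)

  X <- stats::fft(dx - mean(dx)); Y <- stats::fft(dy - mean(dy))
  half <- 2:(floor(n / 2))
  power <- Mod(X[half])^2 + Mod(Y[half])^2
  kDom <- half[which.max(power)]
  freq <- (kDom - 1) / (n * dt)
  period <- 1 / freq
  phase <- Arg(X[kDom] * Conj(Y[kDom])) * 180 / pi

  # fitted sinusoid amplitude at the dominant frequency vs residual noise
  tt <- tr$t_s - tr$t_s[1]
  base <- cbind(cos(2 * pi * freq * tt), sin(2 * pi * freq * tt))
  ampOf <- function(v) {
    f <- stats::lm.fit(cbind(1, base), v)
    list(A = sqrt(sum(f$coefficients[2:3]^2)), s = stats::sd(f$residuals))
  }
  fx <- ampOf(dx); fy <- ampOf(dy)
  ratio <- mean(c(fx$A, fy$A)) / max(mean(c(fx$s, fy$s)), 1e-12)

  cross <- mean(dx[-n] * diff(dy) - dy[-n] * diff(dx))
  hand <- if (ratio < minAmplitudeRatio) "undetermined"
          else if (cross > 0) "anticlockwise" else "clockwise"

  new("HelixReport",
      residuals = data.frame(t_s = tr$t_s, dx_um = dx, dy_um = dy),
      period = period, phaseDeg = phase, handedness = hand,
      amplitudeRatio = ratio,
      lowConfidence = (tt[n] < 2 * period))
}

#' @export
setMethod("show", "HelixReport", function(object) {
  cat(sprintf(paste0(
    "HelixReport: period %.3g s, x-y phase %.1f deg, %s\n",
    "  amplitude/noise ratio %.2f%s\n"),
    object@period, object@phaseDeg, object@handedness,
    object@amplitudeRatio,
    if (object@lowConfidence) " (fewer than two periods: low confidence)" else ""))
})

#' Incorporation half-angle of the outer channel
#'
#' The ridge of the outer concentration channel (Gaussian-fitted outermost
#' peak of c(r) per depth section) is regressed on depth; the slope gives
#' the half-angle of the incorporation cone with respect to the optical
#' axis.
#'
#' @param x A [TrajectorySet-class] (binned internally) or a
#'   [FieldMaps-class] with `crz` filled.
#' @param zRange Depth window, um.
#' @param minCounts Minimum occupancy for a depth section to be used.
#' @param ... Passed to [binConcentration()] for the trajectory method.
#' @return List with `angle` (degrees) and `ridge` (data.frame z, radius).
#' @export
incorporationAngle <- function(x, zRange = c(-4, -0.5), minCounts = 30, ...) {
  maps <- if (is(x, "TrajectorySet")) binConcentration(x, ...) else x
  stopifnot(is(maps, "FieldMaps"), length(maps@crz) > 0)
  sel <- which(maps@zMid >= zRange[1] & maps@zMid <= zRange[2])
  ridge <- data.frame(z = numeric(), radius = numeric())
  for (j in sel) {
    if (sum(maps@countsrz[, j]) < minCounts) next
    prof <- maps@crz[, j]
    ch <- fitGaussianChannels(maps@rMid, prof, nChannels = 2)
    ch <- ch[is.finite(ch$center) & ch$channel == "outer", , drop = FALSE]
    if (!nrow(ch)) next
    ridge <- rbind(ridge, data.frame(z = maps@zMid[j], radius = ch$center))
  }
  if (nrow(ridge) < 3)
    stop("fewer than three usable depth sections for the angle fit")
  fit <- stats::lm(radius ~ depth, data = transform(ridge, depth = abs(z)))
  list(angle = atan(unname(stats::coef(fit)[2])) * 180 / pi, ridge = ridge)
}

#' Detect metastable dwell events below the focus
#'
#' Maximal intervals in which the smoothed particle speed stays below a
#' threshold while the particle is more than `minDepth` below the focus;
#' intervals separated by fewer than 2 frames are merged, and only events of
#' at least `minDuration` frames are reported. The default speed threshold
#' is twice the free-Brownian RMS frame displacement divided by the frame
#' interval.
#'
#' @param traj A [TrajectorySet-class].
#' @param medium A [MediumParticleConfig-class] (sets the default
#'   threshold).
#' @param speedThreshold Speed threshold, um/s.
#' @param minDuration Minimum event length, frames.
#' @param minDepth Minimum depth below focus, um.
#' @param window Savitzky-Golay window for the speed estimate.
#' @return data.frame with columns `particle_id`, `tStart`, `tEnd`,
#'   `meanX`, `meanY`, `meanZ`, `depth`.
#' @export
detectMetastableDwell <- function(traj, medium = mediumParticleConfig(),
                                  speedThreshold = NULL, minDuration = 3,
                                  minDepth = 1, window = 11) {
  stopifnot(is(traj, "TrajectorySet"))
  dt <- traj@dt
  if (is.null(speedThreshold)) {
    D <- diffusionCoefficient(medium)
    speedThreshold <- 2 * sqrt(6 * D * dt) / dt / .um    # um/s
  }
  sm <- smoothTrajectory(traj, window = window)@tracks
  out <- list()
  for (id in unique(sm$particle_id)) {
    p <- sm[sm$particle_id == id, ]
    if (nrow(p) < minDuration + 1) next
    v <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2 + diff(p$z_um)^2) / dt
    slow <- c(v < speedThreshold, FALSE) & p$z_um < -minDepth
    # merge interruptions shorter than 2 frames
    r <- rle(slow)
    gap <- which(!r$values & r$lengths < 2)
    gap <- gap[gap > 1 & gap < length(r$values)]
    r$values[gap] <- TRUE
    slow <- inverse.rle(r)
    r <- rle(slow)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= minDuration)) {
      i <- starts[k]:ends[k]
      out[[length(out) + 1]] <- data.frame(
        particle_id = id, tStart = p$t_s[starts[k]], tEnd = p$t_s[ends[k]],
        meanX = mean(p$x_um[i]), meanY = mean(p$y_um[i]),
        meanZ = mean(p$z_um[i]), depth = -mean(p$z_um[i]))
    }
  }
  if (!length(out))
    return(data.frame(particle_id = numeric(), tStart = numeric(),
                      tEnd = numeric(), meanX = numeric(), meanY = numeric(),
                      meanZ = numeric(), depth = numeric()))
  do.call(rbind, out)
}
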