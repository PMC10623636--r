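#' @include AllClasses.R AllGenerics.R camera.R
NULL

#' Sub-pixel spot localization by phasor analysis
#'
#' The lateral position of a single emitter is read off the phase of the
#' first Fourier coefficient of its region of interest along each axis:
#' for a spot centred at pixel j0 the coefficient is proportional to
#' `exp(-2 pi i (j0 - 1) / m)`, so the phase maps linearly to position.
#' Robust against pixelation and much faster than iterative fitting.
#'
#' @param roi Small matrix (rows = y, columns = x) containing one candidate
#'   spot near its centre.
#' @return Named vector `c(x, y)` in ROI pixel coordinates (pixel centres at
#'   integers, first pixel at 1), or `NULL` when the ROI is rejected (empty
#'   or saturated with no contrast).
#' @export
phasorLocalize <- function(roi) {
  m <- dim(roi)
  if (any(m < 3)) return(NULL)
  roi <- roi - min(roi)
  if (max(roi) <= 0) return(NULL)           # empty or saturated-flat ROI
  axisPhase <- function(profile) {
    n <- length(profile)
    f1 <- sum(profile * exp(-2i * pi * (seq_len(n) - 1) / n))
    ph <- Arg(f1)
    (-ph %% (2 * pi)) * n / (2 * pi) + 1
  }
  c(x = axisPhase(colSums(roi)), y = axisPhase(rowSums(roi)))
}

#' Detect candidate spots in a single image
#'
#' Local maxima above `background + nSigma * sqrt(background)` (Poisson
#' noise scale), excluding a border of half the ROI size.
#'
#' @param img Matrix of photon counts.
#' @param background Expected background level.
#' @param nSigma Detection threshold in background noise units.
#' @param roiHalf Half-width of the localization ROI.
#' @return data.frame with integer columns `x`, `y` and `value`.
#' @export
detectSpots <- function(img, background, nSigma = 5, roiHalf = 3) {
  thr <- background + nSigma * sqrt(max(background, 1))
  ny <- nrow(img); nx <- ncol(img)
  b <- roiHalf + 1
  if (nx <= 2 * b || ny <= 2 * b)
    return(data.frame(x = integer(), y = integer(), value = numeric()))
  core <- img[b:(ny - b), b:(nx - b)]
  isMax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    isMax <- isMax & core >= img[(b + dy):(ny - b + dy), (b + dx):(nx - b + dx)]
  }
  w <- which(isMax, arr.ind = TRUE)
  out <- data.frame(x = w[, 2] + b - 1L, y = w[, 1] + b - 1L,
                    value = core[w])
  # suppress secondary maxima on the defocused pedestal of a brighter spot:
  # keep only the strongest candidate within one ROI distance
  out <- out[order(-out$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  minSep <- 2 * roiHalf
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    d2 <- (out$x - out$x[i])^2 + (out$y - out$y[i])^2
    keep[d2 < minSep^2 & seq_len(nrow(out)) > i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  # prominence over the local background (median of the surrounding box
  # border): rejects noise bumps riding on a defocused pedestal
  if (nrow(out)) {
    h <- 2 * roiHalf
    okP <- vapply(seq_len(nrow(out)), function(i) {
      xs <- max(1, out$x[i] - h):min(nx, out$x[i] + h)
      ys <- max(1, out$y[i] - h):min(ny, out$y[i] + h)
      ring <- img[ys, xs]
      border <- c(ring[1, ], ring[nrow(ring), ], ring[, 1], ring[, ncol(ring)])
      bgLoc <- stats::median(border)
      out$value[i] - bgLoc >= nSigma * sqrt(max(bgLoc, 1))
    }, logical(1))
    out <- out[okP, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Calibrate the axial positions of the detection planes
#'
#' Reproduces the bead-scan calibration: a field of immobilized beads is
#' scanned axially; for each plane the mean image-gradient magnitude is
#' computed at every stage position and its unimodal peak is located by a
#' Gaussian fit. The peak position is the plane's focal depth. Planes whose
#' sharpness curve has no usable peak (featureless images, non-unimodal
#' response) are flagged uncalibrated.
#'
#' @param stacks Array `[ny, nx, nPlanes, nStage]` of bead images.
#' @param stageZ Stage positions (um), one per scan step.
#' @return List with `planes` (data.frame: plane, z, ok) and `curves`
#'   (matrix `[nStage, nPlanes]` of sharpness values).
#' @export
calibratePlanes <- function(stacks, stageZ) {
  d <- dim(stacks)
  stopifnot(length(d) == 4, d[4] == length(stageZ))
  nP <- d[3]
  sharp <- matrix(0, length(stageZ), nP)
  for (p in seq_len(nP)) for (s in seq_along(stageZ)) {
    img <- stacks[, , p, s]
    gx <- img[, -1] - img[, -ncol(img)]
    gy <- img[-1, ] - img[-nrow(img), ]
    sharp[s, p] <- mean(abs(gx)) + mean(abs(gy))
  }
  planes <- data.frame(plane = seq_len(nP), z = NA_real_, ok = FALSE)
  for (p in seq_len(nP)) {
    y <- sharp[, p]
    base <- min(y)
    if (max(y) - base <= 1e-9 * max(abs(y), 1)) next  # featureless
    noise <- stats::sd(y - stats::filter(y, rep(1 / 3, 3)), na.rm = TRUE)
    if (max(y) - base < 5 * noise) next               # no significant peak
    imax <- which.max(y)
    if (imax <= 1 || imax >= length(y)) next          # peak not interior
    # unimodality on the smoothed curve: a single significant maximum
    ys <- stats::filter(y, rep(1 / 5, 5))
    pkS <- which(diff(sign(diff(ys))) < 0) + 1L
    pkS <- pkS[!is.na(ys[pkS]) & ys[pkS] > base + 0.5 * (max(y) - base)]
    if (length(pkS) != 1) next
    fit <- try(minpack.lm::nlsLM(
      y ~ a * exp(-(stageZ - mu)^2 / (2 * s2^2)) + b,
      start = list(a = max(y) - base, mu = stageZ[imax],
                   s2 = diff(range(stageZ)) / 8, b = base),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    mu <- stats::coef(fit)[["mu"]]
    if (mu < min(stageZ) || mu > max(stageZ)) next
    planes$z[p] <- mu; planes$ok[p] <- TRUE
  }
  list(planes = planes, curves = sharp)
}

#' Axial localization from per-plane spot amplitudes
#'
#' With the Gaussian defocus model the peak amplitude of a spot in plane p
#' is a Lorentzian in the axial offset,
#' `A_p = A0 / (1 + ((z - z_p) / zR)^2)`; fitting this response across the
#' calibrated plane positions inverts the forward model and yields z.
#'
#' @param amplitudes Per-plane spot amplitudes (background-subtracted).
#' @param planeZ Calibrated plane depths, um.
#' @param zR Defocus range parameter of the detection PSF, um.
#' @param minPlanes Minimum number of planes with signal.
#' @param threshold Fraction of the maximum amplitude counted as signal.
#' @return List with `z` (um) and `flag` (`"ok"` or `"extrapolated"` when
#'   the response peaks at an edge plane); `NULL` if too few planes carry
#'   signal.
#' @export
axialLocalize <- function(amplitudes, planeZ, zR = 0.5, minPlanes = 3,
                          threshold = 0.05) {
  ok <- is.finite(amplitudes) & amplitudes > threshold * max(amplitudes)
  if (sum(ok) < minPlanes) return(NULL)
  imax <- which.max(amplitudes)
  flag <- if (imax == 1 || imax == length(amplitudes)) "extrapolated" else "ok"
  a <- amplitudes[ok]; zp <- planeZ[ok]
  z0 <- sum(zp * a) / sum(a)
  # free width absorbs pixel-integration broadening of the peak response
  fit <- try(minpack.lm::nlsLM(
    a ~ A0 / (1 + ((zp - mu) / zRf)^2),
    start = list(A0 = max(a), mu = z0, zRf = zR),
    lower = c(0, min(planeZ) - 2, zR / 4),
    upper = c(Inf, max(planeZ) + 2, 10 * zR),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  z <- if (inherits(fit, "try-error")) z0 else stats::coef(fit)[["mu"]]
  list(z = z, flag = flag)
}

#' Localize all particles in a multiplane frame
#'
#' Detection on the per-pixel maximum across planes, lateral sub-pixel
#' position by phasor analysis of the sharpest plane's ROI, axial position
#' by the Lorentzian fit of the per-plane ROI amplitudes
#' (see [axialLocalize()]).
#'
#' @param stack A [PlaneStack-class].
#' @param cfg The [CameraOpticsConfig-class] used for rendering/detection.
#' @param calibration Optional plane depths (um); defaults to the stack's.
#' @param roiHalf ROI half-width, pixels.
#' @param nSigma Detection threshold.
#' @return data.frame with columns `frame`, `x_um`, `y_um`, `z_um`,
#'   `intensity`, `zFlag`.
#' @export
localizeFrame <- function(stack, cfg, calibration = NULL, roiHalf = 3,
                          nSigma = 5) {
  imgs <- stack@images
  planeZ <- if (is.null(calibration)) stack@planeZ else calibration
  # detect on the plane sum: all defocused copies add coherently in xy
  proj <- apply(imgs, c(1, 2), sum)
  cand <- detectSpots(proj, cfg@background * cfg@nPlanes, nSigma = nSigma,
                      roiHalf = roiHalf)
  nx <- ncol(proj); ny <- nrow(proj)
  box3 <- function(m) {   # 3x3 mean filter (noise-robust peak estimate)
    nr <- nrow(m); nc <- ncol(m)
    p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
    (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
     p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
     p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    xs <- (cand$x[i] - roiHalf):(cand$x[i] + roiHalf)
    ys <- (cand$y[i] - roiHalf):(cand$y[i] + roiHalf)
    amps <- vapply(seq_along(planeZ), function(p) {
      max(box3(imgs[ys, xs, p])) - cfg@background
    }, numeric(1))
    pBest <- which.max(amps)
    loc <- phasorLocalize(imgs[ys, xs, pBest])
    if (is.null(loc)) next
    ax <- axialLocalize(amps, planeZ, zR = cfg@psfZR)
    if (is.null(ax)) next
    xPix <- xs[1] + loc[["x"]] - 1; yPix <- ys[1] + loc[["y"]] - 1
    out[[i]] <- data.frame(
      frame = stack@frame,
      x_um = (xPix - (nx + 1) / 2) * cfg@pixelSize,
      y_um = (yPix - (ny + 1) / 2) * cfg@pixelSize,
      z_um = ax$z,
      intensity = sum(amps[amps > 0]),
      zFlag = ax$flag)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = numeric(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), intensity = numeric(),
                      zFlag = character())
  out
}

#' Link frame-wise detections into trajectories
#'
#' Greedy nearest-neighbour assignment with a hard displacement gate, gap
#' closing over up to `maxGap` missed frames, and a conservative ambiguity
#' rule: when the two best candidate tracks for a detection have costs
#' within 10 % of each other, the link is refused and a new trajectory is
#' started rather than risking an identity swap.
#'
#' @param detections data.frame with columns `frame`, `x_um`, `y_um`,
#'   `z_um` (as produced by [localizeFrame()]).
#' @param maxDisp Maximum displacement per frame, um.
#' @param maxGap Maximum number of bridged missing frames.
#' @param dt Frame interval, s.
#' @return A [TrajectorySet-class].
#' @export
linkTrajectories <- function(detections, maxDisp, maxGap = 2, dt = 0.005) {
  det <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  lastPos <- matrix(numeric(), 0, 3)
  lastFrame <- integer(); trackId <- integer()
  nextId <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- det[det$frame == f, , drop = FALSE]
    P <- as.matrix(cur[, c("x_um", "y_um", "z_um")])
    assigned <- rep(NA_integer_, nrow(cur))
    if (length(trackId)) {
      active <- which(f - lastFrame <= maxGap + 1L)
      if (length(active) && nrow(cur)) {
        gapF <- f - lastFrame[active]
        cost <- outer(seq_along(active), seq_len(nrow(cur)),
                      Vectorize(function(a, d)
                        sqrt(sum((lastPos[active[a], ] - P[d, ])^2))))
        gate <- maxDisp * gapF           # allow proportionally more per gap
        cost[cost > gate] <- Inf
        repeat {
          if (!any(is.finite(cost))) break
          m <- which(cost == min(cost), arr.ind = TRUE)[1, ]
          a <- m[1]; d <- m[2]
          best <- cost[a, d]
          others <- cost[, d]; others[a] <- Inf
          second <- min(others)
          if (is.finite(second) && second < 1.1 * best && second > 0) {
            # ambiguous: refuse the link, detection starts a new track
            cost[, d] <- Inf
            next
          }
          assigned[d] <- active[a]
          cost[a, ] <- Inf; cost[, d] <- Inf
        }
      }
    }
    for (d in seq_len(nrow(cur))) {
      if (is.na(assigned[d])) {
        trackId <- c(trackId, nextId)
        lastPos <- rbind(lastPos, P[d, ])
        lastFrame <- c(lastFrame, f)
        assigned[d] <- length(trackId)
        nextId <- nextId + 1L
      } else {
        lastPos[assigned[d], ] <- P[d, ]
        lastFrame[assigned[d]] <- f
      }
    }
    rows[[fi]] <- data.frame(particle_id = trackId[assigned], frame = f,
                             t_s = (f - 1) * dt, x_um = P[, 1],
                             y_um = P[, 2], z_um = P[, 3], trapped = FALSE)
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$particle_id, tr$frame), ]
  rownames(tr) <- NULL
  trajectorySet(tr, dt = dt)
}

#' Displacement gate for trajectory linking
#'
#' Default gate: five standard deviations of the free Brownian 3D frame
#' displacement plus the largest expected drift per frame.
#'
#' @param medium A [MediumParticleConfig-class].
#' @param dt Frame interval, s.
#' @param maxDriftSpeed Largest expected directed speed, m/s.
#' @return Gate in um.
#' @export
linkingGate <- function(medium, dt = 0.005, maxDriftSpeed = 200e-6) {
  D <- diffusionCoefficient(medium)
  (5 * sqrt(6 * D * dt) + maxDriftSpeed * dt) / .um
}
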