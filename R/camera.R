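#' @include AllClasses.R AllGenerics.R
NULL

#' Create a camera/detection configuration
#'
#' Defaults describe the multiplane widefield detection used throughout:
#' eight simultaneously recorded planes spaced by 580 nm (axial range about
#' 4 um), 100 nm pixels over a 50 x 50 um field (500 x 500 pixels), 200
#' frames per second. Plane 1 is conjugate to the trapping focus and deeper
#' planes image below it, so plane p sits at `z = -(p - 1) * planeSpacing`.
#'
#' The defocus model is the standard widefield Gaussian approximation:
#' `sigma(z) = psfSigma0 * sqrt(1 + (z / psfZR)^2)`, with the photon budget
#' split equally among the planes (1/8 each) and per-pixel Poisson noise
#' plus Gaussian read noise.
#'
#' @param nPlanes Number of planes.
#' @param planeSpacing Plane separation, um.
#' @param frameRate Frames per second.
#' @param pixelSize Pixel size in sample space, um.
#' @param frameSize `c(nx, ny)` pixels.
#' @param psfSigma0 In-focus lateral PSF sigma, um.
#' @param psfZR Defocus range parameter, um.
#' @param photonBudget Detected photons per particle per frame.
#' @param background Background photons per pixel per plane.
#' @param readNoise Read noise rms, electrons.
#' @return A [CameraOpticsConfig-class].
#' @export
cameraOpticsConfig <- function(nPlanes = 8, planeSpacing = 0.58,
                               frameRate = 200, pixelSize = 0.1,
                               frameSize = c(500, 500), psfSigma0 = 0.11,
                               psfZR = 0.5, photonBudget = 20000,
                               background = 5, readNoise = 1) {
  new("CameraOpticsConfig", nPlanes = nPlanes, planeSpacing = planeSpacing,
      frameRate = frameRate, pixelSize = pixelSize, frameSize = frameSize,
      psfSigma0 = psfSigma0, psfZR = psfZR, photonBudget = photonBudget,
      background = background, readNoise = readNoise)
}

#' Axial positions of the detection planes
#' @param cfg A [CameraOpticsConfig-class].
#' @return Plane depths in um (plane 1 at the focus, deeper planes below).
#' @export
planePositions <- function(cfg) {
  -(seq_len(cfg@nPlanes) - 1) * cfg@planeSpacing
}

.defocusSigma <- function(cfg, dz) cfg@psfSigma0 * sqrt(1 + (dz / cfg@psfZR)^2)

## Pixel-integrated Gaussian spot: photons spread over pixels by the
## difference of the Gaussian CDF across pixel edges (photon-conserving in
## the noiseless path, up to the tails clipped at the frame edge).
.addSpot <- function(img, xPix, yPix, sigmaPix, photons) {
  nx <- ncol(img); ny <- nrow(img)
  halfw <- max(3, ceiling(6 * sigmaPix))
  x0 <- max(1, floor(xPix - halfw)); x1 <- min(nx, ceiling(xPix + halfw))
  y0 <- max(1, floor(yPix - halfw)); y1 <- min(ny, ceiling(yPix + halfw))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  # pixel i covers [i - 0.5, i + 0.5); pixel centres at integers
  fx <- stats::pnorm(xs + 0.5, xPix, sigmaPix) - stats::pnorm(xs - 0.5, xPix, sigmaPix)
  fy <- stats::pnorm(ys + 0.5, yPix, sigmaPix) - stats::pnorm(ys - 0.5, yPix, sigmaPix)
  img[ys, xs] <- img[ys, xs] + photons * outer(fy, fx)
  img
}

#' Render one multiplane frame from particle positions
#'
#' Forward model of the instrument: every particle appears in every plane as
#' a pixel-integrated Gaussian spot whose width grows, and whose peak dims,
#' with defocus; the collected photons are split equally among the planes.
#' Positions are in um with the optical axis through the centre of the field
#' of view: sample x in [-L/2, L/2] maps to pixel columns 1..nx.
#'
#' @param positions N x 3 matrix of particle positions, um.
#' @param cfg A [CameraOpticsConfig-class].
#' @param frame Frame index stored in the output.
#' @param noise Apply Poisson photon noise and Gaussian read noise.
#' @return A [PlaneStack-class].
#' @export
renderFrame <- function(positions, cfg = cameraOpticsConfig(), frame = 1L,
                        noise = TRUE) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  nx <- cfg@frameSize[1]; ny <- cfg@frameSize[2]
  pz <- planePositions(cfg)
  imgs <- array(cfg@background, dim = c(ny, nx, cfg@nPlanes))
  perPlane <- cfg@photonBudget / cfg@nPlanes
  for (p in seq_len(cfg@nPlanes)) {
    img <- imgs[, , p]
    for (i in seq_len(nrow(positions))) {
      xPix <- positions[i, 1] / cfg@pixelSize + (nx + 1) / 2
      yPix <- positions[i, 2] / cfg@pixelSize + (ny + 1) / 2
      sig <- .defocusSigma(cfg, positions[i, 3] - pz[p]) / cfg@pixelSize
      img <- .addSpot(img, xPix, yPix, sig, perPlane)
    }
    imgs[, , p] <- img
  }
  if (noise) {
    imgs[] <- stats::rpois(length(imgs), lambda = imgs)
    if (cfg@readNoise > 0)
      imgs[] <- pmax(0, imgs + stats::rnorm(length(imgs), sd = cfg@readNoise))
  }
  new("PlaneStack", images = imgs, planeZ = pz, frame = as.numeric(frame),
      pixelSize = cfg@pixelSize)
}

#' @describeIn planeImages image array accessor
#' @export
setMethod("planeImages", "PlaneStack", function(object) object@images)

#' @describeIn planeDepths plane depth accessor
#' @export
setMethod("planeDepths", "PlaneStack", function(object) object@planeZ)

#' @export
setMethod("show", "PlaneStack", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "PlaneStack: frame %d, %d planes of %d x %d px (%.0f nm px), z %.2f..%.2f um\n",
    object@frame, d[3], d[2], d[1], object@pixelSize * 1e3,
    max(object@planeZ), min(object@planeZ)))
})

#' Write / read a multiplane stack as multipage TIFF
#'
#' One 32-bit float page per plane (frame-major when several stacks are
#' given); a JSON sidecar carries the plane depths and pixel size.
#'
#' @param stacks A [PlaneStack-class] or list of them.
#' @param path TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `writePlaneStacks` returns `path` invisibly; `readPlaneStacks`
#'   returns a list of [PlaneStack-class].
#' @export
writePlaneStacks <- function(stacks, path) {
  if (is(stacks, "PlaneStack")) stacks <- list(stacks)
  pages <- list()
  for (st in stacks)
    for (p in seq_along(st@planeZ))
      pages[[length(pages) + 1]] <- st@images[, , p] / max(1, max(st@images))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(planeZ = stacks[[1]]@planeZ,
               pixelSize = stacks[[1]]@pixelSize,
               frames = vapply(stacks, function(s) s@frame, numeric(1)),
               scale = vapply(stacks, function(s) max(1, max(s@images)),
                              numeric(1)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePlaneStacks
#' @export
readPlaneStacks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  np <- length(meta$planeZ)
  lapply(seq_along(meta$frames), function(i) {
    imgs <- simplify2array(pages[((i - 1) * np + 1):(i * np)]) * meta$scale[i]
    new("PlaneStack", images = imgs, planeZ = meta$planeZ,
        frame = meta$frames[i], pixelSize = meta$pixelSize)
  })
}
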