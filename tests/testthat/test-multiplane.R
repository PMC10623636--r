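smallCamera <- function(...) cameraOpticsConfig(frameSize = c(32, 32), ...)

test_that("renderer: background, defocus ordering and symmetry", {
  cfg <- smallCamera()
  # no particles: pure background
  st0 <- renderFrame(matrix(numeric(), 0, 3), cfg, noise = FALSE)
  expect_equal(unique(as.vector(planeImages(st0))), cfg@background)
  st0n <- renderFrame(matrix(numeric(), 0, 3), cfg, noise = TRUE)
  expect_equal(mean(planeImages(st0n)), cfg@background, tolerance = 0.05)

  # particle at plane 3's depth: plane 3 is brightest and sharpest
  pz <- planePositions(cfg)
  st <- renderFrame(matrix(c(0, 0, pz[3]), 1), cfg, noise = FALSE)
  peaks <- apply(planeImages(st), 3, max)
  expect_equal(which.max(peaks), 3)

  # particle midway between planes 4 and 5: symmetric response
  mid <- (pz[4] + pz[5]) / 2
  stm <- renderFrame(matrix(c(0, 0, mid), 1), cfg, noise = FALSE)
  pk <- apply(planeImages(stm), 3, max)
  expect_equal(pk[4], pk[5], tolerance = 1e-10)
  expect_equal(pk[3], pk[6], tolerance = 1e-10)
})

test_that("renderer conserves photons in the noiseless path", {
  cfg <- cameraOpticsConfig(frameSize = c(128, 128))
  pos <- rbind(c(0.4, -0.3, -1.3), c(-0.8, 0.6, -2.4))
  st <- renderFrame(pos, cfg, noise = FALSE)
  total <- sum(planeImages(st))
  expected <- cfg@photonBudget * nrow(pos) +
    cfg@background * prod(cfg@frameSize) * cfg@nPlanes
  expect_lt(abs(total - expected) / expected, 1e-6)
})

test_that("phasor localization is exact on symmetric spots and shifts", {
  g <- function(cx, cy, m = 7, s = 1.2)
    outer(1:m, 1:m, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
  # centred spot
  loc <- phasorLocalize(g(4, 4))
  expect_equal(unname(loc["x"]), 4, tolerance = 1e-9)
  expect_equal(unname(loc["y"]), 4, tolerance = 1e-9)
  # a circular one-pixel shift is recovered as exactly 1.000 px
  # (discrete Fourier shift theorem)
  img <- g(4, 4)
  imgSh <- img[, c(7, 1:6)]
  loc2 <- phasorLocalize(imgSh)
  expect_equal(unname(loc2["x"] - loc["x"]), 1, tolerance = 1e-9)
  # rejected degenerate ROI
  expect_null(phasorLocalize(matrix(7, 7, 7)))
})

test_that("localization precision at the default photon budget", {
  cfg <- smallCamera()
  true <- c(0.13, -0.21, -1.77)
  set.seed(21)
  est <- t(vapply(1:250, function(i) {
    st <- renderFrame(matrix(true, 1), cfg, noise = TRUE)
    d <- localizeFrame(st, cfg)
    if (!nrow(d)) return(c(NA_real_, NA_real_, NA_real_))
    j <- which.min((d$x_um - true[1])^2 + (d$y_um - true[2])^2)
    c(d$x_um[j], d$y_um[j], d$z_um[j])
  }, numeric(3)))
  est <- est[complete.cases(est), ]
  expect_gt(nrow(est), 200)
  expect_lt(sd(est[, 1]), 0.020)            # lateral <= 20 nm
  expect_lt(sd(est[, 2]), 0.020)
  expect_lt(sd(est[, 3]), 0.040)            # axial <= 40 nm
  expect_lt(abs(mean(est[, 3]) - true[3]), 0.02)
})

test_that("plane calibration recovers the 580 nm stack geometry", {
  fx <- generateFixtures("bead-zstack", seed = 3)
  cal <- calibratePlanes(fx$stacks, fx$stageZ)
  ok <- cal$planes$ok
  expect_gte(sum(ok), 7)
  err <- cal$planes$z[ok] - fx$truth[ok]
  expect_lt(max(abs(err)), 0.020)
  spacing <- -diff(cal$planes$z[ok])
  expect_equal(mean(spacing), 0.58, tolerance = 0.02)
})

test_that("featureless images are flagged uncalibrated", {
  stacks <- array(3, dim = c(16, 16, 4, 11))
  cal <- calibratePlanes(stacks, seq(-2, 2, length.out = 11))
  expect_false(any(cal$planes$ok))
})

test_that("axial localization inverts the defocus model", {
  cfg <- smallCamera()
  pz <- planePositions(cfg)
  locZ <- function(z) {
    st <- renderFrame(matrix(c(0, 0, z), 1), cfg, noise = FALSE)
    d <- localizeFrame(st, cfg)
    if (nrow(d) != 1) NA_real_ else d$z_um
  }
  # exactly at a plane
  expect_equal(locZ(pz[4]), pz[4], tolerance = 1e-3)
  # noiseless scan +-1.5 um around the stack centre: error < 30 nm
  zt <- seq(mean(range(pz)) - 1.5, mean(range(pz)) + 1.5, by = 0.06)
  err <- vapply(zt, function(z) locZ(z) - z, numeric(1))
  expect_lt(max(abs(err)), 0.030)
  # signal peaking at an edge plane is flagged extrapolated
  stEdge <- renderFrame(matrix(c(0, 0, 0.4), 1), cfg, noise = FALSE)
  dEdge <- localizeFrame(stEdge, cfg)
  expect_equal(dEdge$zFlag, "extrapolated")
})

test_that("linking keeps identities and breaks ambiguous assignments", {
  # single noiseless particle: one full-length trajectory
  tr <- lineTrajectory(n = 30)
  lt <- linkTrajectories(tr[, c("frame", "x_um", "y_um", "z_um")],
                         maxDisp = 0.5)
  expect_equal(length(lt), 1)
  expect_equal(nrow(tracks(lt)), 30)

  # two well-separated particles: two trajectories, no swaps
  tr2 <- rbind(lineTrajectory(n = 30, id = 1),
               lineTrajectory(n = 30, from = c(5, 5, -4), to = c(5, 5, -0.5),
                              id = 2))
  lt2 <- linkTrajectories(tr2[, c("frame", "x_um", "y_um", "z_um")],
                          maxDisp = 0.5)
  t2 <- tracks(lt2)
  expect_equal(length(lt2), 2)
  sep <- tapply(t2$x_um, t2$particle_id, function(x) diff(range(x)))
  expect_lt(max(sep), 1)                     # no cross-field jumps

  # crossing pair over 100 seeded runs: identity swaps are rare; the
  # ambiguity rule prefers breaking a track over swapping it
  swaps <- 0; nTracks <- 0
  for (s in 1:100) {
    fx <- tracks(generateFixtures("crossing-pair", seed = s))
    lt3 <- linkTrajectories(fx[, c("frame", "x_um", "y_um", "z_um")],
                            maxDisp = 0.25)
    t3 <- tracks(lt3)
    for (id in unique(t3$particle_id)) {
      g <- t3[t3$particle_id == id, ]
      if (nrow(g) < 2) next
      nTracks <- nTracks + 1
      if (diff(range(g$y_um)) > 0.12) swaps <- swaps + 1
    }
  }
  expect_lt(swaps / nTracks, 0.05)
})

test_that("simulate-render-localize round trip recovers the positions", {
  cfg <- cameraOpticsConfig(frameSize = c(128, 128))
  med <- waterMedium()
  run <- simulationRun(dt = 5e-5, nSteps = 1500, nParticles = 8,
                       outputStride = 100, box = c(-6, 6, -6, 6, -3.2, -0.9),
                       seed = 3, trapRadius = 1e-12)
  traj <- simulateDynamics(NULL, med, run)
  tr <- tracks(traj)
  set.seed(11)
  matched <- 0; total <- 0
  for (f in sort(unique(tr$frame))) {
    p <- tr[tr$frame == f, ]
    st <- renderFrame(as.matrix(p[, c("x_um", "y_um", "z_um")]), cfg,
                      frame = f, noise = TRUE)
    d <- localizeFrame(st, cfg)
    for (i in seq_len(nrow(p))) {
      # overlapping pairs excluded (unresolvable by any detector);
      # axial range restricted to the calibrated plane span
      nn <- sqrt((p$x_um - p$x_um[i])^2 + (p$y_um - p$y_um[i])^2)
      nn[i] <- Inf
      if (min(nn) < 1 || p$z_um[i] < -3.6 || p$z_um[i] > -0.5) next
      total <- total + 1
      if (!nrow(d)) next
      e <- sqrt((d$x_um - p$x_um[i])^2 + (d$y_um - p$y_um[i])^2 +
                (d$z_um - p$z_um[i])^2)
      if (min(e) < 0.050) matched <- matched + 1
    }
  }
  expect_gt(total, 50)
  expect_gte(matched / total, 0.95)
})
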