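test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  t <- seq(0, 1, length.out = 80)
  cub <- 1 + 2 * t - 3 * t^2 + 0.5 * t^3
  tr <- data.frame(particle_id = 1, frame = seq_along(t), t_s = t,
                   x_um = cub, y_um = 2 * cub, z_um = -1 + t, trapped = FALSE)
  sm <- smoothTrajectory(tr, window = 11, order = 3)
  expect_lt(max(abs(sm$x_um - cub)), 1e-10)
  # constant trajectory unchanged; smoothing idempotent on polynomials
  trc <- transform(tr, x_um = 5)
  expect_equal(smoothTrajectory(trc)$x_um, rep(5, nrow(trc)))
  expect_equal(smoothTrajectory(sm)$x_um, sm$x_um, tolerance = 1e-10)
  # short trajectory passes through with a warning
  expect_warning(smoothTrajectory(tr[1:5, ]), "shorter than window")
})

test_that("smoothing attenuates white noise by the filter gain", {
  set.seed(14)
  n <- 5000
  tr <- data.frame(particle_id = 1, frame = 1:n, t_s = (1:n) * 0.005,
                   x_um = rnorm(n), y_um = rnorm(n), z_um = rnorm(n),
                   trapped = FALSE)
  sm <- smoothTrajectory(tr, window = 11, order = 3)
  # theoretical variance gain: sum of squared central-row coefficients
  h <- signal::sgolay(p = 3, n = 11)[6, ]
  gain <- sum(h^2)
  expect_equal(var(sm$x_um[20:(n - 20)]) , gain, tolerance = 0.1 * gain)
})

test_that("helicoidal residuals: phase, handedness and Brownian rejection", {
  hx <- generateFixtures("helix", seed = 1)
  h <- helixResiduals(tracks(hx))
  expect_lt(abs(h@phaseDeg - 90), 5)
  expect_equal(h@handedness, "anticlockwise")
  expect_gt(h@amplitudeRatio, 2)
  expect_equal(h@period, 0.1, tolerance = 0.01)
  expect_false(h@lowConfidence)

  # mirrored helix: opposite phase and handedness
  trm <- tracks(hx); trm$y_um <- -trm$y_um
  hm <- helixResiduals(trm)
  expect_lt(abs(hm@phaseDeg + 90), 5)
  expect_equal(hm@handedness, "clockwise")

  # mirrored pairs always flip or both stay undetermined (zero-mean statistic)
  set.seed(33)
  for (k in 1:10) {
    n <- 160
    tr <- data.frame(particle_id = 1, frame = 1:n, t_s = (1:n) * 0.005,
                     x_um = cumsum(rnorm(n, sd = 0.05)) +
                            0.3 * cos(2 * pi * (1:n) / 25),
                     y_um = cumsum(rnorm(n, sd = 0.05)) +
                            sample(c(-0.3, 0.3), 1) * sin(2 * pi * (1:n) / 25),
                     z_um = -2, trapped = FALSE)
    mir <- transform(tr, y_um = -y_um)
    h1 <- helixResiduals(tr); h2 <- helixResiduals(mir)
    if (h1@handedness == "undetermined") {
      expect_equal(h2@handedness, "undetermined")
    } else {
      expect_false(h1@handedness == h2@handedness)
    }
  }

  # pure Brownian trajectories: at least 90 % flagged undetermined
  set.seed(99)
  det <- 0
  for (s in 1:100) {
    n <- 150
    tr <- data.frame(particle_id = 1, frame = 1:n, t_s = (1:n) * 0.005,
                     x_um = cumsum(rnorm(n, sd = 0.07)),
                     y_um = cumsum(rnorm(n, sd = 0.07)),
                     z_um = cumsum(rnorm(n, sd = 0.07)), trapped = FALSE)
    if (helixResiduals(tr)@handedness != "undetermined") det <- det + 1
  }
  expect_lte(det / 100, 0.10)
})

test_that("incorporation angle recovers a constructed 30 degree cone", {
  cone <- generateFixtures("cone-trajectories", seed = 2)
  ia <- incorporationAngle(cone)
  expect_lt(abs(ia$angle - 30), 1)
  # too few usable depths
  shallow <- tracks(cone)
  shallow <- shallow[shallow$z_um > -1, ]
  expect_error(incorporationAngle(trajectorySet(shallow, dt = 0.005)),
               "fewer than three")
})

test_that("metastable dwell detection finds inserted pauses only", {
  dt <- 0.005; n <- 60
  # uniform-velocity descent: no events at a threshold below the speed
  z1 <- seq(-4, -0.5, length.out = n)
  tr1 <- data.frame(particle_id = 1, frame = 1:n, t_s = (1:n) * dt,
                    x_um = seq(2, 0, length.out = n), y_um = 0, z_um = z1,
                    trapped = FALSE)
  dw1 <- detectMetastableDwell(trajectorySet(tr1, dt = dt),
                               speedThreshold = 5)
  expect_equal(nrow(dw1), 0)

  # a 12-frame full stop at z = -2.1 yields exactly one event covering it
  hold <- 25:36
  x2 <- seq(2, 0, length.out = n); z2 <- seq(-4, -0.5, length.out = n)
  x2[hold] <- x2[hold[1]]; z2[hold] <- z2[hold[1]]
  tr2 <- data.frame(particle_id = 1, frame = 1:n, t_s = (1:n) * dt,
                    x_um = x2, y_um = 0, z_um = z2, trapped = FALSE)
  dw2 <- detectMetastableDwell(trajectorySet(tr2, dt = dt),
                               speedThreshold = 5)
  expect_equal(nrow(dw2), 1)
  # the smoothing window erodes the pause edges by up to half a window
  expect_lt(dw2$tStart, (hold[1] + 5) * dt)
  expect_gt(dw2$tEnd, (hold[length(hold)] - 6) * dt)
  expect_equal(dw2$meanZ, z2[hold[1]], tolerance = 0.3)
})

test_that("dwells in the full-aperture trap cluster at the secondary focus", {
  med <- waterMedium()
  ff240 <- scaleForceField(coarseForce36(), 240e-3)
  set.seed(4)
  n <- 120
  init <- cbind(runif(n, -0.6, 0.6), runif(n, -0.6, 0.6),
                runif(n, -3.2, -1.2))
  run <- simulationRun(dt = 5e-5, nSteps = 6000, nParticles = n, seed = 11,
                       box = c(-3, 3, -3, 3, -4.5, 0.3), outputStride = 100,
                       trapRadius = 150e-9)
  tj <- simulateDynamics(ff240, med, run, positions = init)
  # sustained (>= 25 ms) stalls: transient slow patches during the approach
  # are excluded, leaving the metastable residences
  dw <- detectMetastableDwell(tj, med, minDuration = 5)
  expect_gte(nrow(dw), 5)
  sec <- axialMaxima(onAxisIntensity(fullApertureConfig()))
  secZ <- sec$z[sec$relIntensity < 0.999][1]
  expect_lt(abs(median(dw$depth) - (-secZ)), 0.5)
})

test_that("channel ridge angle of simulated incorporation matches the contour", {
  med <- waterMedium()
  ff240 <- scaleForceField(coarseForce36(), 240e-3)
  set.seed(3)
  n <- 800
  init <- cbind(runif(n, -3.6, 3.6), runif(n, -3.6, 3.6),
                runif(n, -4.4, -0.2))
  run <- simulationRun(dt = 5e-5, nSteps = 8000, nParticles = n, seed = 9,
                       box = c(-4.2, 4.2, -4.2, 4.2, -4.5, 0.3),
                       outputStride = 40, trapRadius = 150e-9)
  tj <- simulateDynamics(ff240, med, run, positions = init)
  m <- binConcentration(tj, rBreaks = seq(0, 4.2, by = 0.2), axis = c(0, 0))
  # outer channel is resolvable only below the inner cone's collapse point
  ia <- incorporationAngle(m, zRange = c(-4.2, -2.3))
  contour <- contourHalfAngle(coarseField36())$angle
  expect_lt(abs(ia$angle - contour), 5)
})
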