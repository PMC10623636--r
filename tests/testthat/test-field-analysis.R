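kB <- 1.380649e-23

test_that("concentration binning: uniform, delta and Boltzmann inputs", {
  set.seed(12)
  # uniform positions: flat c3d within Poisson error
  n <- 20000
  tr <- data.frame(particle_id = seq_len(n), frame = 1, t_s = 0,
                   x_um = runif(n, -4, 4), y_um = runif(n, -4, 4),
                   z_um = runif(n, -4, 0), trapped = FALSE)
  m <- binConcentration(trajectorySet(tr, dt = 0.005),
                        xBreaks = seq(-4, 4, by = 2),
                        yBreaks = seq(-4, 4, by = 2),
                        zBreaks = seq(-4, 0, by = 1),
                        rBreaks = seq(0, 4, by = 0.5), axis = c(0, 0))
  cnt <- getMap(m, "counts3d")
  expect_gt(chisq.test(as.vector(cnt))$p.value, 0.01)
  expect_equal(sum(cnt), n)

  # all mass in one voxel
  tr1 <- data.frame(particle_id = 1:50, frame = 1, t_s = 0,
                    x_um = 0.1, y_um = 0.1, z_um = -1.1, trapped = FALSE)
  m1 <- binConcentration(trajectorySet(tr1, dt = 0.005),
                         xBreaks = seq(-2, 2, 1), yBreaks = seq(-2, 2, 1),
                         zBreaks = seq(-2, 0, 1), rBreaks = seq(0, 2, 0.5),
                         axis = c(0, 0))
  c1 <- getMap(m1, "counts3d")
  expect_equal(sum(c1), 50)
  expect_equal(sum(c1 > 0), 1)

  # Boltzmann-weighted sample: concentration ratio = exp(-dU / kB T)
  pos <- generateFixtures("boltzmann-box", seed = 5)
  trB <- data.frame(particle_id = seq_len(nrow(pos)), frame = 1, t_s = 0,
                    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3] - 5.001,
                    trapped = FALSE)
  mB <- binConcentration(trajectorySet(trB, dt = 0.005),
                         xBreaks = seq(-5, 5, by = 1),
                         yBreaks = seq(-5, 5, by = 1),
                         zBreaks = seq(-10.01, 0, by = 2),
                         rBreaks = seq(0, 5, 1), axis = c(0, 0))
  c3 <- getMap(mB, "c3d")
  inside <- mean(c3[4:7, , ]); outside <- mean(c3[c(1:3, 8:10), , ])
  expect_equal(inside / outside, 10, tolerance = 0.15)

  # empty input warns
  expect_warning(binConcentration(trajectorySet(tr1[0, ], dt = 0.005)),
                 "empty")
})

test_that("velocity field recovers constructed flows and nulls", {
  # radial inflow v = -v0 r_hat, two frames
  set.seed(3)
  n <- 4000; v0 <- 5; dt <- 0.005
  r0 <- runif(n, 1, 4); th <- runif(n, 0, 2 * pi); z0 <- runif(n, -3.9, -0.1)
  mk <- function(frame, rr) data.frame(
    particle_id = seq_len(n), frame = frame, t_s = (frame - 1) * dt,
    x_um = rr * cos(th), y_um = rr * sin(th), z_um = z0, trapped = FALSE)
  tj <- trajectorySet(rbind(mk(1, r0), mk(2, r0 - v0 * dt)), dt = dt)
  m <- binConcentration(tj, axis = c(0, 0))
  m <- velocityField(m, tj, nMin = 5)
  vr <- getMap(m, "vr"); vz <- getMap(m, "vz")
  expect_equal(median(vr, na.rm = TRUE), -v0, tolerance = 0.02)
  expect_lt(max(abs(vz), na.rm = TRUE), 1e-9)

  # stationary particles: zero field
  tj0 <- trajectorySet(rbind(mk(1, r0), transform(mk(2, r0))), dt = dt)
  m0 <- velocityField(binConcentration(tj0, axis = c(0, 0)), tj0, nMin = 5)
  expect_equal(max(abs(getMap(m0, "vr")), na.rm = TRUE), 0)

  # pure Brownian motion: per-bin mean velocity consistent with zero
  med <- waterMedium()
  run <- simulationRun(dt = 5e-5, nSteps = 2000, nParticles = 500,
                       box = c(-4, 4, -4, 4, -4, 0), seed = 17,
                       outputStride = 100, trapRadius = 1e-12)
  tjB <- simulateDynamics(NULL, med, run)
  mB <- velocityField(binConcentration(tjB, axis = c(0, 0)), tjB, nMin = 10)
  vrB <- getMap(mB, "vr"); cntB <- getMap(mB, "vCounts")
  D <- diffusionCoefficient(med) / 1e-12          # um^2/s
  sePer <- sqrt(2 * D / tjB@dt)                   # noise sd per sample
  zscore <- vrB / (sePer / sqrt(cntB))
  expect_lt(mean(abs(zscore) > 3, na.rm = TRUE), 0.02)
})

test_that("Stokes drag converts velocity to force", {
  expect_equal(stokesForce(0), 0)
  # 100 um/s on a 100 nm-radius sphere in water: ~1.9e-13 N
  ref <- 6 * pi * 1e-3 * 100e-9 * 100e-6
  expect_equal(stokesForce(100e-6), ref, tolerance = 1e-12)
  expect_equal(stokesForce(100e-6) * 1e13, 1.885, tolerance = 0.001)
  expect_equal(stokesForce(2 * 100e-6), 2 * stokesForce(100e-6))
})

test_that("Peclet number: two routes agree and viscosity cancels", {
  med <- waterMedium()
  v <- c(0, 1e-6, 5e-5, 2e-4)
  expect_equal(pecletNumber(v = 0, medium = med), 0)
  peV <- pecletNumber(v = v, medium = med)
  peF <- pecletNumber(force = stokesForce(v, med@eta, med@radius),
                      medium = med)
  expect_equal(peV, peF, tolerance = 1e-12)
  # at fixed force, quadrupling the viscosity leaves Pe unchanged
  med4 <- mediumParticleConfig(preset = "glycerol40")
  Ffix <- 1e-13
  expect_equal(pecletNumber(force = Ffix, medium = med),
               pecletNumber(force = Ffix, medium = med4), tolerance = 1e-12)
  # equivalently: the slower drift in the viscous medium compensates
  vW <- Ffix / (6 * pi * med@eta * med@radius)
  vG <- Ffix / (6 * pi * med4@eta * med4@radius)
  expect_equal(pecletNumber(v = vW, medium = med),
               pecletNumber(v = vG, medium = med4), tolerance = 1e-12)
})

test_that("Boltzmann trap energy from concentration enhancement", {
  expect_equal(trapEnergy(1, 1), 0)
  expect_equal(trapEnergy(10, 1), -2.3, tolerance = 0.002)
  expect_equal(trapEnergy(50, 1), -log(50), tolerance = 1e-12)
  expect_equal(round(trapEnergy(50, 1), 1), -3.9)
  expect_true(is.na(trapEnergy(0, 1)))
  expect_error(trapEnergy(-1, 1), "non-negative")
  # equilibrium recovery: the sampled 10x region reads -2.3 kB T
  pos <- generateFixtures("boltzmann-box", seed = 5)
  inside <- mean(abs(pos[, 1]) < 2) / 0.4
  outside <- mean(abs(pos[, 1]) >= 2) / 0.6
  expect_equal(trapEnergy(inside, outside), -log(10), tolerance = 0.1)
})

test_that("flux maps are concentration times velocity", {
  set.seed(6)
  n <- 3000; dt <- 0.005; vz0 <- 4
  r0 <- runif(n, 0, 3); th <- runif(n, 0, 2 * pi); z0 <- runif(n, -3.9, -0.2)
  mk <- function(frame, zz) data.frame(
    particle_id = seq_len(n), frame = frame, t_s = (frame - 1) * dt,
    x_um = r0 * cos(th), y_um = r0 * sin(th), z_um = zz, trapped = FALSE)
  tj <- trajectorySet(rbind(mk(1, z0), mk(2, z0 + vz0 * dt)), dt = dt)
  m <- binConcentration(tj, axis = c(0, 0))
  m <- velocityField(m, tj, nMin = 5)
  m <- fluxMap(m)
  jz <- getMap(m, "jz"); crz <- getMap(m, "crz")
  ok <- is.finite(jz) & crz > 0
  expect_equal(jz[ok] / crz[ok], rep(vz0, sum(ok)), tolerance = 0.02)
  # stationary input: zero flux
  tj0 <- trajectorySet(rbind(mk(1, z0), mk(2, z0)), dt = dt)
  m0 <- fluxMap(velocityField(binConcentration(tj0, axis = c(0, 0)), tj0,
                              nMin = 5))
  expect_equal(max(abs(getMap(m0, "jz")), na.rm = TRUE), 0)
})

test_that("steady funnel flow: flux divergence balances the absorption rate", {
  # deterministic tube flow: particles descend at vz0 inside r < R0, are
  # absorbed below zAbs and re-injected at the top (steady state)
  dt <- 0.005; vz0 <- 8; zAbs <- -3.5; zTop <- -0.5
  set.seed(8)
  n <- 2500
  x <- runif(n, -1, 1); y <- runif(n, -1, 1)
  z <- runif(n, zAbs, zTop)
  rows <- list(); absorbed <- 0
  nFrames <- 40; nextId <- n + 1
  ids <- seq_len(n)
  for (f in seq_len(nFrames)) {
    rows[[f]] <- data.frame(particle_id = ids, frame = f, t_s = (f - 1) * dt,
                            x_um = x, y_um = y, z_um = z, trapped = FALSE)
    z <- z - vz0 * dt
    gone <- z < zAbs
    absorbed <- absorbed + sum(gone)
    # re-injection keeps the column in steady state; new identities
    z[gone] <- z[gone] + (zTop - zAbs)
    ids[gone] <- seq(nextId, length.out = sum(gone))
    nextId <- nextId + sum(gone)
  }
  tj <- trajectorySet(do.call(rbind, rows), dt = dt)
  m <- binConcentration(tj, xBreaks = seq(-1.5, 1.5, 0.5),
                        yBreaks = seq(-1.5, 1.5, 0.5),
                        zBreaks = seq(-3.5, -0.5, 0.5),
                        rBreaks = seq(0, 1.5, 0.25), axis = c(0, 0))
  m <- velocityField(m, tj, nMin = 5)
  m <- fluxMap(m)
  # total downward flux through each depth section (particles/s)
  jz <- getMap(m, "jz")
  area <- pi * (seq(0.25, 1.5, 0.25)^2 - seq(0, 1.25, 0.25)^2)
  through <- colSums(-jz * area, na.rm = TRUE)
  rate <- absorbed / (nFrames * dt)
  expect_lt(max(abs(through - rate)) / rate, 0.05)
})

test_that("Gaussian channel fits and power-law scaling are exact on synthetics", {
  r <- seq(0, 4, by = 0.05)
  J <- 3 * exp(-(r - 2.2)^2 / (2 * 0.4^2))
  fit <- fitGaussianChannels(r, J, nChannels = 1)
  expect_equal(fit$amplitude, 3, tolerance = 1e-6)
  expect_equal(fit$center, 2.2, tolerance = 1e-6)
  expect_equal(fit$width, 0.4, tolerance = 1e-6)

  # two channels resolved and ordered
  J2 <- J + 1.5 * exp(-(r - 0.8)^2 / (2 * 0.3^2))
  fit2 <- fitGaussianChannels(r, J2, nChannels = 2)
  expect_equal(fit2$channel, c("inner", "outer"))
  # windowed single-Gaussian fits carry a small bias where channels overlap
  expect_equal(fit2$center, c(0.8, 2.2), tolerance = 0.05)

  # Jmax proportional to power: exponent exactly 1
  powers <- c(36, 60, 120, 240) * 1e-3
  profs <- lapply(powers, function(P) data.frame(r = r, J = P / 0.036 * J))
  sc <- channelFitAndScaling(profs, powers, nChannels = 1)
  expect_equal(sc$scaling$exponent, 1, tolerance = 1e-6)
})
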