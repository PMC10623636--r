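# Shared fixtures. Focal fields are expensive; compute once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

waterMedium <- function() mediumParticleConfig()

fullApertureConfig <- function(power = 36e-3) {
  opticalTrainConfig(power = power)
}

beamConfig <- function(beamMm) {
  opticalTrainConfig(beamDiameter = beamMm * 1e-3)
}

# coarse full-aperture field reused by force/simulation tests
coarseField36 <- function() cached("coarseField36", {
  computeFocalField(fullApertureConfig(),
                    r = seq(0, 6, by = 0.04), z = seq(-9, 0.5, by = 0.1))
})

coarseForce36 <- function() cached("coarseForce36", {
  rayleighForceField(coarseField36())
})

# straight-line trajectory helper
lineTrajectory <- function(n = 60, dt = 0.005, from = c(0, 0, -4),
                           to = c(0, 0, -0.5), id = 1, sd = 0) {
  s <- seq(0, 1, length.out = n)
  data.frame(particle_id = id, frame = seq_len(n), t_s = (seq_len(n) - 1) * dt,
             x_um = from[1] + s * (to[1] - from[1]) + rnorm(n, sd = sd),
             y_um = from[2] + s * (to[2] - from[2]) + rnorm(n, sd = sd),
             z_um = from[3] + s * (to[3] - from[3]) + rnorm(n, sd = sd),
             trapped = FALSE)
}
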