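---
title: "Models and methods behind trapflow"
author: "trapflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trapflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`trapflow` models the incorporation of dielectric nanoparticles into a
tightly focused optical trap and the multiplane widefield microscopy used to
watch it happen in 3D. The reference system throughout is a 1064 nm
continuous-wave beam focused by an NA 1.20 (60x) water-immersion objective
with a 7 mm back aperture into a suspension of 200 nm polystyrene spheres at
an equilibrium concentration of 5e9 particles/mL (volume fraction 2.1e-5),
imaged at 200 frames/s on eight simultaneous planes spaced by roughly
580 nm (a 50 x 50 x 4 um^3 volume below the focus).

The package covers five stages, each usable on its own:

1. vectorial focal-field calculation (angular spectrum / Debye-Wolf),
2. dipole-approximation optical forces,
3. overdamped Langevin dynamics with optional Oseen hydrodynamic coupling,
4. synthetic multiplane imaging and phasor-based 3D tracking,
5. field reconstruction: concentration, velocity, Stokes force, Peclet
   number, Boltzmann trap energy, flux, channel fits and power-law scaling,
   plus per-trajectory analytics (Savitzky-Golay smoothing, helicoidal
   residuals, incorporation angles, metastable dwells).

# The focused field

The trapping beam is refracted by the objective's reference sphere and
propagated to the focus by the angular spectrum representation. Each
aperture point contributes a plane wave; the incident polarization is
decomposed into s and p components, rotated onto the converging ray, and
weighted by the aplanatic apodization `sqrt(n1/n2) sqrt(cos theta)`. The
focal field is the integral of these plane waves over the aperture solid
angle (`theta` up to `thetaMax = asin(NA_eff / n2)`, `phi` over the full
circle). For the three supported polarizations the azimuthal integral
reduces to three Bessel-type radial integrals, which is the default
evaluation path; direct two-dimensional quadrature over a sampled far field
is retained as an independent cross-check and agrees with the Bessel path
to machine precision (the test suite asserts 1e-6).

Numerical choices:

* Gauss-Legendre quadrature over `theta` (512 nodes by default; the
  10 nm-scale structure of the integrand is spectrally resolved),
* the field is normalized so the power transported through the reference
  sphere equals the configured laser power; with the axial Poynting flux
  expressible through the same radial integrals, conservation of the
  transported power across z planes (to < 1 %) is a nontrivial internal
  check of both the normalization and the vector algebra,
* Fresnel coefficients are unity: the trap is focused deep inside an
  index-matched sample, so no interface stratification is modelled.

## Incident-beam profile

The beam profile at the aperture is not a measurable of this package's
target data, and it matters. We model the expanded TEM00 laser as a
Gaussian whose 1/e^2 intensity diameter equals the beam (iris) diameter
(`apodization = "gaussian"`, `fillingFactor = 1`), truncated at the iris
edge; an ideal flat-top beam is available as an option. The Gaussian
default is the physical description of an expanded laser beam said to
"fill" the aperture, and it is the choice that reproduces the axial
structure reported for this instrument class: with it, the on-axis profile
of the fully open NA 1.20 configuration shows a secondary maximum 1.9 um
below the principal focus at 7.7 % of its intensity — the metastable
trapping position where particles pause during incorporation. A flat-top
beam yields the same maximum at 2.0 um depth but at 4.8 % of the peak,
below the 5 % ripple threshold used by `axialMaxima()`.

## Intensity contours and incorporation angles

`contourHalfAngle()` normalizes each z plane to its own maximum, finds the
outermost radius at which the intensity crosses a 20 % level, and fits a
straight line through (radius, depth) over a depth window (default 1-4 um
below the focus, the experimentally imaged range). With the defaults this
gives 33 degrees for the 7.0 mm beam and 26 degrees at 4.5 mm, close to
the 34 and 19 degrees observed for particle incorporation channels under
those apertures.

A genuine model limitation appears for strongly underfilled apertures: a
diffraction-limited NA_eff 0.51 (3.0 mm) beam has a focal Rayleigh range of
about 4 um, so within the imaged 4 um its 20 % contour expands at only
about 2 degrees — the 14 degree channel angle observed experimentally for
that condition cannot be produced by the stated optics in that depth
window (it would require the developed far-cone, tens of um below focus,
or aberrations beyond this model). The package reports the number its
physics gives.

# Optical forces and particle dynamics

Forces use the dipole (Rayleigh) approximation for a 100 nm-radius sphere
(n = 1.59) in water: a gradient force `(1/4) Re(alpha) grad |E|^2` with the
Clausius-Mossotti polarizability, and a scattering force
`(n_m / c) sigma_s S_z` along the propagation axis with
`sigma_s = (8 pi / 3) k^4 a^2`. Both scale linearly with laser power, so a
power sweep reuses one field solution (`scaleForceField()`). At 36 mW the
peak force is ~1.3 pN, consistent with the piconewton forces inferred from
Stokes drag on measured velocities in such traps.

The generator integrates overdamped Langevin dynamics (Euler-Maruyama,
50 us steps; the step is two orders of magnitude below `R^2 / 50 D`) with
reflecting walls. Particles reaching 150 nm from the focus are held as
trapped; a held particle sits at force equilibrium and therefore exerts no
net stokeslet on the fluid, so it drops out of the hydrodynamic coupling.
Optional pairwise Oseen coupling adds `sum_j T(r_ij) F_j` to each drift,
with the 1/r tensor regularized at particle contact. Gravity and
inter-particle collisions are neglected (200 nm polystyrene in water
sediments far slower than it diffuses; the suspension is dilute).

Boltzmann sampling (`equilibriumSampler()`) provides equilibrium ensembles
for validating the trap-energy reconstruction; the dynamics themselves
reproduce Boltzmann statistics in conservative fields (a
Kolmogorov-Smirnov check in the tests).

# Synthetic imaging and tracking

The renderer is a widefield Gaussian-defocus forward model: each particle
appears in every plane as a pixel-integrated Gaussian whose width follows
`sigma(z) = sigma0 sqrt(1 + (z/zR)^2)` (`sigma0` = 110 nm, `zR` = 0.5 um,
matching NA 1.2 detection at ~515 nm), with the collected photons split
equally among the eight planes, Poisson photon noise and 1 e- read noise.
The default photon budget is 20000 detected photons per particle per
frame: 200 nm dye-loaded spheres are very bright emitters, and this budget
places the tracking precision (about 3 nm lateral, 14 nm axial in the
Monte-Carlo tests) at the favourable end of the 10-15 nm / 27 nm
instrument-class precision, which in real data is limited by calibration
and registration rather than photons.

Localization is phasor-based: detection on the plane-summed image (local
maxima with a local-background prominence criterion), sub-pixel x-y from
the phase of the first Fourier coefficients of the sharpest plane's ROI,
and z from a free-width Lorentzian fit of the per-plane peak amplitudes
against the calibrated plane positions — the analytic inverse of the
defocus model. Plane positions are calibrated exactly as in the
experiments: an axial scan of immobilized beads, with the image-gradient
sharpness curve of each plane fitted by a Gaussian peak. Linking is greedy
nearest-neighbour with a displacement gate, two-frame gap closing, and a
conservative ambiguity rule (two candidates within 10 % cost break the
track rather than risk a swap).

What the synthetic data do not emulate: aberrations and field-dependent
PSFs, inter-plane registration errors, camera fixed-pattern noise, and
emitter blinking/bleaching. Passing round-trip tests therefore demonstrate
the correctness of the algorithms, not the full error budget of a real
instrument.

# Field reconstruction

Concentration maps are occupancy counts per voxel per frame (0.25 um
lateral bins, 0.58 um axial bins — one imaging plane per bin). The beam
axis is estimated from the occupancy centroid near the focal plane.
Velocities use single-frame forward differences assigned to the step
mid-point bin; per-bin vector means (not mean speeds) feed the Stokes
force `F = 6 pi eta R v`, which removes the upward Brownian bias of |v|.
Bins with fewer than 10 steps are masked, and bins whose displacement per
frame exceeds the bin size are flagged `underSampled` — there the velocity
(hence force) is systematically underestimated, the same caveat that
applies to the experimental estimates near the focus at high power.

The Peclet number is computed both as `v R / D` and `F R / kB T`; the two
are algebraically identical and the identity (and its corollary, viscosity
independence at fixed force) is asserted in the tests. The trap free
energy is `U = -ln(c / c_eq)` in kB T; a 10-fold enhancement reads
-2.3 kB T, a 50-fold one -3.9 kB T. Fluxes are `j = c v` per bin;
per-depth radial profiles are decomposed into inner/outer Gaussian
channels and the per-channel peak flux is regressed on laser power on
log-log axes.

## Flux scaling with power: what the model can and cannot show

With pairwise Oseen coupling and positions held fixed, the particle flux
is rigorously linear in laser power: both the direct drift and every
induced flow scale with P. Deviations from linearity can only come from
the redistribution of particles over the measurement window. The package
measures the channel flux as the volume-integrated axial transport in the
cone region, baseline-paired against a force-free run with identical
noise: in the uniform-concentration transient this yields a power-law
exponent of 1.00 (+-0.02 across seeds) without hydrodynamics, validating
the linear baseline. Over developed windows the closed-box model shows
accumulation-driven superlinearity *without* coupling and collective
flushing *with* coupling — and at the path volume fraction (2e-4), which
pins the simulable particle number, the channel drift at 36 mW lies below
the Brownian noise floor. The experimentally reported mild superlinearity
(J ~ P^1.15) arises from steady-state collective opto-hydrodynamics that a
dilute point-force model in a closed box does not reproduce; the
corresponding check is retained in the test suite and fails honestly.

# Trajectory analytics

Smoothing is third-order Savitzky-Golay (default window 11 frames, 55 ms);
the residuals between the tracked and smoothed trajectory carry the
helicoidal signature: sinusoidal x and y residuals dephased by 90 degrees.
The dominant frequency and the x-y phase come from the cross-spectrum; the
handedness from the sign of the mean cross-product of the residuals. A
handedness is only reported when the fitted oscillation amplitude exceeds
the residual noise two-fold — on pure Brownian trajectories fewer than
10 % of records pass this gate, mirroring the experimental observation
that about half of the events are indistinguishable from Brownian
fluctuations.

Metastable dwells are maximal intervals of sub-threshold smoothed speed
more than 1 um below the focus (default threshold: twice the free-Brownian
RMS frame displacement over the frame interval; gaps under 2 frames are
merged). In simulations at 240 mW the sustained (>= 25 ms) dwell events
cluster at the depth of the field's secondary axial maximum, connecting
the observed pauses to the computed beam structure. The reported dwell
durations are limited below by the 5 ms frame interval.

Incorporation angles from data follow the same logic as the intensity
contour: the Gaussian-fitted centre of the outermost concentration channel
per depth section, regressed on depth.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run on reduced problem sizes
chosen to keep the full suite in a few minutes on one core: coarse
(40 nm/100 nm) field grids, hundreds to tens of thousands of particles,
tens of milliseconds of simulated time, and 32-128 px synthetic frames.
All stochastic stages take explicit seeds and are bit-reproducible;
`runPipeline()` fans a global seed out to per-stage seeds and writes a
manifest with configuration and output checksums so a rerun can be
verified byte-for-byte.

# Known limitations

* Dipole-order forces only (no Mie/T-matrix corrections; the 200 nm
  spheres are at the edge of the Rayleigh regime, so absolute force
  magnitudes are order-of-magnitude).
* No stratified-medium (coverslip) aberrations; the trap is assumed deep
  in the sample.
* Oseen (point-force) hydrodynamics without lubrication or walls; trapped
  particles are idealized as force-free holds.
* No thermal (Marangoni/convection) effects.
* The 3.0 mm-aperture incorporation angle and the steady-state superlinear
  flux scaling are outside what this model reproduces, as discussed above.
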