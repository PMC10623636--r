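## Physical constants (SI)
.kB    <- 1.380649e-23      # Boltzmann constant, J/K
.c0    <- 299792458         # speed of light in vacuum, m/s
.eps0  <- 8.8541878128e-12  # vacuum permittivity, F/m
.Z0    <- 376.730313668     # vacuum impedance, Ohm

## Unit helpers. Internal computations are SI; trajectory tables and image
## grids are expressed in micrometres (um) and seconds.
.um <- 1e-6
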