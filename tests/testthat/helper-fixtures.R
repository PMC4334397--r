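# Shared fixtures: all built in code at test time.

# The worked-example eRIC load used throughout (obstructive-like values).
example_truth <- function() eric_params(R = 1.5, Rp = 3.0, I = 0.008, C = 0.01)

default_grid <- function() seq(2, 32, by = 2)

# A profile that pins the truth at given element values and disables
# breathing and measurement noise: the noiseless study condition.
quiet_profile <- function(R = 1.5, Rp = 3.0, I = 0.008, C = 0.01,
                          amplitude = 1) {
  subject_profile(
    "quiet",
    param_law = list(R = list(median = R, sdlog = 0),
                     Rp = list(median = Rp, sdlog = 0),
                     I = list(median = I, sdlog = 0),
                     C = list(median = C, sdlog = 0)),
    excitation_amplitude = amplitude,
    breathing_flow_amplitude = 0,
    pressure_noise_sd = 0, flow_noise_sd = 0)
}

# Independent oracle for the eRIC forward model: separate real/imaginary
# closed forms (a different algebraic route than complex division).
oracle_eric_z <- function(p, f) {
  w <- 2 * pi * f
  den <- 1 + (w * p$Rp * p$C)^2
  complex(real = p$R + p$Rp / den,
          imaginary = w * p$I - w * p$Rp^2 * p$C / den)
}

random_eric_params <- function() {
  eric_params(R = runif(1, 0.5, 5), Rp = runif(1, 0.5, 6),
              I = runif(1, 0.002, 0.02), C = runif(1, 0.003, 0.05))
}

# Analytic spectrum plus additive complex Gaussian noise (sd per quadrature
# component), coherence left at 1.
noisy_spectrum <- function(truth, sd = 0.05, grid = default_grid()) {
  z <- eric_impedance(truth, grid)$values
  impedance_spectrum(grid, z + complex(real = rnorm(length(grid), 0, sd),
                                       imaginary = rnorm(length(grid), 0, sd)))
}
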