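# Independent brute-force oracles and fixture builders used across tests.

# Per-band loop oracle for the three-point weighted mean (endpoints copied).
oracle_smooth <- function(v) {
  out <- v
  for (i in seq_along(v)) {
    if (i > 1 && i < length(v)) {
      out[i] <- 0.5 * v[i] + 0.25 * v[i + 1] + 0.25 * v[i - 1]
    }
  }
  out
}

# Per-band loop oracle for the band-window first derivative (literal form).
oracle_derivative <- function(v, delta_lambda = 1.8) {
  n <- length(v)
  out <- numeric(0)
  for (i in seq_len(n)) {
    if (i >= 4 && i <= n - 3) {
      fwd <- v[i + 1] + v[i + 2] + v[i + 3]
      bwd <- v[i - 1] + v[i - 2] + v[i - 3]
      out <- c(out, ((fwd - bwd) / 3) / delta_lambda)
    }
  }
  out
}

# Uniform 1.8 nm instrument-like grid.
uniform_grid <- function(n = 258L, from = 325.8, by = 1.8) {
  seq(from, by = by, length.out = n)
}

# Noiseless logistic-red-edge spectrum as a leaf_spectrum.
logistic_spectrum <- function(lambda0, grid = uniform_grid(),
                              slope_s = 5, meta = list()) {
  p <- leaf_optics_params(chl_total = 15, noise_sd = 0,
                          lambda0 = lambda0, slope_s = slope_s)
  generate_leaf_spectrum(p, grid, seed = 1, meta = meta)
}

# Random plausible reflectance spectrum in [0, 1].
random_spectrum <- function(n = 258L) {
  stats::runif(n, 0.02, 0.6)
}
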