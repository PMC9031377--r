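# Shared fixtures and independent oracles.  Everything is generated in
# code; no stored data.

# Asymmetric reference model oriented so that RL(fmin) < RL(fmax) holds
# without mirroring (the peak sits right of the orientation flip point).
right_model <- function(ftrue = 2.6e9) {
  synthetic_model(ftrue = ftrue, amplitude = 18, offset = 2,
                  sigma_left = 0.07e9, sigma_right = 0.10e9,
                  band = c(2e9, 3e9))
}

# Symmetric Gaussian model: the debiased curve is even about ftrue, so the
# transformed signal is an exact cisoid times a real envelope and its
# phase over the main lobe is exactly 2*pi*ftrue*t (shift theorem).
sym_model <- function(ftrue = 2.47e9, sigma = 0.08e9) {
  synthetic_model(ftrue = ftrue, amplitude = 18, offset = 2,
                  sigma_left = sigma, sigma_right = sigma,
                  band = c(2e9, 3e9))
}

# Direct O(n*m) reference DTFT sum on arbitrary grids — the oracle for the
# compiled rotator kernel and the Bluestein path.
ref_dtft <- function(x, grid_in, grid_out, sign, scale = 1) {
  scale * as.vector(exp(1i * sign * 2 * pi * outer(grid_out, grid_in)) %*%
                      as.complex(x))
}

# Full width at half maximum by linear interpolation of the two half-max
# crossings; falls back to the grid extent when a flank never crosses.
fwhm <- function(x, y) {
  half <- max(y) / 2
  p <- which.max(y)
  left <- x[1L]
  for (i in seq(p, 2L)) {
    if (y[i - 1L] <= half) {
      left <- x[i - 1L] + (x[i] - x[i - 1L]) *
        (half - y[i - 1L]) / (y[i] - y[i - 1L])
      break
    }
  }
  right <- x[length(x)]
  for (i in seq(p, length(x) - 1L)) {
    if (y[i + 1L] <= half) {
      right <- x[i] + (x[i + 1L] - x[i]) *
        (half - y[i]) / (y[i + 1L] - y[i])
      break
    }
  }
  right - left
}

# Least-squares slope of the unwrapped phase over the beta support.
support_phase_slope <- function(signal, support) {
  idx <- support$idx[1L]:support$idx[2L]
  unname(coef(lm(signal$phase_unwrapped[idx] ~ signal$times[idx]))[2L])
}
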