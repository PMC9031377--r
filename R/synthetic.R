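#' Asymmetric-Gaussian synthetic resonance model
#'
#' Parametrises a single-resonance return-loss curve built from two
#' half-Gaussians with a common peak: for \eqn{f \le f_{true}} the width is
#' `sigma_left`, for \eqn{f \ge f_{true}} it is `sigma_right`, so the lobe is
#' asymmetric the way measured sensor responses are.  A constant offset is
#' added to emulate the off-resonance return-loss floor.  The defaults are
#' the reference configuration used throughout the benchmarking experiments:
#' amplitude 18 dB, offset 2 dB, widths 0.07 and 0.10 GHz, band 2-3 GHz.
#'
#' @param ftrue Resonance frequency (point of maximum) in Hz.
#' @param amplitude Peak amplitude above the offset, dB, positive.
#' @param offset Additive floor, dB.
#' @param sigma_left,sigma_right Gaussian widths in Hz for the low- and
#'   high-frequency flanks, positive.
#' @param band Numeric length-2, observation band `c(fmin, fmax)` in Hz.
#' @return An object of class `synthetic_model`.
#' @seealso [synth_return_loss()]
#' @export
synthetic_model <- function(ftrue = 2.25e9,
                            amplitude = 18,
                            offset = 2,
                            sigma_left = 0.07e9,
                            sigma_right = 0.10e9,
                            band = c(2e9, 3e9)) {
  if (length(band) != 2L || band[1L] >= band[2L])
    stop("band must be c(fmin, fmax) with fmin < fmax")
  if (!(ftrue > band[1L] && ftrue < band[2L]))
    stop("invalid model: ftrue (", ftrue, " Hz) must lie strictly inside ",
         "the band [", band[1L], ", ", band[2L], "] Hz")
  if (sigma_left <= 0 || sigma_right <= 0)
    stop("invalid model: sigma_left and sigma_right must be positive")
  if (amplitude <= 0)
    stop("invalid model: amplitude must be positive")
  structure(
    list(ftrue = ftrue, amplitude = amplitude, offset = offset,
         sigma_left = sigma_left, sigma_right = sigma_right,
         band = c(fmin = band[1L], fmax = band[2L])),
    class = "synthetic_model")
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf(
    "<synthetic_model> ftrue %.6g GHz, peak %.3g dB (amp %.3g + offset %.3g)\n",
    x$ftrue / 1e9, x$amplitude + x$offset, x$amplitude, x$offset))
  cat(sprintf("  sigma left/right %.3g / %.3g GHz, band [%.3g, %.3g] GHz\n",
              x$sigma_left / 1e9, x$sigma_right / 1e9,
              x$band[1L] / 1e9, x$band[2L] / 1e9))
  invisible(x)
}

# Model curve evaluated at arbitrary frequencies (Hz).
eval_synthetic <- function(model, f) {
  sigma <- ifelse(f <= model$ftrue, model$sigma_left, model$sigma_right)
  model$amplitude * exp(-(f - model$ftrue)^2 / (2 * sigma^2)) + model$offset
}

#' Generate a synthetic return-loss trace
#'
#' Samples the asymmetric-Gaussian model on a uniform grid of `Nf` points
#' covering the model band.  The curve is continuous at the peak, where it
#' takes the value `amplitude + offset`.
#'
#' @param model A [synthetic_model()].
#' @param Nf Number of frequency samples, at least 3.
#' @return A uniform [return_loss_trace()].
#' @examples
#' tr <- synth_return_loss(synthetic_model(), Nf = 101)
#' max(tr$values)  # 20 dB at the sample nearest 2.25 GHz
#' @export
synth_return_loss <- function(model, Nf = 101L) {
  if (!inherits(model, "synthetic_model"))
    stop("model must be a synthetic_model object")
  Nf <- as.integer(Nf)
  if (Nf < 3L) stop("Nf must be at least 3")
  f <- seq(model$band[1L], model$band[2L], length.out = Nf)
  return_loss_trace(f, eval_synthetic(model, f))
}

#' Acquisition noise model
#'
#' Describes `M` repeated instrument sweeps, each perturbed by additive
#' i.i.d. zero-mean Gaussian noise of standard deviation `sigma_noise` dB
#' per sample.  Averaging the sweeps is the first preprocessing step and
#' reduces the noise standard deviation by \eqn{1/\sqrt{M}}.  The Gaussian
#' law is a modelling choice: the only requirement placed on the instrument
#' noise is that sweep averaging yields a smooth curve.
#'
#' @param sigma_noise Per-sweep noise standard deviation in dB, >= 0.
#' @param M Number of sweeps to average, integer >= 1.
#' @param seed Optional integer seed making the simulated sweeps
#'   reproducible without disturbing the caller's RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_noise = 0.5, M = 16L, seed = NULL) {
  if (sigma_noise < 0) stop("sigma_noise must be non-negative")
  M <- as.integer(M)
  if (M < 1L) stop("M must be at least 1")
  structure(list(sigma_noise = sigma_noise, M = M, seed = seed),
            class = "noise_model")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  NULL seed runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate repeated noisy acquisitions of a trace
#'
#' Returns `M` copies of the input trace, each with independent additive
#' Gaussian perturbations per the noise model.  With `sigma_noise = 0` all
#' copies equal the input.  Given the same seed the output is bit-identical
#' across calls.
#'
#' @param trace A [return_loss_trace()] (the noiseless truth).
#' @param noise A [noise_model()].
#' @return A list of `M` [return_loss_trace()] objects.
#' @seealso [average_traces()]
#' @export
simulate_acquisitions <- function(trace, noise) {
  stopifnot_trace(trace)
  if (!inherits(noise, "noise_model"))
    stop("noise must be a noise_model object")
  n <- length(trace$frequencies)
  with_seed(noise$seed, {
    lapply(seq_len(noise$M), function(i) {
      v <- trace$values
      if (noise$sigma_noise > 0)
        v <- v + rnorm(n, sd = noise$sigma_noise)
      return_loss_trace(trace$frequencies, v)
    })
  })
}
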