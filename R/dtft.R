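#' Discrete-time Fourier sum between uniform grids
#'
#' Evaluates \eqn{y(f_m) = s \sum_k x_k \exp(\mathrm{sign} \cdot j 2\pi f_m
#' t_k)} for every output point \eqn{f_m}.  Both grids must be uniform; the
#' heavy double loop runs in compiled code with a complex-rotator
#' recurrence.  This is the primitive behind the forward and inverse
#' transforms of all three sharpening algorithms: explicit sums keep the
#' output grid density independent of the input sample count (unlike an
#' FFT, which would couple them).
#'
#' @param x Complex (or numeric) input samples.
#' @param grid_in Uniform grid the samples live on (seconds or Hz).
#' @param grid_out Uniform grid to evaluate on (Hz or seconds).
#' @param sign `+1` for the inverse/synthesis convention
#'   \eqn{e^{+j2\pi tf}}, `-1` for the forward convention.
#' @param scale Quadrature scale factor applied to the sum (for instance
#'   the input grid step); it never affects argmax locations.
#' @return Complex vector, one value per `grid_out` point.
#' @keywords internal
dtft_sum <- function(x, grid_in, grid_out, sign, scale = 1) {
  n <- length(grid_in)
  nout <- length(grid_out)
  if (length(x) != n) stop("length(x) must match length(grid_in)")
  if (n < 1L || nout < 1L) stop("empty grid")
  din <- uniform_step(grid_in, "grid_in")
  dout <- if (nout > 1L) uniform_step(grid_out, "grid_out") else 0
  # Small products go through the direct compiled kernel; large ones
  # through the Bluestein chirp-Z factorisation (both exact DTFT sums,
  # cross-checked in the test suite).
  if (as.double(n) * nout <= 2^18 || n < 2L || nout < 2L) {
    cpp_dtft_uniform(as.complex(x), grid_in[1L], din, n,
                     grid_out[1L], dout, nout,
                     as.numeric(sign), as.numeric(scale))
  } else {
    bluestein_dtft(as.complex(x), grid_in[1L], din,
                   grid_out[1L], dout, nout,
                   as.numeric(sign), as.numeric(scale))
  }
}

# Chirp-Z evaluation of the same sum, O((n + nout) log) via three FFTs.
# With mk = (m^2 + k^2 - (m-k)^2) / 2 the kernel exp(i*w*m*k) factors into
# quadratic-phase chirps and a linear convolution, computed circularly on
# a power-of-two length with enough zero padding to avoid wrap-around.
bluestein_dtft <- function(x, t0, dt, f0, df, nout, sign, scale = 1) {
  n <- length(x)
  w <- sign * 2 * pi * df * dt
  k <- 0:(n - 1L)
  m <- 0:(nout - 1L)
  a <- x * exp(1i * (sign * 2 * pi * f0 * dt * k + w * k^2 / 2))
  L <- stats::nextn(n + nout - 1L, 2)
  b <- complex(L)
  b[1:nout] <- exp(-1i * w * m^2 / 2)
  if (n > 1L)
    b[L - (1:(n - 1L)) + 1L] <- exp(-1i * w * ((1:(n - 1L))^2) / 2)
  conv <- stats::fft(stats::fft(c(a, complex(L - n))) * stats::fft(b),
                     inverse = TRUE) / L
  scale * conv[1:nout] *
    exp(1i * (sign * 2 * pi * (f0 + m * df) * t0 + w * m^2 / 2))
}

# Direct reference evaluation (arbitrary grids, O(n * nout)); retained as
# the independent oracle for the fast paths.
dtft_sum_ref <- function(x, grid_in, grid_out, sign, scale = 1) {
  scale * as.vector(exp(1i * sign * 2 * pi * outer(grid_out, grid_in)) %*%
                      as.complex(x))
}

# Nominal step of a uniform grid; errors when spacing is non-uniform.
uniform_step <- function(g, what = "grid") {
  n <- length(g)
  if (n < 2L) return(0)
  d <- (g[n] - g[1L]) / (n - 1L)
  if (max(abs(diff(g) - d)) > 1e-9 * abs(d))
    stop(what, " must be uniformly spaced")
  d
}

#' Complex time signal with unwrapped phase
#'
#' Container for the inverse-transformed return loss \eqn{rl(t)} on a
#' symmetric uniform time grid.  Holds the complex samples together with
#' their magnitude and unwrapped phase (continuous, no jumps of \eqn{\ge
#' \pi} between adjacent samples).
#'
#' @param times Uniform, strictly increasing time grid in seconds.
#' @param values Complex samples, same length.
#' @return An object of class `time_signal` with fields `times`, `values`,
#'   `magnitude`, `phase_unwrapped`, `step` (\eqn{\Delta t}).
#' @export
time_signal <- function(times, values) {
  times <- as.numeric(times)
  if (length(values) != length(times))
    stop("times and values differ in length")
  step <- uniform_step(times, "times")
  values <- as.complex(values)
  structure(
    list(times = times, values = values,
         magnitude = Mod(values),
         phase_unwrapped = unwrap(Arg(values)),
         step = step),
    class = "time_signal")
}

#' @export
print.time_signal <- function(x, ...) {
  cat(sprintf("<time_signal> Nt = %d on [%.4g, %.4g] ns\n",
              length(x$times), x$times[1L] * 1e9,
              x$times[length(x$times)] * 1e9))
  invisible(x)
}

# Unwrap a phase sequence: add multiples of 2*pi so adjacent differences
# stay in (-pi, pi].
unwrap <- function(phase) {
  if (length(phase) < 2L) return(phase)
  d <- diff(phase)
  jumps <- -round(d / (2 * pi))
  phase + c(0, cumsum(jumps)) * 2 * pi
}

#' Unwrap the phase of a time signal
#'
#' Recomputes the continuous phase from the principal-value phase of the
#' complex samples.  The result differs from the principal value by integer
#' multiples of \eqn{2\pi} per sample and has no adjacent jump of
#' \eqn{\pi} or more.  On the magnitude main lobe of the transformed return
#' loss this phase is almost linear, with slope \eqn{2\pi} times the
#' resonance frequency.
#'
#' @param signal A [time_signal()].
#' @return The signal with `phase_unwrapped` refreshed.
#' @export
unwrap_phase <- function(signal) {
  if (!inherits(signal, "time_signal"))
    stop("signal must be a time_signal object")
  signal$phase_unwrapped <- unwrap(Arg(signal$values))
  signal
}

#' Inverse discrete-time Fourier transform of a debiased trace
#'
#' Computes \eqn{rl(t_k) = \Delta f \sum_n |\bar{RL}(f_n)| e^{+j 2\pi t_k
#' f_n}} on `Nt` uniform time points spanning the closed window
#' \eqn{[-0.5/\Delta f, +0.5/\Delta f]}, the period of the inverse DTFT of
#' a signal sampled with frequency step \eqn{\Delta f}.  The magnitude of
#' the debiased return loss is taken so that small negative values caused
#' by noise cannot flip the sign.  `Nt` is free: the transform is pointwise
#' in `t`, so refining the time grid never changes shared samples.
#'
#' @param trace_bar A uniform [return_loss_trace()], normally the output of
#'   [flatten_and_debias()].
#' @param Nt Number of time samples, at least 8.
#' @return A [time_signal()].
#' @export
idtft <- function(trace_bar, Nt = 512L) {
  stopifnot_trace(trace_bar, "trace_bar")
  if (!trace_bar$uniform)
    stop("idtft requires a uniformly sampled trace")
  Nt <- as.integer(Nt)
  if (Nt < 8L) stop("Nt must be at least 8")
  tmax <- 0.5 / trace_bar$step
  times <- seq(-tmax, tmax, length.out = Nt)
  vals <- dtft_sum(abs(trace_bar$values), trace_bar$frequencies, times,
                   sign = +1, scale = trace_bar$step)
  time_signal(times, vals)
}
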