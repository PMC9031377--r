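#' Return-loss trace
#'
#' Container for a sampled return-loss curve \eqn{RL(f)} in dB on a strictly
#' increasing frequency grid.  All frequencies are stored in Hz.  A trace is
#' flagged `uniform` when consecutive grid spacings agree with the nominal
#' step \eqn{\Delta f = (f_{MAX}-f_{min})/(N_f-1)} to a relative tolerance of
#' 1e-9; all sharpening algorithms require a uniform trace.
#'
#' @param frequencies Numeric vector of frequencies in Hz, strictly
#'   increasing, length at least 3.
#' @param values Numeric vector of return-loss values in dB, same length.
#' @return An object of class `return_loss_trace` with fields
#'   `frequencies`, `values`, `band` (`c(fmin, fmax)` in Hz), `uniform`
#'   (logical) and `step` (\eqn{\Delta f} in Hz, `NA` when non-uniform).
#' @examples
#' tr <- return_loss_trace(seq(2e9, 3e9, length.out = 101),
#'                         rnorm(101, mean = 5))
#' tr$step  # 10 MHz
#' @export
return_loss_trace <- function(frequencies, values) {
  frequencies <- as.numeric(frequencies)
  values <- as.numeric(values)
  n <- length(frequencies)
  if (n < 3L)
    stop("a return-loss trace needs at least 3 samples, got ", n)
  if (length(values) != n)
    stop("frequencies and values differ in length (", n, " vs ",
         length(values), ")")
  if (anyNA(frequencies) || anyNA(values))
    stop("frequencies and values must be finite and non-missing")
  d <- diff(frequencies)
  if (any(d <= 0))
    stop("frequencies must be strictly increasing (violated at index ",
         which(d <= 0)[1L] + 1L, ")")
  step <- (frequencies[n] - frequencies[1L]) / (n - 1L)
  uniform <- max(abs(d - step)) <= 1e-9 * step
  structure(
    list(frequencies = frequencies,
         values = values,
         band = c(fmin = frequencies[1L], fmax = frequencies[n]),
         uniform = uniform,
         step = if (uniform) step else NA_real_),
    class = "return_loss_trace")
}

#' @export
print.return_loss_trace <- function(x, ...) {
  cat(sprintf(
    "<return_loss_trace> Nf = %d, band [%.6g, %.6g] GHz, %s\n",
    length(x$frequencies), x$band[1L] / 1e9, x$band[2L] / 1e9,
    if (x$uniform) sprintf("uniform step %.6g MHz", x$step / 1e6)
    else "non-uniform"))
  cat(sprintf("  RL range [%.4g, %.4g] dB, peak at %.6g GHz\n",
              min(x$values), max(x$values),
              x$frequencies[which.max(x$values)] / 1e9))
  invisible(x)
}

#' @export
length.return_loss_trace <- function(x) length(x$frequencies)

is_return_loss_trace <- function(x) inherits(x, "return_loss_trace")

stopifnot_trace <- function(x, arg = "trace") {
  if (!is_return_loss_trace(x))
    stop(arg, " must be a return_loss_trace object")
  invisible(x)
}

#' Return loss from reflection-coefficient magnitude
#'
#' Converts the magnitude of a one-port reflection coefficient
#' \eqn{|\Gamma(f)|} to return loss \eqn{RL(f) = -20 \log_{10} |\Gamma(f)|}
#' in dB.  Total reflection (\eqn{|\Gamma| = 1}) maps to 0 dB.
#'
#' @param gamma_magnitude Numeric vector of reflection-coefficient
#'   magnitudes, each in (0, 1].
#' @param frequencies Frequencies in Hz, strictly increasing, same length.
#' @return A [return_loss_trace()].
#' @examples
#' rl_from_gamma(c(0.5, 0.25, 0.5), c(2e9, 2.5e9, 3e9))$values
#' @export
rl_from_gamma <- function(gamma_magnitude, frequencies) {
  gamma_magnitude <- as.numeric(gamma_magnitude)
  bad <- which(!is.finite(gamma_magnitude) | gamma_magnitude <= 0)
  if (length(bad))
    stop("reflection-coefficient magnitude must be positive; offending ",
         "index ", bad[1L], " (value ", gamma_magnitude[bad[1L]], ")")
  if (any(gamma_magnitude > 1))
    warning(sum(gamma_magnitude > 1),
            " magnitude value(s) exceed 1 (passive one-port expected)")
  return_loss_trace(frequencies, -20 * log10(gamma_magnitude))
}

# Reflect a trace about the band centre, f -> fmin + fmax - f.  Used to
# impose the standing assumption RL(fmin) < RL(fmax) before preprocessing;
# the estimate is reflected back afterwards.
mirror_trace <- function(trace) {
  f <- trace$band[1L] + trace$band[2L] - rev(trace$frequencies)
  return_loss_trace(f, rev(trace$values))
}

mirror_frequency <- function(f, band) unname(band[1L] + band[2L] - f)
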