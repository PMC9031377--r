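#' Average repeated return-loss acquisitions
#'
#' Pointwise arithmetic mean of several sweeps taken on an identical
#' frequency grid.  This is the first preprocessing step and acts as the
#' noise filter: averaging `M` sweeps reduces the per-sample noise standard
#' deviation by \eqn{1/\sqrt{M}} without touching the underlying curve.
#'
#' @param traces A list of [return_loss_trace()] objects sharing one grid.
#' @return A single [return_loss_trace()].
#' @export
average_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L)
    stop("traces must be a non-empty list of return_loss_trace objects")
  lapply(traces, stopifnot_trace)
  f0 <- traces[[1L]]$frequencies
  for (i in seq_along(traces)) {
    fi <- traces[[i]]$frequencies
    if (length(fi) != length(f0) || any(fi != f0))
      stop("incompatible traces: frequency grid of trace ", i,
           " differs from trace 1")
  }
  vals <- rowMeans(vapply(traces, function(tr) tr$values,
                          numeric(length(f0))))
  return_loss_trace(f0, vals)
}

#' Flatten the left endpoint and remove the baseline
#'
#' Implements the endpoint-removal steps of the shared preprocessing chain.
#' The curve is assumed to satisfy the standing orientation
#' \eqn{RL(f_{min}) < RL(f_{MAX})} (callers with the opposite orientation
#' mirror the trace first; [estimate()] does this automatically).  The
#' frequency \eqn{\tilde f} left of the peak where the curve crosses the
#' level \eqn{RL(f_{MAX})} is located (nearest grid sample walking outward
#' from the peak, no interpolation), the values on
#' \eqn{[f_{min}, \tilde f]} are replaced by that level, and
#' \eqn{RL(f_{MAX})} is subtracted everywhere.  The result is
#' non-negative-at-the-ends with value exactly 0 at both band endpoints, so
#' the subsequent Fourier transform is free of endpoint discontinuities.
#'
#' @param trace A [return_loss_trace()] with `RL(fmin) < RL(fmax)`.
#' @return The debiased trace \eqn{\bar{RL}(f)}; attribute `f_tilde` holds
#'   the flattening frequency in Hz.
#' @export
flatten_and_debias <- function(trace) {
  stopifnot_trace(trace)
  v <- trace$values
  n <- length(v)
  level <- v[n]
  peak <- which.max(v)  # ties broken by lowest index
  # walk outward (leftward) from the peak to the first sample at or below
  # the right-endpoint level
  i_tilde <- NA_integer_
  for (i in seq(peak, 1L)) {
    if (v[i] <= level) { i_tilde <- i; break }
  }
  if (is.na(i_tilde))
    stop("precondition violated: the curve never drops to RL(fmax) left ",
         "of the peak (RL(fmin) = ", signif(v[1L], 6), " dB > RL(fmax) = ",
         signif(level, 6), " dB); mirror the trace about the band centre ",
         "and mirror the estimate back")
  out <- v
  out[seq_len(i_tilde)] <- level
  out <- out - level
  res <- return_loss_trace(trace$frequencies, out)
  attr(res, "f_tilde") <- trace$frequencies[i_tilde]
  res
}

#' Alpha band: frequency interval retained around the peak
#'
#' Identifies the band \eqn{[\tilde f_{min}, \tilde f_{MAX}]} where the
#' debiased return loss, normalised by its maximum, is at least `alpha`.
#' Crossings are resolved to the nearest grid sample (the innermost sample
#' on each side whose normalised value reaches `alpha`); on the coarse
#' acquisition grid the boundary samples only approximately attain the
#' level.  The sharpened response and the MUSIC pseudospectrum are later
#' evaluated on a dense grid inside this band.
#'
#' @param trace_bar Output of [flatten_and_debias()].
#' @param alpha Threshold in (0, 1).
#' @return An object of class `alpha_band` with fields `f_tilde_min`,
#'   `f_tilde_max` (Hz) and `alpha`.
#' @export
alpha_band <- function(trace_bar, alpha) {
  stopifnot_trace(trace_bar, "trace_bar")
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie strictly between 0 and 1")
  v <- trace_bar$values
  m <- max(v)
  if (m <= 0) stop("degenerate trace: non-positive maximum after debias")
  rel <- v / m
  peak <- which.max(v)  # ties broken by lowest index
  n <- length(v)
  # walk outward from the peak; the boundary on each side is the first
  # sample at or below the threshold (after debias the endpoint values are
  # exactly 0 < alpha, so a crossing always exists)
  lo <- 1L
  for (i in seq(peak, 1L)) if (rel[i] <= alpha) { lo <- i; break }
  hi <- n
  for (i in seq(peak, n)) if (rel[i] <= alpha) { hi <- i; break }
  structure(
    list(f_tilde_min = trace_bar$frequencies[lo],
         f_tilde_max = trace_bar$frequencies[hi],
         alpha = alpha,
         idx = c(lo, hi)),
    class = "alpha_band")
}

#' Beta support: time interval retained around the magnitude peak
#'
#' Identifies \eqn{[\tilde t_{min}, \tilde t_{MAX}]}, the interval outside
#' which the normalised magnitude \eqn{|rl(t)|/\max|rl(t)|} has dropped to
#' `beta`.  Walking outward from the magnitude peak, the boundary on each
#' side is the first sample whose normalised magnitude is at or below
#' `beta`; when the magnitude never drops to `beta` on a side, the support
#' extends to the window edge there.  The phase samples inside this support
#' are the data every sharpening algorithm actually uses.
#'
#' @param signal A [time_signal()].
#' @param beta Threshold in (0, 1).
#' @return An object of class `beta_support` with fields `t_tilde_min`,
#'   `t_tilde_max` (s), `beta`, `n_tilde_t` (number of grid samples in the
#'   support) and `idx` (their index range).
#' @export
beta_support <- function(signal, beta) {
  if (!inherits(signal, "time_signal"))
    stop("signal must be a time_signal object")
  if (!(beta > 0 && beta < 1))
    stop("beta must lie strictly between 0 and 1")
  mag <- signal$magnitude
  m <- max(mag)
  if (m <= 0) stop("degenerate signal: all-zero magnitude")
  rel <- mag / m
  peak <- which.max(mag)
  n <- length(mag)
  lo <- 1L
  for (i in seq(peak, 1L)) if (rel[i] <= beta) { lo <- i; break }
  hi <- n
  for (i in seq(peak, n)) if (rel[i] <= beta) { hi <- i; break }
  if (hi - lo + 1L < 2L)
    stop("degenerate support: fewer than 2 samples inside the beta support")
  structure(
    list(t_tilde_min = signal$times[lo],
         t_tilde_max = signal$times[hi],
         beta = beta,
         n_tilde_t = hi - lo + 1L,
         idx = c(lo, hi)),
    class = "beta_support")
}

# Shared steps 1-9 run once per trace for a given (alpha, beta, Nt):
# orientation check/mirroring is handled by the caller (estimate);
# here the trace must already satisfy RL(fmin) < RL(fmax).
preprocess_trace <- function(trace, alpha, beta, Nt) {
  bar <- flatten_and_debias(trace)
  band <- alpha_band(bar, alpha)
  sig <- idtft(bar, Nt)
  sup <- beta_support(sig, beta)
  list(trace_bar = bar, alpha_band = band, signal = sig,
       beta_support = sup)
}
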