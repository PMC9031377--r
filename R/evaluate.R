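#' Percentage error of a resonance-frequency estimate
#'
#' \eqn{PE = |f_{true} - f_{est}| / f_{true} \times 100}.  The absolute
#' value is reported (the signed ratio is retained in Monte Carlo records
#' as `pe_signed`): benchmarking plots and percentile statistics are all
#' built on the non-negative error.
#'
#' @param f_true True resonance frequency in Hz, positive.
#' @param f_est Estimated frequency in Hz (vectorised).
#' @return Percentage error(s), non-negative.
#' @export
percentage_error <- function(f_true, f_est) {
  if (any(!is.finite(f_true)) || any(f_true <= 0))
    stop("f_true must be positive and finite")
  abs(f_true - f_est) / f_true * 100
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step CDF of a finite sample, as used to summarise the
#' Monte Carlo percentage errors and blind frequency estimates.  Returned
#' as a callable function (a thin wrapper over [stats::ecdf()]).
#' Percentiles elsewhere in the package use linear interpolation between
#' the closest order statistics ([stats::quantile()] type 7); that
#' convention is stated here once and used everywhere.
#'
#' @param samples Numeric vector with at least one finite value.
#' @return A function of class `empirical_cdf`.
#' @examples
#' F <- empirical_cdf(c(1, 2, 3, 4))
#' F(2.5)  # 0.5
#' @export
empirical_cdf <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L)
    stop("empirical_cdf needs at least one finite sample")
  f <- stats::ecdf(samples)
  class(f) <- c("empirical_cdf", class(f))
  f
}

# Percentile summary used in every report: mean, sd, median, 5th and 95th
# percentile (type-7 linear interpolation), max.
dispersion_stats <- function(x) {
  q <- quantile(x, probs = c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
    median = q[2L], p5 = q[1L], p95 = q[3L], max = max(x))
}

#' Monte Carlo configuration
#'
#' Parameter ranges and bookkeeping for the stochastic benchmarking of the
#' three estimators.  Continuous parameters (`alpha`, `beta`, `ftrue`) are
#' drawn uniformly on their interval; integer parameters (`Nf`, `Nt`,
#' `N_hat_f`) uniformly on the inclusive integer interval.  The default
#' ranges are the reference experiment: `alpha` 0.1-0.9, `beta` 0.05-0.45,
#' `Nf` 100-900, `Nt` 512-4608, `N_hat_f` 512-4608, `ftrue` 2.25-2.75 GHz,
#' 500 repetitions.  `fixed` pins any parameter to a constant without
#' disturbing the other draws: one random stream is advanced per
#' repetition in the fixed order (ftrue, alpha, beta, Nf, Nt, N_hat_f) and
#' pinned values simply override their draw.  All selected algorithms see
#' the same draws, enabling paired comparison.
#'
#' @param n_reps Number of repetitions, >= 1.
#' @param ranges Named list of length-2 inclusive ranges; defaults above.
#'   `ftrue` is in Hz.
#' @param fixed Named list of constants overriding any parameter
#'   (e.g. `list(beta = 0.05)`).
#' @param seed Integer seed for the report's random stream.
#' @param algorithms Character subset of
#'   `c("single_step", "iterative", "music")`.
#' @param max_iterations Iteration cap passed to the iterative algorithm.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_reps = 500L,
                      ranges = list(),
                      fixed = list(),
                      seed = 1L,
                      algorithms = c("single_step", "iterative", "music"),
                      max_iterations = 50L) {
  defaults <- list(alpha = c(0.1, 0.9),
                   beta = c(0.05, 0.45),
                   Nf = c(100, 900),
                   Nt = c(512, 4608),
                   N_hat_f = c(512, 4608),
                   ftrue = c(2.25e9, 2.75e9))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L])
      stop("range for ", nm, " must be c(low, high) with low <= high")
  }
  unknown <- setdiff(names(fixed), names(defaults))
  if (length(unknown))
    stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be at least 1")
  algorithms <- match.arg(algorithms,
                          c("single_step", "iterative", "music"),
                          several.ok = TRUE)
  structure(list(n_reps = n_reps, ranges = ranges, fixed = fixed,
                 seed = as.integer(seed), algorithms = algorithms,
                 max_iterations = as.integer(max_iterations)),
            class = "mc_config")
}

# One repetition's parameter draw.  Consumes exactly six uniforms in fixed
# order regardless of which parameters are pinned, so the stream stays
# aligned across configurations that differ only in `fixed`.
draw_quintuple <- function(config) {
  u <- runif(6L)
  r <- config$ranges
  draw_cont <- function(u, rng) rng[1L] + u * (rng[2L] - rng[1L])
  draw_int <- function(u, rng) {
    lo <- as.integer(rng[1L]); hi <- as.integer(rng[2L])
    min(hi, lo + as.integer(floor(u * (hi - lo + 1L))))
  }
  d <- list(ftrue = draw_cont(u[1L], r$ftrue),
            alpha = draw_cont(u[2L], r$alpha),
            beta = draw_cont(u[3L], r$beta),
            Nf = draw_int(u[4L], r$Nf),
            Nt = draw_int(u[5L], r$Nt),
            N_hat_f = draw_int(u[6L], r$N_hat_f))
  for (nm in names(config$fixed)) d[[nm]] <- config$fixed[[nm]]
  d
}

# Shared engine behind run_monte_carlo and blind_characterize.
mc_engine <- function(config, trace_for = NULL, model_template = NULL,
                      blind = FALSE, progress = FALSE) {
  algs <- config$algorithms
  draws <- vector("list", config$n_reps)
  recs <- vector("list", config$n_reps)
  with_seed(config$seed, {
    for (rep in seq_len(config$n_reps)) {
      d <- draw_quintuple(config)
      draws[[rep]] <- as.data.frame(d)
      trace <- if (blind) trace_for
      else synth_return_loss(
        synthetic_model(ftrue = d$ftrue,
                        amplitude = model_template$amplitude,
                        offset = model_template$offset,
                        sigma_left = model_template$sigma_left,
                        sigma_right = model_template$sigma_right,
                        band = as.numeric(model_template$band)),
        Nf = d$Nf)
      params <- sharpen_params(alpha = d$alpha, beta = d$beta,
                               Nt = d$Nt, N_hat_f = d$N_hat_f,
                               max_iterations = config$max_iterations)
      res <- tryCatch(estimate_shared(trace, params, algs),
                      error = function(e) e)
      if (inherits(res, "error")) {
        recs[[rep]] <- data.frame(
          rep = rep, algorithm = algs, f_est = NA_real_,
          pe = NA_real_, pe_signed = NA_real_,
          iterations = NA_integer_, converged = NA,
          failed = TRUE, error = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        recs[[rep]] <- do.call(rbind, lapply(algs, function(a) {
          r <- res[[a]]
          data.frame(
            rep = rep, algorithm = a, f_est = r$f_est,
            pe = if (blind) NA_real_
                 else percentage_error(d$ftrue, r$f_est),
            pe_signed = if (blind) NA_real_
                        else (d$ftrue - r$f_est) / d$ftrue * 100,
            iterations = r$iterations_used, converged = r$converged,
            failed = FALSE, error = NA_character_,
            stringsAsFactors = FALSE)
        }))
      }
      if (progress && rep %% 50L == 0L)
        message("  rep ", rep, "/", config$n_reps)
    }
  })
  draws <- do.call(rbind, draws)
  draws$rep <- seq_len(config$n_reps)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  metric <- if (blind) "f_est" else "pe"
  summaries <- lapply(algs, function(a) {
    sub <- records[records$algorithm == a, ]
    ok <- sub[!sub$failed, ]
    s <- if (nrow(ok) > 0L) as.list(dispersion_stats(ok[[metric]]))
         else as.list(c(mean = NA_real_, sd = NA_real_, median = NA_real_,
                        p5 = NA_real_, p95 = NA_real_, max = NA_real_))
    s$n_attempted <- nrow(sub)
    s$n_succeeded <- nrow(ok)
    s$n_failed <- nrow(sub) - nrow(ok)
    s$metric <- metric
    s
  })
  names(summaries) <- algs
  cdfs <- lapply(algs, function(a) {
    sub <- records[records$algorithm == a & !records$failed, ]
    if (nrow(sub) > 0L) empirical_cdf(sub[[metric]]) else NULL
  })
  names(cdfs) <- algs
  structure(list(mode = if (blind) "blind" else "pe",
                 config = config, draws = draws, records = records,
                 summary = summaries, cdf = cdfs),
            class = "mc_report")
}

#' Monte Carlo benchmark of the estimators on synthetic traces
#'
#' For each repetition, draws the parameter set (ftrue, alpha, beta, Nf,
#' Nt, N_hat_f), synthesises an asymmetric-Gaussian trace with `Nf`
#' samples, runs every selected algorithm on the shared preprocessing
#' output, and records the estimate and its percentage error.  Fully
#' seeded and reproducible.  Repetitions that raise an error (e.g. a
#' degenerate support) are recorded as failures, excluded from the
#' statistics, and counted in the summary — never silently dropped.
#'
#' @param config An [mc_config()].
#' @param model_template A [synthetic_model()] supplying the non-random
#'   curve constants (amplitude, offset, flank widths, band); its `ftrue`
#'   is ignored in favour of the per-repetition draw.
#' @param progress Emit a message every 50 repetitions.
#' @return An object of class `mc_report` with per-repetition `draws` and
#'   `records` data frames, per-algorithm `summary` (mean, sd, median,
#'   5th/95th percentile, max of PE, plus failure counts) and empirical
#'   CDFs.
#' @export
run_monte_carlo <- function(config = mc_config(),
                            model_template = synthetic_model(),
                            progress = FALSE) {
  if (!inherits(config, "mc_config"))
    stop("config must be an mc_config object")
  if (!inherits(model_template, "synthetic_model"))
    stop("model_template must be a synthetic_model object")
  mc_engine(config, model_template = model_template, progress = progress)
}

#' Blind dispersion characterisation on a fixed trace
#'
#' When the true resonance frequency is unknown (measured data), the
#' percentage error cannot be computed; instead the dispersion of the
#' estimate itself is characterised over random algorithm settings.  The
#' trace is fixed; `beta` is pinned (default 0.05) and `alpha`, `Nt`,
#' `N_hat_f` are drawn from the configured ranges.  The summary reports
#' the sample mean, standard deviation, median and 5th/95th percentiles
#' of `f_est` per algorithm — the mean is a good estimate of the
#' resonance frequency, and the 5-95 percentile spread measures the
#' precision of the blind estimate (on well-behaved traces it falls well
#' below the acquisition step).
#'
#' @param trace The fixed [return_loss_trace()] to characterise.
#' @param config An [mc_config()]; its `ftrue` and `Nf` draws are ignored
#'   (the trace supplies the data), and `beta` is pinned to 0.05 unless
#'   already present in `config$fixed`.
#' @param progress Emit a message every 50 repetitions.
#' @return An `mc_report` whose statistics are over `f_est` in Hz.
#' @export
blind_characterize <- function(trace, config = mc_config(),
                               progress = FALSE) {
  stopifnot_trace(trace)
  if (!inherits(config, "mc_config"))
    stop("config must be an mc_config object")
  if (is.null(config$fixed$beta)) config$fixed$beta <- 0.05
  mc_engine(config, trace_for = trace, blind = TRUE, progress = progress)
}

#' @export
print.mc_report <- function(x, ...) {
  unit <- if (x$mode == "blind") "GHz (f_est)" else "% (PE)"
  scale <- if (x$mode == "blind") 1e9 else 1
  cat(sprintf("<mc_report> %s mode, %d rep(s), seed %d\n",
              x$mode, x$config$n_reps, x$config$seed))
  for (a in names(x$summary)) {
    s <- x$summary[[a]]
    cat(sprintf(
      "  %-12s mean %.6g  sd %.3g  median %.6g  P5 %.6g  P95 %.6g  [%s]%s\n",
      a, s$mean / scale, s$sd / scale, s$median / scale, s$p5 / scale,
      s$p95 / scale, unit,
      if (s$n_failed > 0) sprintf("  (%d failed)", s$n_failed) else ""))
  }
  invisible(x)
}

#' Serialise a Monte Carlo report
#'
#' Writes the per-repetition records (joined with the parameter draws, the
#' tidy surface behind the PE-versus-parameter scatter studies) to
#' `<prefix>_records.csv` and the per-algorithm summary (percentiles,
#' means, failure counts, configuration) to `<prefix>_summary.json`.
#'
#' @param report An `mc_report`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_mc_report <- function(report, dir, prefix = "mc") {
  if (!inherits(report, "mc_report"))
    stop("report must be an mc_report object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tidy <- merge(report$records, report$draws, by = "rep", sort = TRUE)
  tidy <- tidy[order(tidy$rep, tidy$algorithm), ]
  csv <- file.path(dir, paste0(prefix, "_records.csv"))
  write.csv(tidy, csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  payload <- list(mode = report$mode,
                  seed = report$config$seed,
                  n_reps = report$config$n_reps,
                  fixed = report$config$fixed,
                  ranges = report$config$ranges,
                  summary = report$summary)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(records = csv, summary = js))
}
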