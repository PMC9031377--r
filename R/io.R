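#' Read a return-loss trace from disk
#'
#' Two dialects are supported.  `"csv"` expects two numeric columns
#' (frequency, return loss in dB) with an optional header line; the
#' frequency unit must be given explicitly via `unit` (silent misparsing
#' by a factor of 1e9 would be catastrophic, so no magnitude heuristics
#' are applied).  `"touchstone_s1p"` reads a standard Touchstone v1
#' one-port file: the option line supplies the frequency unit and format
#' (MA, DB or RI), and the reflection-coefficient magnitude is converted
#' to return loss via \eqn{RL = -20\log_{10}|\Gamma|}.  Magnitudes above 1
#' (non-passive readings, usually calibration artefacts) are clamped to 1
#' with a warning reporting the count.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"touchstone_s1p"`; by default inferred from
#'   the extension (`.s1p` means Touchstone, anything else CSV).
#' @param unit Frequency unit for CSV input: `"hz"` or `"ghz"`.
#'   Ignored for Touchstone (the option line governs).
#' @return A [return_loss_trace()].
#' @export
read_trace <- function(path, dialect = NULL, unit = c("hz", "ghz")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.s1p$", path, ignore.case = TRUE))
      "touchstone_s1p" else "csv"
  dialect <- match.arg(dialect, c("csv", "touchstone_s1p"))
  if (dialect == "csv") {
    unit <- match.arg(unit)
    read_trace_csv(path, unit)
  } else {
    read_trace_s1p(path)
  }
}

read_trace_csv <- function(path, unit) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error in ", path, ": empty file")
  sep <- if (grepl(",", lines[1L]) || (length(lines) > 1L &&
                                       grepl(",", lines[2L]))) "," else ""
  start <- 1L
  first <- strsplit(trimws(lines[1L]), if (sep == ",") "," else "[ \t]+")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  f <- numeric(0); v <- numeric(0)
  for (i in seq(start, length(lines))) {
    parts <- strsplit(trimws(lines[i]),
                      if (sep == ",") "," else "[ \t]+")[[1L]]
    parts <- parts[nzchar(parts)]
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) < 2L || anyNA(num[1:2]))
      stop("parse error in ", path, " at line ", i,
           ": expected two numeric columns, got '", lines[i], "'")
    f <- c(f, num[1L]); v <- c(v, num[2L])
  }
  mult <- if (unit == "ghz") 1e9 else 1
  return_loss_trace(f * mult, v)
}

read_trace_s1p <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit_mult <- NULL; fmt <- NULL
  f <- numeric(0); a <- numeric(0); b <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])  # strip comments
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      toks <- toupper(strsplit(ln, "[ \t]+")[[1L]])
      utok <- intersect(toks, c("HZ", "KHZ", "MHZ", "GHZ"))
      ftok <- intersect(toks, c("MA", "DB", "RI"))
      if (length(utok) != 1L || length(ftok) != 1L)
        stop("parse error in ", path, " at line ", i,
             ": unsupported Touchstone option line '", lines[i], "'")
      unit_mult <- switch(utok, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
      fmt <- ftok
      next
    }
    num <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1L]]))
    if (length(num) < 3L || anyNA(num[1:3]))
      stop("parse error in ", path, " at line ", i,
           ": expected 'freq value value', got '", lines[i], "'")
    f <- c(f, num[1L]); a <- c(a, num[2L]); b <- c(b, num[3L])
  }
  if (is.null(fmt))
    stop("parse error in ", path, ": missing Touchstone option line (#)")
  if (length(f) == 0L) stop("parse error in ", path, ": no data lines")
  mag <- switch(fmt,
                MA = a,
                DB = 10^(a / 20),
                RI = sqrt(a^2 + b^2))
  over <- mag > 1
  if (any(over)) {
    warning(sum(over), " |S11| value(s) above 1 clamped to 1 (passive ",
            "one-port expected)")
    mag[over] <- 1
  }
  rl_from_gamma(mag, f * unit_mult)
}

#' Write a return-loss trace to CSV
#'
#' Two columns, `frequency_hz` and `rl_db`, serialised at full double
#' precision so that a write/read round trip is bit-identical.
#'
#' @param trace A [return_loss_trace()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frequency_hz,rl_db", con)
  writeLines(sprintf("%.17g,%.17g", trace$frequencies, trace$values), con)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Parses and validates a JSON configuration for the command-line
#' interface.  Recognised blocks: `model` (keys `ftrue_ghz`,
#' `amplitude_db`, `offset_db`, `sigma_left_ghz`, `sigma_right_ghz`,
#' `fmin_ghz`, `fmax_ghz`, `nf`, `noise_sigma_db`, `m_sweeps`, `seed`),
#' `params` (`alpha`, `beta`, `nt`, `n_hat_f`, `max_iterations`,
#' `algorithm`), `monte_carlo` (`n_reps`, `seed`, `ranges`, `fixed`,
#' `algorithms`), plus top-level `input`, `unit`, `seed`, `output_dir`.
#'
#' @param path Path to a JSON file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("input", "unit", "dialect", "seed", "output_dir", "model",
             "params", "monte_carlo")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (!is.null(cfg$input) && !is.null(cfg$model))
    stop("config must name exactly one input source (file or model), ",
         "not both")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("config input file not found: ", cfg$input)
  structure(cfg, class = "run_config")
}

model_from_config <- function(m) {
  if (is.null(m)) return(synthetic_model())
  synthetic_model(
    ftrue = ghz_to_hz(m$ftrue_ghz %||% 2.25),
    amplitude = m$amplitude_db %||% 18,
    offset = m$offset_db %||% 2,
    sigma_left = ghz_to_hz(m$sigma_left_ghz %||% 0.07),
    sigma_right = ghz_to_hz(m$sigma_right_ghz %||% 0.10),
    band = ghz_to_hz(c(m$fmin_ghz %||% 2, m$fmax_ghz %||% 3)))
}

ghz_to_hz <- function(x) as.numeric(x) * 1e9

`%||%` <- function(a, b) if (is.null(a)) b else a
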