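#' Generate a stochastic electrical vestibular stimulus
#'
#' Creates the band-limited stochastic current waveform used as the vestibular
#' disturbance: Gaussian white noise, low-pass filtered with a zero-phase
#' (forward-backward) Butterworth filter, mean-removed, and linearly scaled so
#' that its maximum absolute value equals `peak`. With the defaults (25 Hz
#' cutoff, 4th order, 5.0 mA peak, 8 min at 200 samples/s) the realized RMS
#' amplitude is an emergent ~1.1-1.2 mA.
#'
#' The peak is treated as the binding amplitude constraint and the RMS as
#' emergent: only one of the two can be scaled to exactly.
#'
#' @param duration stimulus duration in seconds (> 0).
#' @param rate sampling rate in samples/s.
#' @param cutoff low-pass cutoff in Hz. Rates below `2 * cutoff` are refused
#'   (aliasing); rates below `4 * cutoff` draw a warning.
#' @param order design order of the Butterworth low-pass (applied
#'   forward-backward, so the effective roll-off is doubled).
#' @param peak target maximum absolute current in mA (> 0).
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return An object of class `evs_signal`: a list with `samples` (mA),
#'   `rate`, `duration`, `seed`, `cutoff`, `filter_order` and `peak`.
#' @examples
#' evs <- generate_evs(duration = 10, seed = 1)
#' max(abs(evs$samples))    # == 5 exactly
#' sqrt(mean(evs$samples^2))
#' @export
generate_evs <- function(duration, rate = 200, cutoff = 25, order = 4,
                         peak = 5.0, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be a positive number of seconds")
  }
  if (!is.numeric(peak) || peak <= 0) stop("peak must be positive (mA)")
  if (order < 1) stop("filter order must be >= 1")
  if (rate < 2 * cutoff) {
    stop("rate (", rate, ") below 2 * cutoff (", 2 * cutoff,
         "): the requested band cannot be represented (aliasing)")
  }
  if (rate < 4 * cutoff) {
    warning("rate below 4 * cutoff; the filter design is poorly conditioned")
  }
  n <- round(duration * rate)
  x <- with_seed(seed, stats::rnorm(n))
  x <- zero_phase_lowpass(x, rate, cutoff, order)
  x <- x - mean(x)
  x <- x * (peak / max(abs(x)))
  structure(
    list(samples = x, rate = rate, duration = duration,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         cutoff = cutoff, filter_order = as.integer(order), peak = peak),
    class = "evs_signal"
  )
}

#' @export
print.evs_signal <- function(x, ...) {
  cat("<evs_signal> stochastic vestibular stimulus\n")
  cat(sprintf("  duration: %g s @ %g samples/s (%d samples)\n",
              x$duration, x$rate, length(x$samples)))
  cat(sprintf("  band: 0-%g Hz (zero-phase Butterworth, order %d)\n",
              x$cutoff, x$filter_order))
  cat(sprintf("  peak: %g mA, RMS: %.3f mA, seed: %s\n",
              x$peak, sqrt(mean(x$samples^2)),
              ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' @export
plot.evs_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$rate
  plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "current (mA)",
       main = "stochastic vestibular stimulus", ...)
  abline(h = c(-x$peak, 0, x$peak), lty = c(2, 1, 2), col = "grey60")
  invisible(x)
}

#' Write / read an EVS signal as delimited text
#'
#' The file carries `#`-prefixed header lines naming the sampling rate, units,
#' seed and filter design, followed by one sample per row.
#'
#' @param evs an `evs_signal`.
#' @param path output (input) file path.
#' @return `write_evs` returns `path` invisibly; `read_evs` returns the
#'   reconstructed `evs_signal`.
#' @export
write_evs <- function(evs, path) {
  stopifnot(inherits(evs, "evs_signal"))
  hdr <- c(
    sprintf("# rate_hz: %.10g", evs$rate),
    "# units: mA",
    sprintf("# seed: %s", ifelse(is.na(evs$seed), "NA", evs$seed)),
    sprintf("# cutoff_hz: %.10g", evs$cutoff),
    sprintf("# filter_order: %d", evs$filter_order),
    sprintf("# peak_ma: %.10g", evs$peak),
    "current_ma"
  )
  writeLines(c(hdr, format(evs$samples, digits = 17, trim = TRUE,
                           scientific = TRUE)), path)
  invisible(path)
}

#' @rdname write_evs
#' @export
read_evs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  samples <- as.numeric(lines[-seq_len(length(hdr) + 1L)])
  rate <- as.numeric(get("rate_hz"))
  seed <- suppressWarnings(as.integer(get("seed")))
  structure(
    list(samples = samples, rate = rate, duration = length(samples) / rate,
         seed = seed, cutoff = as.numeric(get("cutoff_hz")),
         filter_order = as.integer(get("filter_order")),
         peak = as.numeric(get("peak_ma"))),
    class = "evs_signal"
  )
}
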