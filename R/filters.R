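# Internal DSP helpers shared by the stimulus and signal-conditioning code.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of the stated design order forward and
#' backward (`signal::filtfilt`), so the net filter has zero group delay and
#' twice the design roll-off. The order refers to the designed (single-pass)
#' filter, matching the convention of the gait/EVS literature.
#'
#' @param x numeric vector.
#' @param rate sampling rate (samples/s).
#' @param cutoff cutoff frequency (Hz); must be below `rate / 2`.
#' @param order design order of the Butterworth filter (>= 1).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
zero_phase_lowpass <- function(x, rate, cutoff, order) {
  stopifnot(is.numeric(x), rate > 0, order >= 1)
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         rate / 2, " Hz), got ", cutoff)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  pad <- min(n - 1L, 3L * order * ceiling(rate / cutoff))
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    y[(pad + 1L):(pad + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

# FIR convolution y = h * x (causal, same length as x), FFT-based.
fir_filter <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Shift a signal later in time by `delay` seconds (zero-padded at the start).
delay_signal <- function(x, rate, delay) {
  k <- round(delay * rate)
  if (k <= 0) return(x)
  c(rep(0, k), x)[seq_along(x)]
}

# Linear-interpolation resample of a uniformly sampled signal onto a new rate.
resample_to_rate <- function(x, rate_in, rate_out) {
  t_in <- (seq_along(x) - 1) / rate_in
  n_out <- floor(t_in[length(t_in)] * rate_out) + 1L
  t_out <- (seq_len(n_out) - 1) / rate_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Fan a global seed out into named substream seeds (31-bit, reproducible).
substream_seeds <- function(seed, names) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(as.integer(s), names)
}
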