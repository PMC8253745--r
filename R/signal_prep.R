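# Conditioning of EMG/GRF/EVS streams and stride-synchronized segmentation.

#' Stride-normalized average EMG envelope
#'
#' Full-wave rectification, zero-phase 6th-order Butterworth low-pass at
#' 20 Hz, time-normalization of each stride onto a fixed 0-100% grid, and
#' averaging across the first `n_strides` strides. Amplitude normalization to
#' the channel maximum is a study-level step across conditions — see
#' [normalize_envelopes()] — not applied per trial.
#'
#' @param emg raw EMG samples.
#' @param rate EMG sampling rate (>= 200 samples/s).
#' @param strikes heel-strike times (s) of the aligning foot.
#' @param n_strides number of strides to average (default: all complete).
#' @param n_points points of the stride-phase grid (>= 200; default 1000,
#'   i.e. 0.1% steps).
#' @param cutoff,order envelope low-pass design (Hz / filter order).
#' @return numeric vector of length `n_points` with attributes `phase`
#'   (0-100%) and `n_strides`.
#' @export
emg_envelope <- function(emg, rate, strikes, n_strides = NULL,
                         n_points = 1000, cutoff = 20, order = 6) {
  if (rate < 200) stop("EMG rate must be >= 200 samples/s")
  if (stats::sd(emg) < .Machine$double.eps * max(1, abs(mean(emg)))) {
    warning("degenerate EMG channel (constant or saturated signal)")
  }
  env <- zero_phase_lowpass(abs(emg), rate, cutoff, order)
  n_avail <- length(strikes) - 1L
  if (is.null(n_strides)) n_strides <- n_avail
  if (n_avail < n_strides) {
    stop("only ", n_avail, " complete strides available, ", n_strides,
         " requested")
  }
  grid <- seq(0, 1, length.out = n_points)
  t <- (seq_along(env) - 1) / rate
  acc <- numeric(n_points)
  for (i in seq_len(n_strides)) {
    tt <- strikes[i] + grid * (strikes[i + 1] - strikes[i])
    acc <- acc + stats::approx(t, env, xout = tt, rule = 2)$y
  }
  out <- acc / n_strides
  attr(out, "phase") <- grid * 100
  attr(out, "n_strides") <- n_strides
  out
}

#' Normalize averaged envelopes to the per-channel maximum across conditions
#'
#' @param envelopes list (one element per condition) of envelope vectors for
#'   the same channel.
#' @return the list, each element divided by the global maximum (so the
#'   per-channel maximum across conditions is 1).
#' @export
normalize_envelopes <- function(envelopes) {
  m <- max(vapply(envelopes, max, numeric(1)))
  if (m <= 0) stop("cannot normalize: non-positive envelope maximum")
  lapply(envelopes, function(e) e / m)
}

#' Condition a signal for coherence analysis
#'
#' EMG is full-wave rectified, then every path is zero-phase low-pass
#' filtered (6th-order Butterworth, 100 Hz) and down-sampled to exactly
#' 200 samples/s by integer decimation (the low-pass is the anti-alias
#' stage). The GRF path sums left + right mediolateral forces before
#' filtering (required for conditions where feet cross belts). Inputs already
#' at the target rate pass through unchanged apart from the low-pass when it
#' is representable; up-sampling is refused.
#'
#' @param x numeric vector, or for `kind = "grf"` a list/data frame whose
#'   elements are the per-belt mediolateral forces to sum.
#' @param rate input sampling rate (>= 200 samples/s, an integer multiple of
#'   `target_rate`).
#' @param kind one of `"evs"`, `"emg"`, `"grf"`.
#' @param target_rate output rate (samples/s).
#' @param cutoff,order anti-alias low-pass design.
#' @return list with `samples` and `rate` (= `target_rate`).
#' @export
prep_for_coherence <- function(x, rate, kind = c("evs", "emg", "grf"),
                               target_rate = 200, cutoff = 100, order = 6) {
  kind <- match.arg(kind)
  if (rate < target_rate) {
    stop("input rate (", rate, ") below ", target_rate,
         " samples/s: up-sampling is refused")
  }
  if (kind == "grf") x <- Reduce(`+`, as.list(as.data.frame(x)))
  if (kind == "emg") x <- abs(x)
  x <- as.numeric(x)
  if (cutoff < rate / 2) x <- zero_phase_lowpass(x, rate, cutoff, order)
  if (rate > target_rate) {
    dec <- rate / target_rate
    if (abs(dec - round(dec)) > 1e-9) {
      stop("input rate must be an integer multiple of the target rate")
    }
    x <- x[seq(1, length(x), by = round(dec))]
  }
  list(samples = x, rate = target_rate)
}

#' Cut a conditioned signal into padded stride segments
#'
#' Each retained stride `i` spans `[strike_i - pad * T_i,
#' strike_{i+1} + pad * T_i]`: the core stride plus `pad_fraction` of a
#' stride's worth of neighbouring data on each side, protecting the
#' subsequent wavelet transform from edge distortion. Segments are aligned on
#' the given limb's own heel strikes so left- and right-aligned sets can be
#' pooled. The first and last stride are dropped (no neighbour to pad from).
#'
#' @param x conditioned signal (numeric vector) sampled at `rate`.
#' @param rate sampling rate (samples/s).
#' @param strikes heel-strike times (s) of the aligning foot.
#' @param pad_fraction fraction of the stride padded on each side (0.5 =
#'   half a neighbouring stride per side).
#' @param n_strides optional cap on the number of strides retained.
#' @return object of class `stride_segments`: list with `segments` (list of
#'   numeric vectors), `core_start` (index of the first core sample within
#'   each segment), `core_length`, `durations` (s), `rate`, `pad_fraction`.
#' @export
segment_strides <- function(x, rate, strikes, pad_fraction = 0.5,
                            n_strides = NULL) {
  if (pad_fraction < 0) stop("pad_fraction must be >= 0")
  ns <- length(strikes) - 1L
  if (ns < 3 && pad_fraction > 0) {
    stop("need at least 3 strides to pad interior strides")
  }
  keep <- if (pad_fraction > 0) seq(2L, ns - 1L) else seq_len(ns)
  if (!is.null(n_strides)) {
    if (length(keep) < n_strides) {
      stop("only ", length(keep), " padded strides available, ",
           n_strides, " requested")
    }
    keep <- keep[seq_len(n_strides)]
  }
  starts <- floor(strikes * rate) + 1L       # first sample of each stride
  segments <- vector("list", length(keep))
  core_start <- integer(length(keep))
  core_len <- integer(length(keep))
  excluded <- 0L
  for (j in seq_along(keep)) {
    i <- keep[j]
    s0 <- starts[i]; s1 <- starts[i + 1L] - 1L
    ncore <- s1 - s0 + 1L
    npad <- round(pad_fraction * ncore)
    a <- s0 - npad; b <- s1 + npad
    if (a < 1L || b > length(x)) { excluded <- excluded + 1L; next }
    segments[[j]] <- x[a:b]
    core_start[j] <- npad + 1L
    core_len[j] <- ncore
  }
  ok <- !vapply(segments, is.null, logical(1))
  if (excluded > 0) {
    message(excluded, " stride(s) excluded: padded window exceeds the record")
  }
  structure(
    list(segments = segments[ok], core_start = core_start[ok],
         core_length = core_len[ok],
         durations = core_len[ok] / rate, rate = rate,
         pad_fraction = pad_fraction, n_excluded = excluded),
    class = "stride_segments"
  )
}

#' @export
print.stride_segments <- function(x, ...) {
  cat("<stride_segments>", length(x$segments), "strides @", x$rate,
      "samples/s\n")
  cat(sprintf("  stride duration: %.3f +/- %.3f s; pad: %g per side\n",
              mean(x$durations), stats::sd(x$durations), x$pad_fraction))
  invisible(x)
}

#' Reconstruct the analysed span from stride segments
#'
#' Crops the pads off every segment and concatenates the cores; by
#' construction this reproduces the original samples bit-exactly.
#'
#' @param segs a `stride_segments` object.
#' @return numeric vector of concatenated core samples.
#' @export
crop_and_concat <- function(segs) {
  stopifnot(inherits(segs, "stride_segments"))
  unlist(lapply(seq_along(segs$segments), function(j) {
    s <- segs$segments[[j]]
    s[segs$core_start[j]:(segs$core_start[j] + segs$core_length[j] - 1L)]
  }), use.names = FALSE)
}

#' Resample stride segments onto the grand-average stride duration
#'
#' The stride-time axis of each segment is linearly resampled so every stride
#' has the sample count of the average stride duration. For spectra the same
#' normalization is applied per stride inside [stride_averaged_spectra()]
#' (on the auto- and cross-spectra, frequency axis untouched).
#'
#' @param segs a `stride_segments` object.
#' @param target_duration optional duration (s) to normalize to; defaults to
#'   the grand-average stride duration of `segs`.
#' @return a `stride_segments` object with equal-length segments.
#' @export
normalize_durations <- function(segs, target_duration = NULL) {
  stopifnot(inherits(segs, "stride_segments"))
  if (any(segs$core_length == 0)) stop("zero-length stride")
  if (is.null(target_duration)) target_duration <- mean(segs$durations)
  n_core <- round(target_duration * segs$rate)
  n_pad <- round(segs$pad_fraction * n_core)
  n_tot <- n_core + 2L * n_pad
  out <- lapply(seq_along(segs$segments), function(j) {
    s <- segs$segments[[j]]
    stats::approx(seq(0, 1, length.out = length(s)), s,
                  xout = seq(0, 1, length.out = n_tot))$y
  })
  structure(
    list(segments = out, core_start = rep(n_pad + 1L, length(out)),
         core_length = rep(n_core, length(out)),
         durations = rep(target_duration, length(out)), rate = segs$rate,
         pad_fraction = segs$pad_fraction, n_excluded = segs$n_excluded),
    class = "stride_segments"
  )
}
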