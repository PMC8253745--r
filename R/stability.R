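# Local dynamic stability: local divergence exponent via Rosenstein's
# nearest-neighbour divergence tracking.

#' Three-point velocity from a position trace
#'
#' Central differences `v[i] = (x[i+1] - x[i-1]) * rate / 2`, with one-sided
#' differences at the endpoints.
#'
#' @param x position samples (>= 3).
#' @param rate sampling rate (samples/s).
#' @return velocity series, same length as `x`.
#' @export
three_point_velocity <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v
}

#' Resample a series to a fixed number of samples per stride
#'
#' Each stride (between consecutive same-foot heel strikes) is linearly
#' resampled to exactly `samples_per_stride` samples, so `n_strides` strides
#' yield `n_strides * samples_per_stride` samples (256 strides at 100
#' samples/stride give 25,600).
#'
#' @param x series sampled at `rate`.
#' @param rate sampling rate (samples/s).
#' @param strikes heel-strike times (s) of one foot.
#' @param n_strides number of strides to use.
#' @param samples_per_stride samples per normalized stride.
#' @return numeric vector of length `n_strides * samples_per_stride`.
#' @export
resample_strides <- function(x, rate, strikes, n_strides = 256,
                             samples_per_stride = 100) {
  avail <- length(strikes) - 1L
  if (avail < n_strides) {
    stop("only ", avail, " complete strides available, ", n_strides,
         " requested")
  }
  t <- (seq_along(x) - 1) / rate
  out <- numeric(n_strides * samples_per_stride)
  for (i in seq_len(n_strides)) {
    tt <- seq(strikes[i], strikes[i + 1],
              length.out = samples_per_stride + 1L)[seq_len(samples_per_stride)]
    out[((i - 1L) * samples_per_stride + 1L):(i * samples_per_stride)] <-
      stats::approx(t, x, xout = tt, rule = 2)$y
  }
  out
}

#' Rosenstein mean log-divergence curve
#'
#' Delay-embeds the series, finds each point's nearest neighbour outside a
#' Theiler exclusion window, and tracks the mean natural log of the
#' inter-trajectory distance over the horizon. Distances are floored at
#' 1e-12 so exactly periodic series give a flat (slope ~0) curve rather than
#' `-Inf`.
#'
#' @param x fixed-length series (one sample grid per stride, e.g. from
#'   [resample_strides()]).
#' @param dim embedding dimension.
#' @param delay embedding delay (samples).
#' @param theiler Theiler exclusion window (samples); neighbours with
#'   `|i - j| <= theiler` are excluded.
#' @param samples_per_stride samples per stride (sets the stride-time axis).
#' @param horizon tracking horizon in strides.
#' @return object of class `divergence_curve`: `time` (strides),
#'   `mean_log_div`, `n_pairs`, embedding metadata, and `lde` (slope over
#'   0-0.5 stride, per stride).
#' @export
rosenstein_divergence <- function(x, dim = 5, delay = 10, theiler = 50,
                                  samples_per_stride = 100, horizon = 1) {
  if (stats::sd(x) == 0) stop("degenerate (constant) series")
  m <- length(x) - (dim - 1L) * delay
  h <- round(horizon * samples_per_stride)
  if (m <= h + theiler + 1L) {
    stop("series too short for the requested embedding and horizon")
  }
  emb <- sapply(seq_len(dim), function(d) x[(1:m) + (d - 1L) * delay])
  res <- rosenstein_divergence_cpp(emb, as.integer(theiler), as.integer(h))
  curve <- structure(
    list(time = (0:h) / samples_per_stride,
         mean_log_div = res$mean_log_div,
         n_pairs = res$n_pairs,
         dim = dim, delay = delay, theiler = theiler,
         samples_per_stride = samples_per_stride,
         n_strides = length(x) / samples_per_stride),
    class = "divergence_curve")
  curve$lde <- lde_slope(curve)
  curve
}

#' Local divergence exponent: slope of the divergence curve
#'
#' Ordinary least-squares slope of the mean log divergence over normalized
#' time in `[window[1], window[2]]` strides (default 0-0.5).
#'
#' @param curve a `divergence_curve`.
#' @param window slope window in strides.
#' @return slope in 1/stride.
#' @export
lde_slope <- function(curve, window = c(0, 0.5)) {
  stopifnot(inherits(curve, "divergence_curve"))
  if (max(curve$time) < window[2]) {
    stop("divergence curve does not cover ", window[2], " strides")
  }
  sel <- curve$time >= window[1] & curve$time <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 points in the slope window")
  unname(stats::coef(stats::lm(curve$mean_log_div[sel] ~
                                 curve$time[sel]))[2])
}

#' @export
print.divergence_curve <- function(x, ...) {
  cat("<divergence_curve> Rosenstein mean log divergence\n")
  cat(sprintf("  embedding: dim %d, delay %d samples; Theiler %d; %g strides\n",
              x$dim, x$delay, x$theiler, x$n_strides))
  cat(sprintf("  LDE (0-0.5 stride): %.4f / stride\n", x$lde))
  invisible(x)
}

#' @export
plot.divergence_curve <- function(x, ...) {
  plot(x$time, x$mean_log_div, type = "l", xlab = "time (strides)",
       ylab = "mean ln divergence", main = "local divergence", ...)
  sel <- x$time <= 0.5
  fit <- stats::lm(x$mean_log_div[sel] ~ x$time[sel])
  lines(x$time[sel], stats::predict(fit), col = "red", lwd = 2)
  legend("bottomright", sprintf("LDE = %.3f / stride", x$lde), bty = "n")
  invisible(x)
}

#' Local divergence exponent of a trial's trunk velocity
#'
#' Convenience wrapper: takes the T6 marker mediolateral position from a
#' trial, differentiates it (three-point), resamples to a fixed number of
#' samples per stride using the trial's gait events, and runs the Rosenstein
#' estimator.
#'
#' @param trial a `trial_recording`.
#' @param events a [gait_events()] object (defaults to the trial's ground
#'   truth events if present).
#' @param n_strides,samples_per_stride resampling contract (256 x 100 by
#'   default at full study scale).
#' @param axes `"ml"` (default) uses mediolateral velocity only; `"3d"`
#'   stacks all three axes into the state via the embedding.
#' @param ... passed to [rosenstein_divergence()].
#' @return a `divergence_curve`.
#' @export
trial_lde <- function(trial, events = NULL, n_strides = 256,
                      samples_per_stride = 100, axes = c("ml", "3d"), ...) {
  stopifnot(inherits(trial, "trial_recording"))
  axes <- match.arg(axes)
  strikes <- if (!is.null(events)) events$heel_strikes_left else
    trial$truth$heel_strikes_left
  rate <- trial$rates$markers
  pos <- trial$markers$t6
  vel <- if (axes == "ml") three_point_velocity(pos$x, rate) else
    sqrt(three_point_velocity(pos$x, rate)^2 +
         three_point_velocity(pos$y, rate)^2 +
         three_point_velocity(pos$z, rate)^2)
  v <- resample_strides(vel, rate, strikes, n_strides, samples_per_stride)
  rosenstein_divergence(v, samples_per_stride = samples_per_stride, ...)
}
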