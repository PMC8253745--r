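# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# Evenly spaced heel-strike times starting at t0 (seconds).
uniform_strikes <- function(n_strides, stride = 1.54, t0 = 1.0) {
  t0 + (seq_len(n_strides + 1L) - 1L) * stride
}

# A small clean walking trial reused across files (20 strides, default
# coupling), plus its detected events.
small_trial <- function() {
  if (is.null(.fixtures$small_trial)) {
    evs <- generate_evs(duration = 40, seed = 301)
    .fixtures$small_trial <- simulate_trial(evs, n_strides = 20, seed = 302)
    .fixtures$small_events <- detect_heel_strikes(.fixtures$small_trial)
  }
  .fixtures$small_trial
}

small_events <- function() {
  small_trial()
  .fixtures$small_events
}

# A 256-stride trial used for law-of-large-numbers checks (step widths,
# stride times). step_width_mean chosen to match the convergence example.
big_trial <- function() {
  if (is.null(.fixtures$big_trial)) {
    evs <- generate_evs(duration = ceiling(262 * 1.54), seed = 311)
    .fixtures$big_trial <- simulate_trial(
      evs, n_strides = 258, seed = 312,
      step_width_mean = 0.18, step_width_sd = 0.02)
    .fixtures$big_events <- detect_heel_strikes(.fixtures$big_trial)
  }
  .fixtures$big_trial
}

big_events <- function() {
  big_trial()
  .fixtures$big_events
}

# Pure-R brute-force Rosenstein oracle: all-pairs nearest neighbour with
# Theiler exclusion, mean log distance over the horizon. Independent of the
# compiled implementation.
brute_rosenstein <- function(x, dim = 5, delay = 10, theiler = 50,
                             horizon_samples = 100) {
  m <- length(x) - (dim - 1L) * delay
  emb <- sapply(seq_len(dim), function(d) x[(1:m) + (d - 1L) * delay])
  last <- m - horizon_samples
  dmat <- as.matrix(stats::dist(emb[seq_len(last), , drop = FALSE]))
  for (i in seq_len(last)) {
    lo <- max(1L, i - theiler); hi <- min(last, i + theiler)
    dmat[i, lo:hi] <- Inf
  }
  nn <- apply(dmat, 1L, which.min)
  valid <- is.finite(dmat[cbind(seq_len(last), nn)])
  acc <- numeric(horizon_samples + 1L)
  cnt <- 0L
  for (i in which(valid)) {
    j <- nn[i]
    d_k <- sqrt(rowSums((emb[i + 0:horizon_samples, , drop = FALSE] -
                           emb[j + 0:horizon_samples, , drop = FALSE])^2))
    acc <- acc + log(pmax(d_k, 1e-12))
    cnt <- cnt + 1L
  }
  acc / cnt
}
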