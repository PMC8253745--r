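test_that("EMG envelope reproduces closed-form values", {
  rate <- 2000
  strikes <- uniform_strikes(6, stride = 1.5, t0 = 0.5)
  n <- rate * 11
  t <- (seq_len(n) - 1) / rate
  # constant input passes through rectify + low-pass unchanged (a constant
  # channel also legitimately draws the degenerate-signal warning)
  env_c <- suppressWarnings(emg_envelope(rep(2.5, n), rate, strikes))
  expect_equal(unclass(env_c)[seq_along(env_c)], rep(2.5, 1000),
               tolerance = 1e-6, ignore_attr = TRUE)
  # |A sin| has mean 2A/pi; harmonics (>= 100 Hz) die in the 20 Hz low-pass
  A <- 3
  env_s <- emg_envelope(A * sin(2 * pi * 50 * t), rate, strikes)
  mid <- env_s[100:900]
  expect_equal(mean(mid), 2 * A / pi, tolerance = 0.02)
  expect_lt(sd(mid) / mean(mid), 0.02)
})

test_that("degenerate EMG channels draw a warning", {
  strikes <- uniform_strikes(4, stride = 1.5, t0 = 0.5)
  expect_warning(emg_envelope(rep(0, 2000 * 8), 2000, strikes), "degenerate")
})

test_that("envelope normalization is a study-level maximum of one", {
  strikes <- uniform_strikes(6, stride = 1.5, t0 = 0.5)
  n <- 2000 * 11
  t <- (seq_len(n) - 1) / 2000
  envs <- lapply(c(1, 2, 0.5), function(a)
    emg_envelope(a * (1 + sin(2 * pi * t / 1.5)), 2000, strikes))
  normed <- normalize_envelopes(envs)
  expect_equal(max(vapply(normed, max, numeric(1))), 1)
  expect_equal(normed[[1]] * 2, normed[[2]], tolerance = 1e-10)
})

test_that("coherence conditioning hits 200 samples/s with the stated filter", {
  n <- 2000 * 5
  t <- (seq_len(n) - 1) / 2000
  out <- prep_for_coherence(sin(2 * pi * 7 * t) + 2, 2000, "evs")
  expect_equal(out$rate, 200)
  expect_length(out$samples, n / 10)
  # DC passes unchanged
  dc <- prep_for_coherence(rep(1.5, n), 2000, "evs")
  expect_equal(dc$samples, rep(1.5, n / 10), tolerance = 1e-6)
  # 150 Hz (1.5x cutoff) attenuated below 5% by the bidirectional 6th order
  hi <- prep_for_coherence(sin(2 * pi * 150 * t), 2000, "evs")
  expect_lt(max(abs(hi$samples[100:900])), 0.05)
  # rectification precedes filtering on the EMG path
  emg <- prep_for_coherence(-abs(rnorm(n)), 2000, "emg")
  expect_gt(mean(emg$samples), 0)
  # up-sampling is refused; GRF path sums the belts
  expect_error(prep_for_coherence(rnorm(100), 100, "evs"), "refused")
  g <- prep_for_coherence(list(l = rep(1, 400), r = rep(2, 400)), 200, "grf")
  expect_equal(g$samples, rep(3, 400), tolerance = 1e-6)
})

test_that("stride segmentation pads, crops and round-trips exactly", {
  rate <- 200
  strikes <- uniform_strikes(8, stride = 1.5, t0 = 2)
  x <- rnorm(rate * 16)
  segs <- segment_strides(x, rate, strikes, pad_fraction = 0.5)
  expect_length(segs$segments, 6)          # first/last strides dropped
  expect_equal(lengths(segs$segments), 2L * segs$core_length)
  # pad 0: segment equals the stride exactly
  segs0 <- segment_strides(x, rate, strikes, pad_fraction = 0)
  expect_length(segs0$segments, 8)
  expect_equal(lengths(segs0$segments), segs0$core_length)
  # cropping pads and concatenating cores reproduces the source bit-exactly
  s2 <- round(strikes[2] * rate) + 1L
  s8 <- round(strikes[8] * rate)
  expect_identical(crop_and_concat(segs), x[s2:s8])
  expect_error(segment_strides(x, rate, strikes, n_strides = 10),
               "6 padded strides")
})

test_that("duration normalization maps all strides onto the average grid", {
  rate <- 200
  # two strides of 1.4 s and 1.6 s resample onto the 1.5 s grid
  strikes <- c(2, 3.4, 5.0)
  x <- rnorm(rate * 8)
  segs <- segment_strides(x, rate, strikes, pad_fraction = 0)
  nd <- normalize_durations(segs)
  expect_equal(unique(nd$core_length), round(1.5 * rate))
  expect_equal(unique(nd$durations), 1.5)
  # equal durations: identity
  segs_eq <- segment_strides(x, rate, uniform_strikes(3, 1.5, 2), 0)
  nd_eq <- normalize_durations(segs_eq)
  expect_equal(nd_eq$segments, segs_eq$segments)
})

test_that("stride-time jitter does not distort the coherence map", {
  # same continuous signals, segmented with uniform vs 2%-jittered strike
  # times: after duration normalization the maps agree closely
  set.seed(77)
  rate <- 200; nseg <- 48; stride <- 1.5
  n <- round((nseg + 4) * stride * rate)
  strikes_u <- uniform_strikes(nseg + 2, stride, t0 = 1.5)
  strikes_j <- strikes_u + pmin(pmax(rnorm(nseg + 3, sd = 0.02 * stride),
                                     -0.2), 0.2)
  t <- (seq_len(n) - 1) / rate
  x <- rnorm(n)
  y <- phase_gate(t, strikes_u, 0.5, 0.4) * x + 0.5 * rnorm(n)
  freqs <- seq(2, 20, by = 1)
  map_u <- coherence_map(stride_averaged_spectra(
    segment_strides(x, rate, strikes_u, 0.5),
    segment_strides(y, rate, strikes_u, 0.5), freqs))
  map_j <- coherence_map(stride_averaged_spectra(
    segment_strides(x, rate, strikes_j, 0.5),
    segment_strides(y, rate, strikes_j, 0.5), freqs))
  expect_lt(sqrt(mean((map_u$values - map_j$values)^2)), 0.02)
})
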