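test_that("Morlet transform has a flat ridge at a sinusoid's frequency", {
  rate <- 200
  t <- (0:(rate * 10 - 1)) / rate
  x <- sin(2 * pi * 8 * t)
  freqs <- seq(2, 20, by = 1)
  W <- morlet_cwt(x, rate, freqs)
  mid <- 400:1600
  prof <- colMeans(Mod(W[mid, ])^2)
  expect_equal(freqs[which.max(prof)], 8)
  ridge <- Mod(W[mid, freqs == 8])
  expect_lt(sd(ridge) / mean(ridge), 0.01)   # flat away from edges
})

test_that("Morlet transform is linear and refuses super-Nyquist frequencies", {
  rate <- 200
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500)
  freqs <- c(5, 10)
  expect_equal(morlet_cwt(x + y, rate, freqs),
               morlet_cwt(x, rate, freqs) + morlet_cwt(y, rate, freqs),
               tolerance = 1e-12)
  expect_error(morlet_cwt(x, rate, c(5, 120)), "Nyquist")
  expect_error(morlet_cwt(c(x, NA), rate, 5), "finite")
})

test_that("a unit impulse returns the analytic wavelet at each scale", {
  rate <- 200; n <- 2000; k0 <- 1000; omega0 <- 6
  x <- numeric(n); x[k0] <- 1
  freqs <- c(2, 8)
  W <- morlet_cwt(x, rate, freqs, omega0)
  dt <- 1 / rate
  for (j in seq_along(freqs)) {
    s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs[j])
    tau <- ((1:n) - k0) * dt
    # closed-form inverse transform of the energy-normalized Morlet window
    oracle <- sqrt(2 * pi * s / dt) * pi^(-0.25) * dt / (s * sqrt(2 * pi)) *
      exp(-tau^2 / (2 * s^2)) * exp(1i * omega0 * tau / s)
    expect_lt(max(Mod(W[, j] - oracle)), 1e-6 * max(Mod(oracle)))
  }
})

test_that("stride-averaged spectra honour identity and degenerate cases", {
  rate <- 200
  strikes <- uniform_strikes(6, 1.5, 2)
  set.seed(3)
  x <- rnorm(rate * 13)
  xs <- segment_strides(x, rate, strikes, 0.5)
  freqs <- seq(2, 20, 2)
  sp <- stride_averaged_spectra(xs, xs, freqs)
  expect_equal(sp$Pxy, sp$Pxx + 0i, tolerance = 1e-10)
  expect_equal(sp$Pxx, sp$Pyy, tolerance = 1e-12)
  expect_true(all(sp$Pxx >= 0))
  # Cauchy-Schwarz after averaging
  y <- rnorm(rate * 13)
  sp2 <- stride_averaged_spectra(xs, segment_strides(y, rate, strikes, 0.5),
                                 freqs)
  expect_true(all(Mod(sp2$Pxy)^2 <= sp2$Pxx * sp2$Pyy * (1 + 1e-12)))
  # single stride: |Pxy|^2 = Pxx * Pyy exactly. The stride-phase grid is
  # set to the native stride sampling: at interpolated points the equality
  # is only approximate (convexity), on the native grid it is exact.
  xs1 <- segment_strides(x, rate, strikes, 0.5, n_strides = 1)
  ys1 <- segment_strides(y, rate, strikes, 0.5, n_strides = 1)
  sp1 <- stride_averaged_spectra(xs1, ys1, freqs,
                                 n_tau = xs1$core_length[1])
  expect_equal(Mod(sp1$Pxy)^2, sp1$Pxx * sp1$Pyy, tolerance = 1e-10)
  expect_error(stride_averaged_spectra(xs, ys1, freqs), "mismatched")
})

test_that("independent signals give coherence near the 1/N bias", {
  rate <- 200; nseg <- 256
  strikes <- uniform_strikes(nseg + 2, 1.5, 2)
  n <- round((nseg + 6) * 1.5 * rate)
  set.seed(4)
  sp <- stride_averaged_spectra(
    segment_strides(rnorm(n), rate, strikes, 0.5),
    segment_strides(rnorm(n), rate, strikes, 0.5),
    freqs = seq(3, 24, by = 1.5), n_tau = 51)
  C <- coherence_map(sp)
  expect_gt(mean(C$values), 0.5 / nseg)
  expect_lt(mean(C$values), 2 / nseg)
})

test_that("coherence and gain reproduce linear-system closed forms", {
  rate <- 200
  strikes <- uniform_strikes(64, 1.5, 2)
  n <- round(70 * 1.5 * rate)
  set.seed(6)
  x <- rnorm(n)
  xs <- segment_strides(x, rate, strikes, 0.5)
  freqs <- seq(2, 24, by = 1)
  # y = 2x: gain 2 and coherence 1 everywhere
  sp <- stride_averaged_spectra(xs, segment_strides(2 * x, rate, strikes, 0.5),
                                freqs)
  expect_equal(unname(gain_map(sp)$values),
               matrix(2, length(sp$tau), length(freqs)), tolerance = 1e-10)
  expect_equal(min(coherence_map(sp)$values), 1, tolerance = 1e-10)
  # pure (short) delay: all-pass gain ~1 in band. The delay must be small
  # against the wavelet length: time-frequency gain decays with the
  # coefficient autocorrelation at the delay lag.
  yd <- c(rep(0, 2), x)[seq_len(n)]
  spd <- stride_averaged_spectra(xs, segment_strides(yd, rate, strikes, 0.5),
                                 freqs)
  mid <- freqs >= 4 & freqs <= 20
  expect_equal(mean(gain_map(spd)$values[, mid]), 1, tolerance = 0.05)
  # known FIR: recovered gain matches |H(f)| mid-band
  h <- default_evs_kernel()
  yh <- vestigait:::fir_filter(x, h)
  sph <- stride_averaged_spectra(xs, segment_strides(yh, rate, strikes, 0.5),
                                 freqs)
  H <- Mod(fft(c(h, rep(0, 4096 - length(h)))))
  fH <- (seq_len(4096) - 1) * rate / 4096
  Hf <- approx(fH[1:2048], H[1:2048], xout = freqs)$y
  Gf <- colMeans(gain_map(sph)$values)
  expect_lt(max(abs(Gf[mid] - Hf[mid]) / Hf[mid]), 0.05)
})

test_that("coherence is scale-invariant while gain scales linearly", {
  rate <- 200
  strikes <- uniform_strikes(16, 1.5, 2)
  n <- round(20 * 1.5 * rate)
  set.seed(8)
  x <- rnorm(n); y <- vestigait:::fir_filter(x, default_evs_kernel()) +
    0.5 * rnorm(n)
  freqs <- seq(2, 20, 2)
  base <- stride_averaged_spectra(segment_strides(x, rate, strikes, 0.5),
                                  segment_strides(y, rate, strikes, 0.5),
                                  freqs)
  scaled <- stride_averaged_spectra(
    segment_strides(3 * x, rate, strikes, 0.5),
    segment_strides(5 * y, rate, strikes, 0.5), freqs)
  expect_equal(coherence_map(base)$values, coherence_map(scaled)$values,
               tolerance = 1e-10)
  expect_equal(gain_map(scaled)$values, gain_map(base)$values * 5 / 3,
               tolerance = 1e-10)
})

test_that("undefined grid points are flagged, never zero-filled", {
  sp <- structure(list(Pxx = matrix(c(0, 1, 1, 1), 2),
                       Pyy = matrix(c(1, 0, 1, 1), 2),
                       Pxy = matrix(c(0, 0, 0.5, 0.2) + 0i, 2),
                       tau = c(0, 1), freqs = c(5, 10), n_strides = 8),
                  class = "spectra_set")
  C <- coherence_map(sp)
  expect_true(is.na(C$values[1, 1]) && is.na(C$values[2, 1]))
  G <- gain_map(sp)
  expect_true(is.na(G$values[1, 1]) && is.finite(G$values[2, 1]))
})

test_that("the analytic significance bound matches its closed form", {
  expect_equal(significance_threshold(2, 0.05), 0.95)
  expect_equal(significance_threshold(100, 0.05), 1 - 0.05^(1 / 99))
  expect_error(significance_threshold(1, 0.05), "n_strides")
  expect_error(significance_threshold(10, 1.2), "alpha")
})

test_that("null exceedance at N = 64 stays near the nominal alpha", {
  rate <- 200; nseg <- 64
  strikes <- uniform_strikes(nseg + 2, 1.5, 2)
  n <- round((nseg + 6) * 1.5 * rate)
  set.seed(9)
  sp <- stride_averaged_spectra(
    segment_strides(rnorm(n), rate, strikes, 0.5),
    segment_strides(rnorm(n), rate, strikes, 0.5),
    freqs = seq(3, 24, by = 1.5), n_tau = 51)
  C <- coherence_map(sp, alpha = 0.05)
  rate_exc <- mean(C$values > significance_threshold(nseg, 0.05))
  expect_gt(rate_exc, 0.01)
  expect_lt(rate_exc, 0.12)
})
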