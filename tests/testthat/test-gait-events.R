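test_that("centre of pressure is the moment-to-force ratio", {
  f <- data.frame(fx = 0, fy = 0, fz = 700,
                  mx = -0.05 * 700, my = -0.1 * 700)
  cop <- compute_cop(f)
  expect_equal(cop$x, 0.1)
  expect_equal(cop$y, -0.05)

  # two equal point loads at x = +/- 0.1 m: net CoP x = 0
  f2 <- data.frame(fx = 0, fy = 0, fz = 1400,
                   mx = 0, my = -(0.1 * 700) - (-0.1 * 700))
  expect_equal(compute_cop(f2)$x, 0)

  # below the force floor: flagged undefined / no-contact error
  f3 <- data.frame(fx = 0, fy = 0, fz = c(700, 5), mx = 0, my = c(-70, 0))
  cop3 <- compute_cop(f3)
  expect_true(is.na(cop3$x[2]) && !cop3$defined[2])
  expect_error(compute_cop(data.frame(fx = 0, fy = 0, fz = 1, mx = 0,
                                      my = 0)), "no contact")
})

test_that("CoP of a simulated trial tracks the stance foot within 5 mm", {
  tr <- small_trial()
  cop <- compute_cop(tr$forces_left, floor = 100)
  t200 <- (seq_len(nrow(tr$forces_left)) - 1) / tr$rates$forces
  t100 <- (seq_len(nrow(tr$markers$heel_left)) - 1) / tr$rates$markers
  foot_ml <- approx(t100, tr$markers$heel_left$x, xout = t200, rule = 2)$y
  ok <- cop$defined
  expect_lt(sqrt(mean((cop$x[ok] - foot_ml[ok])^2)), 0.005)
})

test_that("clean per-belt forces give heel strikes within 10 ms of truth", {
  tr <- small_trial()
  ev <- small_events()
  expect_identical(ev$method, "per_belt")
  err_l <- vapply(ev$heel_strikes_left, function(t0)
    min(abs(t0 - tr$truth$heel_strikes_left)), numeric(1))
  err_r <- vapply(ev$heel_strikes_right, function(t0)
    min(abs(t0 - tr$truth$heel_strikes_right)), numeric(1))
  expect_lt(max(err_l, err_r), 0.010)
})

test_that("a constant standing load yields an explicit empty event set", {
  n <- 200 * 10
  standing <- list(
    forces_left = data.frame(fx = 0, fy = 0, fz = rep(350, n),
                             mx = 0, my = rep(-35, n)),
    forces_right = data.frame(fx = 0, fy = 0, fz = rep(350, n),
                              mx = 0, my = rep(35, n)),
    rates = list(forces = 200), belts_separated = TRUE)
  ev <- detect_heel_strikes(standing)
  expect_length(ev$heel_strikes_left, 0)
  expect_length(ev$heel_strikes_right, 0)
  expect_identical(ev$method, "none")
})

test_that("cross-stepping falls back to summed-CoP detection", {
  evs <- generate_evs(duration = 40, seed = 3)
  pre <- condition_preset("narrow")
  tr <- simulate_trial(evs, config = pre$config, n_strides = 20, seed = 5,
                       step_width_mean = pre$step_width_mean,
                       step_width_sd = pre$step_width_sd,
                       cross_step = TRUE, condition = "narrow")
  ev <- detect_heel_strikes(tr)
  expect_identical(ev$method, "cop_fallback")
  det <- sort(c(ev$heel_strikes_left, ev$heel_strikes_right))
  truth <- sort(c(tr$truth$heel_strikes_left, tr$truth$heel_strikes_right))
  hit <- vapply(truth, function(t0) min(abs(t0 - det)) < 0.020, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("stride times are same-foot first differences", {
  ev <- gait_events(c(0, 1.5, 3), c(0.75, 2.25))
  st <- compute_stride_times(ev)
  expect_equal(st$left, c(1.5, 1.5))
  expect_warning(compute_stride_times(gait_events(1.0, numeric(0))),
                 "fewer than 2")
})

test_that("metronome pacing is recovered from detected events", {
  # zero stride jitter: mean stride time = 2 * 60 / 78 s up to the force
  # sample grid
  evs <- generate_evs(duration = 30, seed = 21)
  tr <- simulate_trial(evs, n_strides = 15, seed = 22, stride_cv = 0)
  st <- compute_stride_times(detect_heel_strikes(tr))
  expect_equal(attr(st, "mean"), 2 * 60 / 78, tolerance = 0.004)
  # jittered simulation converges to the nominal cadence
  st_big <- compute_stride_times(big_events())
  expect_equal(attr(st_big, "mean"), 2 * 60 / 78, tolerance = 0.01)
})

test_that("left/right interleaving violations raise instead of reordering", {
  expect_error(gait_events(c(0, 1, 1.5), c(0.5, 2.0)), "interleave")
  expect_error(gait_events(c(1, 0.5), c(0.7)), "strictly increasing")
})

test_that("step widths match marker geometry and converge to the mean", {
  mk <- list(heel_left = data.frame(x = rep(-0.06, 500), y = 0, z = 0),
             heel_right = data.frame(x = rep(0.06, 500), y = 0, z = 0))
  ev <- gait_events(c(1, 2.5), c(1.75, 3.25))
  w <- compute_step_widths(ev, mk, rate = 100)
  expect_equal(w$width, rep(0.12, 4))
  mk0 <- list(heel_left = data.frame(x = rep(0.02, 500), y = 0, z = 0),
              heel_right = data.frame(x = rep(0.02, 500), y = 0, z = 0))
  expect_equal(compute_step_widths(ev, mk0, rate = 100)$width, rep(0, 4))

  tr <- big_trial()
  w <- compute_step_widths(big_events(), tr$markers, tr$rates$markers)
  expect_equal(mean(w$width, na.rm = TRUE), 0.18, tolerance = 0.005 / 0.18)
})
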