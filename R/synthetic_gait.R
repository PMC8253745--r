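# Synthetic walking trials with known, injected vestibulo-motor coupling.
#
# The simulator stands in for raw treadmill recordings: per-belt 3-axis force
# plate signals at 200 samples/s, surface EMG at 2000 samples/s, marker
# clusters (T6, pelvis, both heels) at 100 samples/s, and the applied EVS
# current. Coupling from EVS to each output is modelled as gated linear
# filtering: a phase-locked raised-cosine gate multiplies a band-limited FIR
# response to the stimulus, so the stride-phase, bandwidth and strength of the
# injected coupling are exactly known ground truth.

#' Default band-limited EVS response kernel
#'
#' A biphasic, causal finite impulse response (150 ms support, energy
#' concentrated below ~20 Hz and within the first ~50 ms, unit energy)
#' linking the vestibular stimulus to a motor output. The short group delay
#' (~28 ms) keeps the time-frequency localization of the injected coupling
#' close to the phase gate: wavelet cross-spectra place coupled energy
#' between the stimulus and response times, so a long-latency kernel would
#' bias recovered gate phases early by roughly the kernel delay.
#'
#' @param rate sampling rate of the kernel (samples/s).
#' @return numeric vector of FIR coefficients with unit energy.
#' @export
default_evs_kernel <- function(rate = 200) {
  t <- seq(0, 0.15, by = 1 / rate)
  h <- sin(2 * pi * 8 * t) * exp(-((t - 0.025) / 0.025)^2)
  h / sqrt(sum(h^2))
}

#' Per-channel vestibulo-motor coupling configuration
#'
#' Describes how the EVS couples into one output channel: a raised-cosine
#' stride-phase gate (`gate_center`, `gate_width`), a linear FIR `kernel`
#' applied to the stimulus, an overall `gain`, a transmission `delay`, and
#' additive/multiplicative output `noise_sd`.
#'
#' @param gate_center stride fraction in `[0, 1)` at which coupling peaks.
#' @param gate_width stride fraction in `(0, 1]`: full support of the gate.
#' @param gain dimensionless coupling scale (>= 0); 0 disables coupling.
#' @param delay transmission delay in seconds (>= 0).
#' @param kernel FIR impulse response at the force-plate rate (200 samples/s).
#' @param noise_sd output noise standard deviation (output units).
#' @return a list of class `channel_coupling`.
#' @export
coupling_config <- function(gate_center = 0.5, gate_width = 0.4, gain = 0.2,
                            delay = 0.01, kernel = default_evs_kernel(),
                            noise_sd = 0.1) {
  if (gate_center < 0 || gate_center >= 1) stop("gate_center must be in [0, 1)")
  if (gate_width <= 0 || gate_width > 1) stop("gate_width must be in (0, 1]")
  if (gain < 0) stop("gain must be >= 0")
  if (delay < 0) stop("delay must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(is.finite(kernel))) stop("kernel energy must be finite")
  structure(list(gate_center = gate_center, gate_width = gate_width,
                 gain = gain, delay = delay, kernel = kernel,
                 noise_sd = noise_sd),
            class = "channel_coupling")
}

#' Default study coupling configuration
#'
#' One [coupling_config()] per simulated output channel: the three bilateral
#' muscles (medial gastrocnemius — coupling in mid/late stance; gluteus
#' medius — just before contralateral heel strike; erector spinae — around
#' heel strike) and the net mediolateral ground reaction force. Gate phases
#' are expressed relative to the ipsilateral heel strike.
#'
#' @param gain_scale multiplier applied to every channel's gain (conditions
#'   with reduced stabilization demand use values < 1).
#' @param muscle_gains optional named numeric vector of per-channel gain
#'   multipliers (names among `gastrocnemius`, `gluteus_medius`,
#'   `erector_spinae`, `grf_ml`), applied on top of `gain_scale`.
#' @return named list of `channel_coupling` objects.
#' @export
default_coupling <- function(gain_scale = 1, muscle_gains = NULL) {
  cfg <- list(
    gastrocnemius  = coupling_config(gate_center = 0.40, gate_width = 0.45,
                                     gain = 0.25, noise_sd = 0.30),
    gluteus_medius = coupling_config(gate_center = 0.90, gate_width = 0.40,
                                     gain = 0.25, noise_sd = 0.30),
    erector_spinae = coupling_config(gate_center = 0.02, gate_width = 0.35,
                                     gain = 0.20, noise_sd = 0.30),
    grf_ml         = coupling_config(gate_center = 0.30, gate_width = 0.80,
                                     gain = 8, noise_sd = 6)
  )
  for (nm in names(cfg)) {
    mult <- gain_scale
    if (!is.null(muscle_gains) && nm %in% names(muscle_gains)) {
      mult <- mult * muscle_gains[[nm]]
    }
    cfg[[nm]]$gain <- cfg[[nm]]$gain * mult
  }
  cfg
}

#' Stride phase of arbitrary times
#'
#' Piecewise-linear stride phase relative to a strictly increasing sequence of
#' (same-foot) heel-strike times; extrapolated with the first/last stride
#' duration outside the event span.
#'
#' @param t times (s).
#' @param events strictly increasing heel-strike times (s) of one foot.
#' @return stride phase in `[0, 1)` for each element of `t`.
#' @keywords internal
#' @noRd
phase_of_time <- function(t, events) {
  if (length(events) < 2) stop("need at least 2 events to define stride phase")
  if (is.unsorted(events, strictly = TRUE)) {
    stop("events must be strictly increasing")
  }
  k <- findInterval(t, events)
  k <- pmin(pmax(k, 1L), length(events) - 1L)
  phi <- (k - 1) + (t - events[k]) / (events[k + 1L] - events[k])
  phi - floor(phi)
}

#' Raised-cosine stride-phase gate
#'
#' A smooth periodic window over the stride cycle: value 1 at `center`,
#' falling to 0 at `center +/- width / 2` (phase wrapped), 0 outside. The
#' integral of the gate over one stride of duration `T` is `width / 2 * T`.
#'
#' @param t times (s) within the recording span.
#' @param events strictly increasing heel-strike times (s) of the reference
#'   foot (at least 2).
#' @param center stride fraction in `[0, 1)` of the gate maximum.
#' @param width stride fraction in `(0, 1]`: full support of the gate.
#' @return gate values in `[0, 1]`, same length as `t`.
#' @examples
#' ev <- c(0, 1, 2)
#' phase_gate(0.5, ev, center = 0.5, width = 0.2)  # 1 at the gate centre
#' phase_gate(0.0, ev, center = 0.5, width = 0.2)  # 0 opposite the gate
#' @export
phase_gate <- function(t, events, center, width) {
  if (center < 0 || center >= 1) stop("center must be in [0, 1)")
  if (width <= 0 || width > 1) stop("width must be in (0, 1]")
  phi <- phase_of_time(t, events)
  d <- phi - center
  d <- d - round(d)                      # wrap to [-0.5, 0.5)
  ifelse(abs(d) <= width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

# Wrapped raised-cosine bump used for phasic baseline envelopes.
phase_bump <- function(phi, center, width) {
  d <- phi - center
  d <- d - round(d)
  ifelse(abs(d) <= width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

# Phasic baseline EMG envelopes (a.u.), qualitative shapes only: medial
# gastrocnemius peaks in late stance (~45-50% of the ipsilateral stride),
# gluteus medius just after ipsilateral heel strike (~15-20%), erector spinae
# is bimodal with bursts around both heel strikes.
baseline_envelope <- function(muscle, phi) {
  switch(muscle,
    gastrocnemius  = 0.15 + 1.0 * phase_bump(phi, 0.47, 0.45),
    gluteus_medius = 0.15 + 0.9 * phase_bump(phi, 0.17, 0.40),
    erector_spinae = 0.20 + 0.8 * phase_bump(phi, 0.03, 0.25) +
                            0.8 * phase_bump(phi, 0.53, 0.25),
    stop("unknown muscle: ", muscle)
  )
}

#' Simulate a noise-driven trunk-velocity limit cycle
#'
#' A planar stable limit-cycle oscillator whose dynamical noise perturbs the
#' phase velocity (stride-timing noise) and, more weakly, the radial state;
#' the mediolateral velocity component is returned. Phase perturbations are
#' not corrected by the radial relaxation, so neighbouring trajectories
#' diverge along the cycle at a rate proportional to `noise_sd` while the
#' attractor geometry itself stays fixed: the local divergence exponent
#' increases monotonically with `noise_sd`. With `noise_sd = 0` the output
#' is a noiseless periodic orbit (divergence exponent numerically ~0).
#'
#' @param n_strides number of strides (>= 10).
#' @param samples_per_stride samples per stride cycle.
#' @param noise_sd dynamical noise SD in output units (m/s), >= 0.
#' @param seed optional integer seed.
#' @param amplitude limit-cycle velocity amplitude (m/s).
#' @param contraction radial relaxation rate per sample (stability of the
#'   orbit; larger pulls radially perturbed trajectories back faster).
#' @return numeric vector of length `n_strides * samples_per_stride` (m/s).
#' @export
simulate_t6_series <- function(n_strides, samples_per_stride = 100,
                               noise_sd = 0.05, seed = NULL,
                               amplitude = 0.15, contraction = 0.05) {
  if (n_strides < 10) stop("n_strides must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- n_strides * samples_per_stride
  dlt <- 2 * pi / samples_per_stride
  sig <- noise_sd / amplitude            # noise in state (unit-cycle) units
  eps <- with_seed(seed, matrix(stats::rnorm(2L * n, sd = max(sig, 0)), 2L, n))
  if (sig == 0) eps[] <- 0
  out <- numeric(n)
  theta <- 0; r <- 1
  for (i in seq_len(n)) {
    theta <- theta + dlt * (1 + 0.35 * eps[1L, i])  # phase-velocity noise
    r <- r + contraction * (1 - r) + 0.3 * dlt * eps[2L, i]
    out[i] <- amplitude * r * cos(theta)
  }
  out
}

#' Simulate a complete walking trial
#'
#' Generates a synchronized multirate recording of metronome-paced treadmill
#' walking under continuous EVS, with known (stored) ground truth: heel-strike
#' times, step widths, and the phase-gated linear EVS coupling injected into
#' each EMG channel and the mediolateral ground reaction force.
#'
#' Streams produced:
#' \itemize{
#'   \item `forces_left` / `forces_right`: per-belt `fx` (mediolateral,
#'     rightward +), `fy` (anteroposterior), `fz` (vertical, >= 0) in N and
#'     plate moments `mx`, `my` (N m) at 200 samples/s.
#'   \item `emg`: six channels (`<muscle>_left` / `<muscle>_right`) in a.u. at
#'     2000 samples/s, built as phasic baseline envelope x (1 + noise) +
#'     gain x gate(phase) x (kernel * EVS)(t - delay), half-wave floored at 0.
#'   \item `markers`: T6, pelvis and both heel cluster centroids (m, x = ML)
#'     at 100 samples/s; T6 integrates a noise-driven limit-cycle velocity
#'     whose divergence grows with `t6_noise_sd`.
#' }
#'
#' @param evs an [generate_evs()] signal (resampled to 200 samples/s if
#'   needed); must cover at least `(n_strides + 3)` stride periods.
#' @param config named list of [coupling_config()]s as from
#'   [default_coupling()].
#' @param n_strides number of complete strides to simulate (>= 2).
#' @param cadence metronome cadence in steps/min (two steps per stride).
#' @param step_width_mean,step_width_sd step-width distribution (m).
#' @param t6_noise_sd dynamical noise of the trunk oscillator (m/s).
#' @param seed integer seed; one global seed fans out to per-stream substreams.
#' @param condition condition label stored with the trial.
#' @param cross_step if `TRUE` (narrow-base walking), each foot's load is
#'   split across both belts according to its mediolateral position, so
#'   per-belt event detection is unreliable and analyses must use the summed
#'   plates.
#' @param stride_cv coefficient of variation of stride-time jitter.
#' @param belt_speed treadmill belt speed (m/s), used for CoP progression.
#' @param body_weight participant weight (N) scaling vertical forces.
#' @return an object of class `trial_recording`.
#' @export
simulate_trial <- function(evs, config = default_coupling(), n_strides,
                           cadence = 78, step_width_mean = 0.27,
                           step_width_sd = 0.02, t6_noise_sd = 0.08,
                           seed = NULL, condition = "normal",
                           cross_step = FALSE, stride_cv = 0.02,
                           belt_speed = 0.8, body_weight = 700) {
  stopifnot(inherits(evs, "evs_signal"))
  if (n_strides < 2) stop("n_strides must be >= 2")
  if (cadence <= 0) stop("cadence must be positive")
  T_nom <- 2 * 60 / cadence
  need <- (n_strides + 3) * T_nom
  if (evs$duration < need) {
    stop(sprintf(
      "EVS signal too short: %.1f s available, %.1f s needed for %d strides",
      evs$duration, need, n_strides))
  }
  seeds <- substream_seeds(seed,
    c("events", "widths", "t6", "emg", "forces", "markers"))

  ## --- gait events -------------------------------------------------------
  stride_T <- with_seed(seeds[["events"]],
    T_nom * (1 + stride_cv * stats::rnorm(n_strides)))
  stride_T <- pmax(stride_T, 0.5 * T_nom)
  hs_left <- 1.5 * T_nom + c(0, cumsum(stride_T))      # n_strides + 1 strikes
  mid_jit <- with_seed(seeds[["events"]] + 1L,
    stats::rnorm(n_strides + 1L, sd = 0.005))
  hs_right <- hs_left + 0.5 * c(stride_T, T_nom) + mid_jit
  stance_frac <- 0.65
  to_left <- hs_left[-length(hs_left)] + stance_frac * stride_T
  to_right <- hs_right + stance_frac *
    c(stride_T[-1], rep(stride_T[n_strides], 2L))

  duration <- min(hs_left[length(hs_left)] + 1.5 * T_nom, evs$duration)
  f_rate <- 200; e_rate <- 2000; m_rate <- 100
  n200 <- floor(duration * f_rate); t200 <- (seq_len(n200) - 1) / f_rate
  n2000 <- floor(duration * e_rate); t2000 <- (seq_len(n2000) - 1) / e_rate
  n100 <- floor(duration * m_rate); t100 <- (seq_len(n100) - 1) / m_rate

  evs200 <- if (evs$rate == f_rate) evs$samples else
    resample_to_rate(evs$samples, evs$rate, f_rate)
  evs200 <- evs200[seq_len(n200)]

  ## --- step widths and foot placements ----------------------------------
  strikes <- rbind(
    data.frame(time = hs_left, foot = "left"),
    data.frame(time = hs_right, foot = "right"))
  strikes <- strikes[order(strikes$time), ]
  widths <- with_seed(seeds[["widths"]],
    pmax(stats::rnorm(nrow(strikes), step_width_mean, step_width_sd), 0.01))
  pos_l <- -step_width_mean / 2; pos_r <- step_width_mean / 2
  place <- data.frame(time = strikes$time, foot = strikes$foot,
                      width = widths, ml = NA_real_, other_ml = NA_real_)
  for (i in seq_len(nrow(place))) {
    if (place$foot[i] == "left") {
      pos_l <- pos_r - place$width[i]
      place$ml[i] <- pos_l; place$other_ml[i] <- pos_r
    } else {
      pos_r <- pos_l + place$width[i]
      place$ml[i] <- pos_r; place$other_ml[i] <- pos_l
    }
    shift <- (pos_l + pos_r) / 2          # weak recentring; widths unaffected
    pos_l <- pos_l - shift; pos_r <- pos_r - shift
    place$ml[i] <- place$ml[i] - shift
    place$other_ml[i] <- place$other_ml[i] - shift
  }

  # Continuous foot ML trajectories: hold placement through stance, move
  # linearly to the next placement during swing.
  foot_ml_trace <- function(foot) {
    pl <- place[place$foot == foot, ]
    knot_t <- c(0)
    knot_x <- c(pl$ml[1])
    for (i in seq_len(nrow(pl))) {
      hold_end <- pl$time[i] +
        stance_frac * (if (i < nrow(pl)) pl$time[i + 1] - pl$time[i] else T_nom)
      knot_t <- c(knot_t, pl$time[i], hold_end)
      knot_x <- c(knot_x, pl$ml[i], pl$ml[i])
    }
    list(t = knot_t, x = knot_x)
  }
  tr_l <- foot_ml_trace("left"); tr_r <- foot_ml_trace("right")
  ml_left_100 <- stats::approx(tr_l$t, tr_l$x, xout = t100, rule = 2)$y
  ml_right_100 <- stats::approx(tr_r$t, tr_r$x, xout = t100, rule = 2)$y
  ml_left_200 <- stats::approx(tr_l$t, tr_l$x, xout = t200, rule = 2)$y
  ml_right_200 <- stats::approx(tr_r$t, tr_r$x, xout = t200, rule = 2)$y

  ## --- per-foot vertical force and CoP -----------------------------------
  # double-bump stance profile with a sharp loading transient at contact
  stance_profile <- function(s) {
    1.05 * (sin(pi * s) + 0.2 * sin(3 * pi * s)) +
      0.18 * exp(-((s - 0.02) / 0.018)^2)
  }
  foot_force <- function(hs, foot_ml_200) {
    fz <- numeric(n200); copx <- numeric(n200); copy <- numeric(n200)
    for (i in seq_along(hs)) {
      dur <- stance_frac * (if (i < length(hs)) hs[i + 1] - hs[i] else T_nom)
      idx <- which(t200 >= hs[i] & t200 < hs[i] + dur)
      if (!length(idx)) next
      s <- (t200[idx] - hs[i]) / dur
      fz[idx] <- fz[idx] + body_weight * stance_profile(s)
      copx[idx] <- foot_ml_200[idx]
      copy[idx] <- 0.4 + 0.25 * s - belt_speed * (t200[idx] - hs[i])
    }
    list(fz = fz, copx = copx, copy = copy)
  }
  fl <- foot_force(hs_left, ml_left_200)
  fr <- foot_force(hs_right, ml_right_200)

  ## --- coupled drives -----------------------------------------------------
  drive_for <- function(cc) {
    d <- fir_filter(evs200, cc$kernel)
    delay_signal(d, f_rate, cc$delay)
  }

  ## --- mediolateral forces (baseline + injected EVS coupling) ------------
  # Output noise is band-limited (it must survive the analysis anti-alias
  # filters to act as noise) and rescaled so noise_sd is the realized SD.
  band_noise <- function(n, rate, cutoff, sd_target, seed) {
    if (sd_target <= 0) return(numeric(n))
    z <- with_seed(seed, stats::rnorm(n))
    z <- zero_phase_lowpass(z, rate, cutoff, 4)
    z / stats::sd(z) * sd_target
  }

  g_grf <- config[["grf_ml"]]
  grf_noise <- band_noise(n200, f_rate, 30, g_grf$noise_sd,
                          seeds[["forces"]])
  ml_base_l <- 30 * (fl$fz / body_weight)        # stance-modulated baseline
  ml_base_r <- -30 * (fr$fz / body_weight)
  gate_grf <- phase_gate(t200, hs_left, g_grf$gate_center, g_grf$gate_width)
  coupled_ml <- g_grf$gain * gate_grf *
    zero_phase_lowpass(drive_for(g_grf), f_rate, 10, 4) + grf_noise
  share_l <- ifelse(fl$fz + fr$fz > 0, fl$fz / pmax(fl$fz + fr$fz, 1e-9), 0.5)
  fx_l <- ml_base_l + coupled_ml * share_l
  fx_r <- ml_base_r + coupled_ml * (1 - share_l)
  fy_l <- 15 * (fl$fz / body_weight); fy_r <- 15 * (fr$fz / body_weight)

  ## --- belt assignment (cross-stepping splits loads) ----------------------
  plate <- function(fzs, copxs, copys, fxs, fys) {
    fz <- Reduce(`+`, fzs)
    mx <- Reduce(`+`, Map(function(z, y) z * y, fzs, copys))
    my <- Reduce(`+`, Map(function(z, x) -z * x, fzs, copxs))
    data.frame(fx = Reduce(`+`, fxs), fy = Reduce(`+`, fys), fz = fz,
               mx = mx, my = my)
  }
  if (!cross_step) {
    forces_left <- plate(list(fl$fz), list(fl$copx), list(fl$copy),
                         list(fx_l), list(fy_l))
    forces_right <- plate(list(fr$fz), list(fr$copx), list(fr$copy),
                          list(fx_r), list(fy_r))
  } else {
    # Load of each foot splits across belts by its ML position: with feet
    # near the belt gap both plates are loaded throughout, so per-belt
    # signals no longer isolate single feet.
    p_l <- stats::plogis(ml_left_200 / 0.02)     # fraction on RIGHT belt
    p_r <- stats::plogis(ml_right_200 / 0.02)
    forces_left <- plate(
      list(fl$fz * (1 - p_l), fr$fz * (1 - p_r)),
      list(fl$copx, fr$copx), list(fl$copy, fr$copy),
      list(fx_l * (1 - p_l), fx_r * (1 - p_r)),
      list(fy_l * (1 - p_l), fy_r * (1 - p_r)))
    forces_right <- plate(
      list(fl$fz * p_l, fr$fz * p_r),
      list(fl$copx, fr$copx), list(fl$copy, fr$copy),
      list(fx_l * p_l, fx_r * p_r),
      list(fy_l * p_l, fy_r * p_r))
  }

  ## --- EMG ----------------------------------------------------------------
  muscles <- setdiff(names(config), "grf_ml")
  emg <- list()
  emg_seed <- seeds[["emg"]]
  for (m in muscles) {
    cc <- config[[m]]
    drive2000 <- stats::approx(t200, drive_for(cc), xout = t2000, rule = 2)$y
    for (side in c("left", "right")) {
      hs <- if (side == "left") hs_left else hs_right
      phi <- phase_of_time(t2000, hs)
      base <- baseline_envelope(m, phi)
      gate <- phase_gate(t2000, hs, cc$gate_center, cc$gate_width)
      emg_seed <- emg_seed + 1L
      noise <- band_noise(n2000, e_rate, 50, cc$noise_sd, emg_seed)
      emg[[paste0(m, "_", side)]] <-
        pmax(base * (1 + noise) + cc$gain * gate * drive2000, 0)
    }
  }

  ## --- markers ------------------------------------------------------------
  # The trunk oscillates with the stepping rhythm: generate the limit-cycle
  # velocity on a uniform per-stride grid, then warp it onto the actual
  # (jittered) stride times via the continuous left-stride phase.
  spstr <- round(m_rate * T_nom)
  k <- pmin(pmax(findInterval(t100, hs_left), 1L), length(hs_left) - 1L)
  phi_u <- (k - 1) + (t100 - hs_left[k]) / (hs_left[k + 1L] - hs_left[k])
  shift <- ceiling(-min(phi_u)) + 1
  n_str_t6 <- max(ceiling(max(phi_u) + shift) + 1L, 10L)
  v_ser <- simulate_t6_series(n_str_t6, samples_per_stride = spstr,
                              noise_sd = t6_noise_sd, seed = seeds[["t6"]])
  v_t6 <- stats::approx(seq_along(v_ser), v_ser,
                        xout = (phi_u + shift) * spstr + 1, rule = 2)$y
  t6_x <- cumsum(v_t6) / m_rate
  t6_x <- t6_x - mean(t6_x)
  mk_noise <- function(k, sd = 1e-4) with_seed(seeds[["markers"]] + k,
    stats::rnorm(n100, sd = sd))
  markers <- list(
    t6 = data.frame(x = t6_x, y = mk_noise(1L), z = 1.4 + mk_noise(2L)),
    pelvis = data.frame(x = 0.6 * t6_x + mk_noise(3L),
                        y = mk_noise(4L), z = 1.0 + mk_noise(5L)),
    heel_left = data.frame(x = ml_left_100 + mk_noise(6L),
                           y = stats::approx(c(0, hs_left), c(0.4, rep(0.4,
                             length(hs_left))), xout = t100, rule = 2)$y,
                           z = 0.05 + mk_noise(7L)),
    heel_right = data.frame(x = ml_right_100 + mk_noise(8L),
                            y = 0.4 + mk_noise(9L),
                            z = 0.05 + mk_noise(10L))
  )

  truth <- list(
    heel_strikes_left = hs_left, heel_strikes_right = hs_right,
    toe_offs_left = to_left, toe_offs_right = to_right,
    step_widths = place[, c("time", "foot", "width")],
    config = config, seed = seed, t6_noise_sd = t6_noise_sd,
    step_width_mean = step_width_mean, step_width_sd = step_width_sd
  )
  structure(
    list(evs = evs200, evs_rate = f_rate,
         forces_left = forces_left, forces_right = forces_right,
         emg = emg, markers = markers,
         rates = list(forces = f_rate, emg = e_rate, markers = m_rate),
         condition = condition, stride_period = T_nom, cadence = cadence,
         n_strides = n_strides, duration = duration,
         belts_separated = !cross_step, truth = truth),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording>", x$condition, "walking\n")
  cat(sprintf("  %d strides @ %g steps/min (stride %.3f s), %.1f s total\n",
              x$n_strides, x$cadence, x$stride_period, x$duration))
  cat(sprintf("  streams: forces 2 belts @%d Hz, EMG %d ch @%d Hz, markers %d @%d Hz\n",
              x$rates$forces, length(x$emg), x$rates$emg,
              length(x$markers), x$rates$markers))
  cat(sprintf("  belts separated: %s; ground truth: %s\n",
              x$belts_separated, !is.null(x$truth)))
  invisible(x)
}

#' Condition presets mirroring the four study walking conditions
#'
#' Returns simulator settings for `normal`, `stabilized` (external lateral
#' stabilization: narrower steps, calmer trunk dynamics, reduced vestibular
#' coupling), `wide` (wider steps, reduced coupling) and `narrow` (narrower
#' steps, calmer trunk, cross-stepping onto both belts, muscle-specific
#' coupling changes: erector spinae up, gastrocnemius down, net GRF up).
#'
#' @param condition one of `"normal"`, `"stabilized"`, `"wide"`, `"narrow"`.
#' @return list of arguments understood by [simulate_trial()].
#' @export
condition_preset <- function(condition = c("normal", "stabilized",
                                           "wide", "narrow")) {
  condition <- match.arg(condition)
  switch(condition,
    normal = list(condition = "normal", step_width_mean = 0.27,
                  step_width_sd = 0.02, t6_noise_sd = 0.08,
                  config = default_coupling(), cross_step = FALSE),
    stabilized = list(condition = "stabilized", step_width_mean = 0.09,
                      step_width_sd = 0.012, t6_noise_sd = 0.03,
                      config = default_coupling(gain_scale = 0.35),
                      cross_step = FALSE),
    wide = list(condition = "wide", step_width_mean = 0.35,
                step_width_sd = 0.025, t6_noise_sd = 0.09,
                config = default_coupling(gain_scale = 0.55),
                cross_step = FALSE),
    narrow = list(condition = "narrow", step_width_mean = 0.16,
                  step_width_sd = 0.015, t6_noise_sd = 0.055,
                  config = default_coupling(muscle_gains = c(
                    gastrocnemius = 0.6, gluteus_medius = 1.0,
                    erector_spinae = 1.8, grf_ml = 1.4)),
                  cross_step = TRUE)
  )
}
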