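# Heel-strike / toe-off extraction and spatiotemporal gait parameters.

#' Centre of pressure from force-plate signals
#'
#' CoP is the moment-to-force ratio per horizontal axis (`x = -my / fz`,
#' `y = mx / fz`, z-up convention with moments about the plate origin),
#' evaluated only where the vertical force exceeds `floor`; other samples are
#' returned as `NA` and flagged, never silently interpolated.
#'
#' @param forces data frame with columns `fx`, `fy`, `fz`, `mx`, `my`.
#' @param floor minimum vertical force (N) for the CoP to be defined.
#' @return data frame with columns `x`, `y` (m) and logical `defined`.
#' @examples
#' f <- data.frame(fx = 0, fy = 0, fz = 700, mx = -0.05 * 700,
#'                 my = -0.1 * 700)
#' compute_cop(f)   # CoP at (0.1, -0.05)
#' @export
compute_cop <- function(forces, floor = 20) {
  stopifnot(all(c("fz", "mx", "my") %in% names(forces)))
  ok <- forces$fz > floor
  if (!any(ok)) stop("no contact: vertical force never exceeds the floor (",
                     floor, " N)")
  x <- ifelse(ok, -forces$my / forces$fz, NA_real_)
  y <- ifelse(ok, forces$mx / forces$fz, NA_real_)
  data.frame(x = x, y = y, defined = ok)
}

# Rising/falling threshold crossings with a refractory period (seconds).
threshold_crossings <- function(fz, rate, thr, refractory = 0.2) {
  above <- fz > thr
  d <- diff(above)
  rise <- which(d == 1L) + 1L
  fall <- which(d == -1L) + 1L
  keep_refractory <- function(idx) {
    if (!length(idx)) return(idx)
    out <- idx[1]
    for (i in idx[-1]) if ((i - out[length(out)]) / rate >= refractory) {
      out <- c(out, i)
    }
    out
  }
  list(rise = keep_refractory(rise), fall = keep_refractory(fall))
}

# Per-belt force-threshold event detection for one foot.
detect_belt_events <- function(fz, rate, threshold_frac = 0.05,
                               refractory = 0.2) {
  # first pass with a coarse threshold to find stance peaks
  coarse <- threshold_crossings(fz, rate, 0.2 * max(fz), refractory)
  if (length(coarse$rise) < 2) {
    return(list(heel_strikes = numeric(0), toe_offs = numeric(0)))
  }
  peaks <- vapply(seq_along(coarse$rise), function(i) {
    to <- coarse$fall[coarse$fall > coarse$rise[i]][1]
    if (is.na(to)) to <- length(fz)
    max(fz[coarse$rise[i]:to])
  }, numeric(1))
  thr <- threshold_frac * stats::median(peaks)
  cr <- threshold_crossings(fz, rate, thr, refractory)
  list(heel_strikes = (cr$rise - 1) / rate, toe_offs = (cr$fall - 1) / rate)
}

#' Gait events container
#'
#' @param heel_strikes_left,heel_strikes_right strictly increasing times (s).
#' @param toe_offs_left,toe_offs_right times (s).
#' @param method detection method label.
#' @return object of class `gait_events`. Left/right heel strikes must
#'   interleave strictly; a violation raises an error rather than reordering.
#' @export
gait_events <- function(heel_strikes_left, heel_strikes_right,
                        toe_offs_left = numeric(0),
                        toe_offs_right = numeric(0), method = "manual") {
  for (v in list(heel_strikes_left, heel_strikes_right)) {
    if (length(v) > 1 && is.unsorted(v, strictly = TRUE)) {
      stop("heel-strike times must be strictly increasing")
    }
  }
  ev <- rbind(
    data.frame(time = heel_strikes_left,
               foot = rep("left", length(heel_strikes_left))),
    data.frame(time = heel_strikes_right,
               foot = rep("right", length(heel_strikes_right))))
  ev <- ev[order(ev$time), ]
  if (nrow(ev) > 1 && any(ev$foot[-1] == ev$foot[-nrow(ev)])) {
    stop("left and right heel strikes do not interleave strictly; ",
         "refusing to reorder events silently")
  }
  structure(list(heel_strikes_left = heel_strikes_left,
                 heel_strikes_right = heel_strikes_right,
                 toe_offs_left = toe_offs_left,
                 toe_offs_right = toe_offs_right,
                 method = method),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> method:", x$method, "\n")
  cat(sprintf("  heel strikes: %d left, %d right; toe-offs: %d left, %d right\n",
              length(x$heel_strikes_left), length(x$heel_strikes_right),
              length(x$toe_offs_left), length(x$toe_offs_right)))
  st <- unlist(suppressWarnings(compute_stride_times(x)))
  if (length(st)) cat(sprintf("  stride time: %.3f +/- %.3f s (%d strides)\n",
                              mean(st), stats::sd(st), length(st)))
  invisible(x)
}

#' Detect heel strikes and toe-offs from force-plate data
#'
#' Primary path: per-belt vertical-force threshold crossings (rising edge =
#' heel strike, falling edge = toe-off) at a threshold of `threshold_frac`
#' times the median peak stance force, with a refractory period. When
#' per-belt separation fails — e.g. narrow-base walking with cross-stepping
#' loads both belts continuously — the detector falls back to
#' anteroposterior CoP-excursion maxima of the summed force signal, with feet
#' assigned by the mediolateral CoP at each strike.
#'
#' @param recording a `trial_recording`, or a list with `forces_left`,
#'   `forces_right` data frames and `rates$forces`.
#' @param threshold_frac fraction of median peak stance force (default 5%).
#' @param refractory minimum time between successive events on a belt (s).
#' @return a [gait_events()] object; `method` records which path was used.
#' @export
detect_heel_strikes <- function(recording, threshold_frac = 0.05,
                                refractory = 0.2) {
  rate <- recording$rates$forces
  n <- nrow(recording$forces_left)
  if (n / rate < 3) stop("need at least 3 s of force data")
  ev_l <- detect_belt_events(recording$forces_left$fz, rate,
                             threshold_frac, refractory)
  ev_r <- detect_belt_events(recording$forces_right$fz, rate,
                             threshold_frac, refractory)
  per_belt_ok <- length(ev_l$heel_strikes) >= 3 &&
    length(ev_r$heel_strikes) >= 3 && {
      ev <- rbind(data.frame(time = ev_l$heel_strikes, foot = "left"),
                  data.frame(time = ev_r$heel_strikes, foot = "right"))
      ev <- ev[order(ev$time), ]
      mean(ev$foot[-1] != ev$foot[-nrow(ev)]) > 0.95  # strikes alternate
    }
  if (isTRUE(recording$belts_separated) && per_belt_ok) {
    return(gait_events(ev_l$heel_strikes, ev_r$heel_strikes,
                       ev_l$toe_offs, ev_r$toe_offs, method = "per_belt"))
  }

  ## fallback: summed-plate anterior CoP excursion extrema
  tot <- recording$forces_left
  for (cl in c("fx", "fy", "fz", "mx", "my")) {
    tot[[cl]] <- tot[[cl]] + recording$forces_right[[cl]]
  }
  cop <- compute_cop(tot)
  contact <- cop$defined & tot$fz > 0.3 * max(tot$fz)
  # standing (constant load, no CoP excursion): explicitly no gait events
  y_rng <- diff(range(cop$y[contact]))
  if (y_rng < 0.05) {
    return(gait_events(numeric(0), numeric(0), method = "none"))
  }
  y <- cop$y
  y[!contact] <- stats::median(y[contact])
  y <- zero_phase_lowpass(y, rate, 40, 2)
  y[!contact] <- NA
  refr_n <- round(refractory * rate)
  # a heel strike is the onset of the anterior CoP transfer to the newly
  # placed (forward) foot: the local minimum of the summed anterior CoP
  is_min <- which(diff(sign(diff(y))) == 2) + 1L
  is_min <- is_min[!is.na(y[is_min])]
  if (length(is_min) < 4) stop("insufficient data: fewer than 2 strides found")
  keep <- is_min[1]
  for (i in is_min[-1]) {
    if ((i - keep[length(keep)]) < refr_n) {
      if (y[i] < y[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  times <- (keep - 1) / rate
  # assign feet from the ML CoP once the striking foot has taken up load
  # (~0.15 s after contact the CoP sits under the new stance foot)
  ml <- cop$x[pmin(keep + round(0.15 * rate), length(cop$x))]
  side <- ifelse(ml - stats::median(ml, na.rm = TRUE) > 0, "right", "left")
  side[is.na(side)] <- "left"
  # enforce alternation by majority vote of parity
  par <- seq_along(side) %% 2
  right_even <- mean(side[par == 0] == "right") +
    mean(side[par == 1] == "left")
  if (right_even >= 1) {
    side <- ifelse(par == 0, "right", "left")
  } else {
    side <- ifelse(par == 0, "left", "right")
  }
  hs_l <- times[side == "left"]; hs_r <- times[side == "right"]
  if (length(hs_l) < 2 || length(hs_r) < 2) {
    stop("insufficient data: fewer than 2 strides per foot")
  }
  gait_events(hs_l, hs_r, method = "cop_fallback")
}

#' Stride times from gait events
#'
#' Stride time is the duration between two consecutive heel strikes of the
#' same foot (first differences per foot).
#'
#' @param events a [gait_events()] object.
#' @return list with numeric vectors `left` and `right` (s) plus attributes
#'   `mean` and `sd` over all strides.
#' @export
compute_stride_times <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  st <- list(left = diff(events$heel_strikes_left),
             right = diff(events$heel_strikes_right))
  if (!length(st$left) && !length(st$right)) {
    warning("fewer than 2 heel strikes on both feet; no stride times")
  }
  all <- c(st$left, st$right)
  attr(st, "mean") <- if (length(all)) mean(all) else NA_real_
  attr(st, "sd") <- if (length(all) > 1) stats::sd(all) else NA_real_
  st
}

#' Step widths at heel strikes
#'
#' At each heel strike, the step width is the absolute mediolateral distance
#' between the centroid of the striking foot's marker cluster and that of the
#' other foot, evaluated at the strike sample. Marker dropout (`NA`) at a
#' strike yields an `NA` width for that step.
#'
#' @param events a [gait_events()] object.
#' @param markers named list with `heel_left` and `heel_right` data frames
#'   (columns `x` = ML, `y`, `z`) as in a `trial_recording`.
#' @param rate marker sampling rate (samples/s).
#' @return data frame with `time`, `foot` and `width` (m).
#' @export
compute_step_widths <- function(events, markers, rate = 100) {
  stopifnot(inherits(events, "gait_events"))
  ev <- rbind(
    data.frame(time = events$heel_strikes_left, foot = "left"),
    data.frame(time = events$heel_strikes_right, foot = "right"))
  ev <- ev[order(ev$time), ]
  n <- nrow(markers$heel_left)
  idx <- pmin(pmax(round(ev$time * rate) + 1L, 1L), n)
  ml_l <- markers$heel_left$x[idx]
  ml_r <- markers$heel_right$x[idx]
  ev$width <- abs(ml_l - ml_r)
  ev
}
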