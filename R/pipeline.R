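# Study orchestration: simulate or load the four walking conditions, extract
# events, condition signals, compute coherence/gain and LDE, and compare
# conditions statistically.

# Full-precision CSV writer/reader (numeric columns survive a text
# round-trip bit-exactly).
write_csv17 <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      out[[cl]] <- format(out[[cl]], digits = 17, trim = TRUE,
                          scientific = TRUE)
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Order-insensitive cheap content hash used for provenance stamps.
config_hash <- function(x) {
  r <- as.integer(serialize(x, NULL, xdr = TRUE))
  h <- 2166136261
  for (chunk in split(r, ceiling(seq_along(r) / 4096))) {
    h <- (h + sum(chunk * (seq_along(chunk) %% 251 + 1))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write / load a trial recording as per-stream CSV files + JSON sidecar
#'
#' One directory per trial: `evs.csv`, `forces_left.csv`, `forces_right.csv`,
#' `emg.csv`, `markers.csv` and `sidecar.json` (rates, condition, seed,
#' ground truth when present). Loading validates stream lengths against the
#' declared rates; real-data directories without a `truth` block load with
#' `truth = NULL`.
#'
#' @param trial a `trial_recording`.
#' @param dir trial directory (created if missing).
#' @return `write_trial` returns `dir` invisibly; `load_recording` the
#'   reconstructed `trial_recording`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv17(data.frame(current_ma = trial$evs), file.path(dir, "evs.csv"))
  write_csv17(trial$forces_left, file.path(dir, "forces_left.csv"))
  write_csv17(trial$forces_right, file.path(dir, "forces_right.csv"))
  write_csv17(as.data.frame(trial$emg), file.path(dir, "emg.csv"))
  mk <- do.call(cbind, lapply(names(trial$markers), function(nm) {
    m <- trial$markers[[nm]]
    names(m) <- paste(nm, names(m), sep = "_")
    m
  }))
  write_csv17(mk, file.path(dir, "markers.csv"))
  truth <- trial$truth
  if (!is.null(truth)) {
    truth$config <- lapply(truth$config, unclass)
  }
  sidecar <- list(
    rates = trial$rates, evs_rate = trial$evs_rate,
    condition = trial$condition, stride_period = trial$stride_period,
    cadence = trial$cadence, n_strides = trial$n_strides,
    duration = trial$duration, belts_separated = trial$belts_separated,
    truth = truth
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trial
#' @export
load_recording <- function(dir) {
  needed <- c("evs.csv", "forces_left.csv", "forces_right.csv", "emg.csv",
              "markers.csv", "sidecar.json")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing)) {
    stop("missing stream files: ", paste(missing, collapse = ", "))
  }
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                            simplifyVector = TRUE)
  evs <- utils::read.csv(file.path(dir, "evs.csv"))$current_ma
  fl <- utils::read.csv(file.path(dir, "forces_left.csv"))
  fr <- utils::read.csv(file.path(dir, "forces_right.csv"))
  emg <- as.list(utils::read.csv(file.path(dir, "emg.csv")))
  mk_raw <- utils::read.csv(file.path(dir, "markers.csv"))
  clusters <- unique(sub("_[xyz]$", "", names(mk_raw)))
  markers <- lapply(clusters, function(nm) {
    stats::setNames(mk_raw[paste(nm, c("x", "y", "z"), sep = "_")],
                    c("x", "y", "z"))
  })
  names(markers) <- clusters

  problems <- character(0)
  check_len <- function(n, rate, what) {
    if (abs(n / rate - sc$duration) > 2 / rate) {
      problems <<- c(problems, sprintf(
        "%s: %d samples at %g samples/s does not match duration %.3f s",
        what, n, rate, sc$duration))
    }
  }
  check_len(nrow(fl), sc$rates$forces, "forces_left")
  check_len(nrow(fr), sc$rates$forces, "forces_right")
  check_len(length(emg[[1]]), sc$rates$emg, "emg")
  check_len(nrow(mk_raw), sc$rates$markers, "markers")
  check_len(length(evs), sc$evs_rate, "evs")
  if (length(problems)) {
    stop("trial validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  truth <- sc$truth
  if (!is.null(truth) && !is.null(truth$config)) {
    truth$config <- lapply(truth$config, function(cc) {
      structure(cc, class = "channel_coupling")
    })
  }
  structure(
    list(evs = evs, evs_rate = sc$evs_rate, forces_left = fl,
         forces_right = fr, emg = emg, markers = markers, rates = sc$rates,
         condition = sc$condition, stride_period = sc$stride_period,
         cadence = sc$cadence, n_strides = sc$n_strides,
         duration = sc$duration, belts_separated = sc$belts_separated,
         truth = truth),
    class = "trial_recording"
  )
}

#' EVS-output time-frequency coherence or gain for one trial channel
#'
#' Conditions the stimulus and the requested output channel
#' ([prep_for_coherence()]), segments both into padded stride segments
#' aligned on each limb's heel strikes ([segment_strides()]), computes
#' stride-averaged Morlet spectra and the coherence (or gain) map per limb
#' alignment, and averages the two maps (left/right pooling). The GRF path
#' sums both belts' mediolateral forces before filtering.
#'
#' @param trial a `trial_recording`.
#' @param channel `"grf_ml"` or a muscle name (`"gastrocnemius"`,
#'   `"gluteus_medius"`, `"erector_spinae"`).
#' @param events [gait_events()]; detected from the forces when `NULL`.
#' @param n_strides number of strides entering the average (default: all).
#' @param kind `"coherence"` or `"gain"`.
#' @param pool `"average"` pools the two limb alignments at the map level;
#'   `"left"` / `"right"` use a single alignment (`"none"` is an alias for
#'   `"left"`).
#' @param freqs,omega0,n_tau,pad_fraction,alpha analysis parameters.
#' @return a `tf_map`.
#' @export
evs_coherence <- function(trial, channel = "grf_ml", events = NULL,
                          n_strides = NULL,
                          kind = c("coherence", "gain"),
                          pool = c("average", "none", "left", "right"),
                          freqs = seq(0.5, 25, by = 0.25), omega0 = 6,
                          n_tau = 101, pad_fraction = 0.5, alpha = 0.01) {
  stopifnot(inherits(trial, "trial_recording"))
  kind <- match.arg(kind); pool <- match.arg(pool)
  if (is.null(events)) events <- detect_heel_strikes(trial)
  x <- prep_for_coherence(trial$evs, trial$evs_rate, "evs")
  sides <- switch(pool, average = c("left", "right"), right = "right",
                  "left")
  maps <- lapply(sides, function(side) {
    strikes <- if (side == "left") events$heel_strikes_left else
      events$heel_strikes_right
    if (channel == "grf_ml") {
      y <- prep_for_coherence(
        list(left = trial$forces_left$fx, right = trial$forces_right$fx),
        trial$rates$forces, "grf")
    } else {
      nm <- paste0(channel, "_", side)
      if (!nm %in% names(trial$emg)) stop("unknown EMG channel: ", nm)
      y <- prep_for_coherence(trial$emg[[nm]], trial$rates$emg, "emg")
    }
    xs <- segment_strides(x$samples, x$rate, strikes, pad_fraction, n_strides)
    ys <- segment_strides(y$samples, y$rate, strikes, pad_fraction, n_strides)
    sp <- stride_averaged_spectra(xs, ys, freqs, omega0, n_tau)
    if (kind == "coherence") coherence_map(sp, alpha) else gain_map(sp)
  })
  average_tf_maps(maps)
}

#' Study configuration for the full pipeline
#'
#' @param n_subjects number of simulated participants.
#' @param n_strides strides entering every per-trial analysis.
#' @param conditions subset of `c("normal", "stabilized", "wide", "narrow")`;
#'   `"normal"` must be first (it is the planned-comparison reference).
#' @param channels output channels analysed for coherence.
#' @param cadence metronome cadence (steps/min).
#' @param seed global study seed (fans out per subject/condition).
#' @param freqs,omega0,n_tau coherence analysis grid.
#' @param n_perm,cluster_alpha cluster permutation parameters.
#' @param lde_dim,lde_delay,lde_theiler,samples_per_stride LDE parameters.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_subjects = 11, n_strides = 256,
                         conditions = c("normal", "stabilized", "wide",
                                        "narrow"),
                         channels = c("grf_ml", "gastrocnemius",
                                      "gluteus_medius", "erector_spinae"),
                         cadence = 78, seed = 1,
                         freqs = seq(0.5, 25, by = 0.25), omega0 = 6,
                         n_tau = 101, n_perm = 5000, cluster_alpha = 0.05,
                         lde_dim = 5, lde_delay = 10, lde_theiler = 50,
                         samples_per_stride = 100) {
  if (conditions[1] != "normal") {
    stop("'normal' must be the first (reference) condition")
  }
  structure(
    list(n_subjects = n_subjects, n_strides = n_strides,
         conditions = conditions, channels = channels, cadence = cadence,
         seed = seed, freqs = freqs, omega0 = omega0, n_tau = n_tau,
         n_perm = n_perm, cluster_alpha = cluster_alpha, lde_dim = lde_dim,
         lde_delay = lde_delay, lde_theiler = lde_theiler,
         samples_per_stride = samples_per_stride),
    class = "study_config"
  )
}

#' Run the full study analysis on simulated participants
#'
#' For every simulated subject and condition: generate the EVS, simulate the
#' walking trial ([condition_preset()] defaults), detect gait events,
#' compute stride times, step widths, the local divergence exponent and the
#' EVS-output coherence maps; then compare conditions with one-way
#' repeated-measures ANOVAs + planned pairwise tests (gait parameters, LDE)
#' and cluster-based permutation tests (coherence maps, normal vs each other
#' condition).
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, gait-parameter and
#'   cluster tables, per-condition mean maps and a provenance manifest
#'   (config hash, seed, versions) are written as CSV/JSON.
#' @param progress print one structured line per stage.
#' @return object of class `study_report`.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  n_sim <- config$n_strides + 2L          # padding strides for segmentation
  stride_T <- 2 * 60 / config$cadence
  evs_dur <- ceiling((n_sim + 4) * stride_T)
  subj_seeds <- substream_seeds(config$seed,
                                paste0("subject", seq_len(config$n_subjects)))
  gait <- list(); maps <- list()
  for (s in seq_len(config$n_subjects)) {
    cond_seeds <- substream_seeds(subj_seeds[[s]], config$conditions)
    for (cond in config$conditions) {
      sd_c <- cond_seeds[[cond]]
      preset <- condition_preset(cond)
      evs <- generate_evs(duration = evs_dur, seed = sd_c)
      trial <- simulate_trial(
        evs, config = preset$config, n_strides = n_sim,
        cadence = config$cadence,
        step_width_mean = preset$step_width_mean,
        step_width_sd = preset$step_width_sd,
        t6_noise_sd = preset$t6_noise_sd, seed = sd_c + 1L,
        condition = cond, cross_step = preset$cross_step)
      events <- detect_heel_strikes(trial)
      st <- compute_stride_times(events)
      widths <- compute_step_widths(events, trial$markers,
                                    trial$rates$markers)
      lde <- trial_lde(trial, events, n_strides = config$n_strides,
                       samples_per_stride = config$samples_per_stride,
                       dim = config$lde_dim, delay = config$lde_delay,
                       theiler = config$lde_theiler)
      gait[[length(gait) + 1L]] <- data.frame(
        subject = s, condition = cond,
        stride_time = attr(st, "mean"),
        step_width = mean(widths$width, na.rm = TRUE),
        lde = lde$lde, n_strides_detected = length(st$left),
        event_method = events$method)
      for (ch in config$channels) {
        maps[[paste(s, cond, ch, sep = "|")]] <- evs_coherence(
          trial, ch, events = events, n_strides = config$n_strides,
          freqs = config$freqs, omega0 = config$omega0,
          n_tau = config$n_tau)
      }
      say("stage=trial subject=%d condition=%s strides=%d events=%s lde=%.3f",
          s, cond, config$n_strides, events$method, lde$lde)
    }
  }
  gait <- do.call(rbind, gait)

  anovas <- list()
  for (var in c("stride_time", "step_width", "lde")) {
    tab <- matrix(NA_real_, config$n_subjects, length(config$conditions),
                  dimnames = list(NULL, config$conditions))
    for (i in seq_len(nrow(gait))) {
      tab[gait$subject[i], gait$condition[i]] <- gait[[var]][i]
    }
    anovas[[var]] <- rm_anova_planned(tab)
    say("stage=anova variable=%s F=%.2f p=%.4g", var, anovas[[var]]$F,
        anovas[[var]]$p)
  }

  clusters <- list()
  stat_seeds <- substream_seeds(config$seed + 1L,
    paste0(rep(config$channels, each = length(config$conditions) - 1L),
           rep(config$conditions[-1], length(config$channels))))
  for (ch in config$channels) {
    for (cond in setdiff(config$conditions, "normal")) {
      key <- paste0(ch, cond)
      ma <- lapply(seq_len(config$n_subjects), function(s)
        maps[[paste(s, "normal", ch, sep = "|")]])
      mb <- lapply(seq_len(config$n_subjects), function(s)
        maps[[paste(s, cond, ch, sep = "|")]])
      clusters[[paste(ch, cond, sep = "|")]] <- cluster_permutation_test(
        ma, mb, n_perm = config$n_perm,
        cluster_alpha = config$cluster_alpha, seed = stat_seeds[[key]])
      say("stage=cluster channel=%s contrast=normal-vs-%s min_p=%.4g",
          ch, cond, suppressWarnings(
            min(clusters[[paste(ch, cond, sep = "|")]]$clusters$p, Inf)))
    }
  }

  report <- structure(
    list(gait = gait, anovas = anovas, clusters = clusters, maps = maps,
         config = config,
         manifest = list(config_hash = config_hash(unclass(config)),
                         seed = config$seed,
                         package_version =
                           as.character(utils::packageVersion("vestigait")),
                         n_trials = nrow(gait))),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$config$n_subjects, "subjects x",
      length(x$config$conditions), "conditions,", x$config$n_strides,
      "strides/trial\n")
  agg <- stats::aggregate(cbind(stride_time, step_width, lde) ~ condition,
                          x$gait, mean)
  print(agg, row.names = FALSE)
  for (v in names(x$anovas)) {
    a <- x$anovas[[v]]
    cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.4g, eta^2 = %.3f\n",
                v, a$df[1], a$df[2], a$F, a$p, a$eta_squared))
  }
  sig <- vapply(x$clusters, function(cl)
    suppressWarnings(min(cl$clusters$p, Inf)), numeric(1))
  cat("  cluster tests with p < 0.05:",
      sum(sig < 0.05), "of", length(sig), "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' @param report a `study_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv17(report$gait, file.path(out_dir, "gait_parameters.csv"))
  cl <- do.call(rbind, lapply(names(report$clusters), function(nm) {
    df <- report$clusters[[nm]]$clusters
    if (nrow(df) == 0) return(NULL)
    df$contrast <- nm
    df
  }))
  if (!is.null(cl)) write_csv17(cl, file.path(out_dir, "cluster_tests.csv"))
  an <- do.call(rbind, lapply(names(report$anovas), function(v) {
    a <- report$anovas[[v]]
    data.frame(variable = v, F = a$F, df1 = a$df[1], df2 = a$df[2], p = a$p,
               eta_squared = a$eta_squared,
               partial_eta_squared = a$partial_eta_squared)
  }))
  write_csv17(an, file.path(out_dir, "anovas.csv"))
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
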