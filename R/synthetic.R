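#' Simulator parameters for synthetic gaze recordings
#'
#' The generator alternates fixation epochs with saccadic jumps.  Fixation
#' durations are log-normal (parameterized by median and log-scale sigma),
#' saccade amplitudes are gamma (parameterized by mean and SD; `sd = 0`
#' degenerates to a fixed amplitude), and each saccade follows a
#' minimum-jerk displacement profile whose duration is set by a linear main
#' sequence: peak velocity = `main_sequence_slope * amplitude`.  Within a
#' fixation the gaze drifts at `intra_fixation_drift_speed` in a random
#' direction with isotropic Gaussian jitter of SD `intra_fixation_noise_sd`.
#' Blinks arrive as a Poisson process and are emitted as invalid samples
#' (coordinates `NA`), so downstream cleaning logic is exercised.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param fixation_duration_median Median fixation duration, seconds.
#' @param fixation_duration_sigma Log-scale SD of fixation durations.
#' @param saccade_amplitude_mean,saccade_amplitude_sd Gamma amplitude
#'   distribution, degrees.
#' @param main_sequence_slope Peak-velocity-per-amplitude coefficient, 1/s.
#' @param saccade_curvature Trajectory bow of a saccade: the maximum
#'   perpendicular deviation from the straight chord, as a fraction of the
#'   amplitude (real saccades are measurably curved; 0 gives straight
#'   ones).  The bow side is random per saccade.
#' @param intra_fixation_drift_speed Fixational drift speed, deg/s.
#' @param intra_fixation_noise_sd Per-sample jitter SD, degrees.
#' @param blink_rate Blink events per minute.
#' @param blink_gap_duration Duration of each blink gap, seconds.
#' @param screen_bounds Numeric `c(xmin, xmax, ymin, ymax)` in degrees;
#'   generated positions are clipped to these bounds.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sample_rate = 100,
                       fixation_duration_median = 0.25,
                       fixation_duration_sigma = 0.4,
                       saccade_amplitude_mean = 4,
                       saccade_amplitude_sd = 2,
                       main_sequence_slope = 40,
                       saccade_curvature = 0.06,
                       intra_fixation_drift_speed = 0.5,
                       intra_fixation_noise_sd = 0.03,
                       blink_rate = 12,
                       blink_gap_duration = 0.2,
                       screen_bounds = c(-15, 15, -12, 12)) {
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  stopifnot_scalar_pos(fixation_duration_median, "fixation_duration_median")
  stopifnot_scalar_pos(fixation_duration_sigma, "fixation_duration_sigma",
                       strict = FALSE)
  stopifnot_scalar_pos(saccade_amplitude_mean, "saccade_amplitude_mean")
  stopifnot_scalar_pos(saccade_amplitude_sd, "saccade_amplitude_sd",
                       strict = FALSE)
  stopifnot_scalar_pos(main_sequence_slope, "main_sequence_slope")
  stopifnot_scalar_pos(saccade_curvature, "saccade_curvature", strict = FALSE)
  stopifnot_scalar_pos(intra_fixation_drift_speed,
                       "intra_fixation_drift_speed", strict = FALSE)
  stopifnot_scalar_pos(intra_fixation_noise_sd, "intra_fixation_noise_sd",
                       strict = FALSE)
  stopifnot_scalar_pos(blink_rate, "blink_rate", strict = FALSE)
  stopifnot_scalar_pos(blink_gap_duration, "blink_gap_duration")
  stopifnot(length(screen_bounds) == 4L,
            screen_bounds[2] > screen_bounds[1],
            screen_bounds[4] > screen_bounds[3])
  structure(as.list(environment()), class = "sim_params")
}

#' Fatigue effect configuration
#'
#' Signed multipliers applied to [sim_params()] fields as the fatigue level
#' goes from 0 to 1: at fatigue level `f` a parameter with multiplier `m`
#' becomes `value * m^f` (a geometric, hence monotone, interpolation).
#'
#' The defaults shift the expert-selected characteristics in the directions
#' implied by within-session fatigue trends: fixation durations lengthen
#' (so the share of fixations shorter than 150 ms falls), fixational drift
#' slows (so the average velocity within the fixation area falls), jitter
#' amplitude shrinks (which raises trajectory curvature, since curvature
#' scales inversely with the spatial scale of the gaze path), and saccades
#' grow slightly longer.
#'
#' Ground-truth noise SDs for the simulated Landolt Au index, reaction
#' times, and VAS-F scores live here too; set them to zero for fully
#' deterministic session ground truth.
#'
#' @param fixation_duration_median,intra_fixation_drift_speed,
#'   intra_fixation_noise_sd,saccade_amplitude_mean,saccade_curvature,
#'   main_sequence_slope,blink_rate Multipliers at fatigue level 1.
#' @param au_noise_sd,rt_noise_sd,vasf_noise_sd Additive Gaussian noise SDs
#'   on the simulated ground-truth scores.
#' @return An object of class `fatigue_effects`.
#' @export
fatigue_effects <- function(fixation_duration_median = 1.6,
                            intra_fixation_drift_speed = 0.45,
                            intra_fixation_noise_sd = 0.6,
                            saccade_amplitude_mean = 1.2,
                            saccade_curvature = 1.6,
                            main_sequence_slope = 1,
                            blink_rate = 1.2,
                            au_noise_sd = 0.35,
                            rt_noise_sd = 0.02,
                            vasf_noise_sd = 0.8) {
  mult <- c(fixation_duration_median = fixation_duration_median,
            intra_fixation_drift_speed = intra_fixation_drift_speed,
            intra_fixation_noise_sd = intra_fixation_noise_sd,
            saccade_amplitude_mean = saccade_amplitude_mean,
            saccade_amplitude_sd = saccade_amplitude_mean,
            saccade_curvature = saccade_curvature,
            main_sequence_slope = main_sequence_slope,
            blink_rate = blink_rate)
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("effect multipliers must be finite and positive", call. = FALSE)
  }
  for (nm in c("au_noise_sd", "rt_noise_sd", "vasf_noise_sd")) {
    stopifnot_scalar_pos(get(nm), nm, strict = FALSE)
  }
  structure(list(multipliers = mult,
                 au_noise_sd = au_noise_sd,
                 rt_noise_sd = rt_noise_sd,
                 vasf_noise_sd = vasf_noise_sd),
            class = "fatigue_effects")
}

#' @rdname fatigue_effects
#' @param ... Overrides for the ground-truth noise SDs.
#' @export
null_effects <- function(...) {
  fatigue_effects(fixation_duration_median = 1,
                  intra_fixation_drift_speed = 1,
                  intra_fixation_noise_sd = 1,
                  saccade_amplitude_mean = 1,
                  saccade_curvature = 1,
                  main_sequence_slope = 1,
                  blink_rate = 1, ...)
}

# Shift simulator parameters to a given fatigue level.
apply_fatigue <- function(params, effects, fatigue_level) {
  stopifnot(inherits(params, "sim_params"),
            inherits(effects, "fatigue_effects"))
  if (!is.finite(fatigue_level) || fatigue_level < 0 || fatigue_level > 1) {
    stop("`fatigue_level` must lie in [0, 1]", call. = FALSE)
  }
  m <- effects$multipliers
  for (nm in names(m)) params[[nm]] <- params[[nm]] * m[[nm]] ^ fatigue_level
  params
}

#' Study design for synthetic experiments
#'
#' @param n_participants,n_days,sessions_per_day Counts (each at least 1).
#' @param session_duration Duration of each recording in seconds (>= 10).
#' @param fatigue_schedule Function `(participant, day, session, design)`
#'   returning the fatigue level in `[0, 1]` at the start of that session.
#'   The default ramps mostly across the sessions of a day (morning to
#'   evening) and partly across days.
#' @param within_session_increment How much the fatigue level rises from the
#'   start to the end of one session (capped at 1).
#' @param seed Integer master seed; every session derives its own sub-seed
#'   from it.
#' @param sample_budget Refuse designs whose total sample count (sessions x
#'   duration x rate at 100 Hz equivalents) exceeds this guard.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants, n_days, sessions_per_day,
                         session_duration, fatigue_schedule = NULL,
                         within_session_increment = 0.25, seed = 1,
                         sample_budget = 2e7) {
  for (nm in c("n_participants", "n_days", "sessions_per_day")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (!is.numeric(session_duration) || session_duration < 10) {
    stop("`session_duration` must be at least 10 seconds", call. = FALSE)
  }
  if (is.null(fatigue_schedule)) {
    fatigue_schedule <- function(participant, day, session, design) {
      dfrac <- if (design$n_days > 1) (day - 1) / (design$n_days - 1) else 0
      sfrac <- if (design$sessions_per_day > 1) {
        (session - 1) / (design$sessions_per_day - 1)
      } else 0
      0.4 * dfrac + 0.6 * sfrac
    }
  }
  structure(list(n_participants = n_participants, n_days = n_days,
                 sessions_per_day = sessions_per_day,
                 session_duration = session_duration,
                 fatigue_schedule = fatigue_schedule,
                 within_session_increment = within_session_increment,
                 seed = seed, sample_budget = sample_budget),
            class = "study_design")
}

# Linear interpolation between two parameter sets at epoch-start fraction u.
interp_params <- function(p0, p1, u) {
  if (is.null(p1)) return(p0)
  out <- p0
  for (nm in c("fixation_duration_median", "fixation_duration_sigma",
               "saccade_amplitude_mean", "saccade_amplitude_sd",
               "main_sequence_slope", "saccade_curvature",
               "intra_fixation_drift_speed", "intra_fixation_noise_sd")) {
    out[[nm]] <- (1 - u) * p0[[nm]] + u * p1[[nm]]
  }
  out
}

# Minimum-jerk displacement fraction at normalized time tau in [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate a single gaze recording
#'
#' Alternates fixation epochs and saccadic jumps on a uniform sampling grid.
#' Saccade durations follow from the linear main sequence: a minimum-jerk
#' displacement profile has peak velocity `1.875 * amplitude / duration`,
#' so `duration = 1.875 / main_sequence_slope` under the linear relation
#' `v_peak = slope * amplitude`.  Blinks are overlaid as invalid samples.
#'
#' @param params A [sim_params()].
#' @param duration Recording duration in seconds (>= 1).
#' @param seed Optional seed; identical `(params, duration, seed)` give
#'   bit-identical recordings.
#' @param params_end Optional second [sim_params()]; when given, epoch
#'   parameters interpolate linearly from `params` at the start of the
#'   recording to `params_end` at its end (used to ramp fatigue within a
#'   session).
#' @param meta Passed through to the recording.
#' @return A [gaze_recording()] with an `events` attribute holding the
#'   ground-truth epoch log (type, start/end time, and per-saccade amplitude).
#' @export
simulate_recording <- function(params, duration, seed = NULL,
                               params_end = NULL, meta = list()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(duration) || length(duration) != 1L || duration < 1) {
    stop("`duration` must be at least 1 second", call. = FALSE)
  }
  with_seed(seed, {
    rate <- params$sample_rate
    n <- floor(duration * rate) + 1L
    ts <- (seq_len(n) - 1L) / rate
    x <- numeric(n); y <- numeric(n)
    bounds <- params$screen_bounds
    pos <- c(mean(bounds[1:2]), mean(bounds[3:4]))
    ev_type <- character(0); ev_start <- ev_end <- ev_amp <- numeric(0)
    i <- 1L
    while (i <= n) {
      u <- ts[i] / duration
      p <- interp_params(params, params_end, u)
      ## fixation epoch
      fdur <- if (p$fixation_duration_sigma > 0) {
        rlnorm(1, log(p$fixation_duration_median), p$fixation_duration_sigma)
      } else p$fixation_duration_median
      k <- max(1L, round(fdur * rate))
      idx <- i:min(n, i + k - 1L)
      tt <- ts[idx] - ts[i]
      theta <- runif(1, 0, 2 * pi)
      drift_end <- pos + p$intra_fixation_drift_speed * max(tt) *
        c(cos(theta), sin(theta))
      if (drift_end[1] < bounds[1] || drift_end[1] > bounds[2] ||
          drift_end[2] < bounds[3] || drift_end[2] > bounds[4]) {
        # reflect the drift direction towards the screen centre
        theta <- atan2(mean(bounds[3:4]) - pos[2], mean(bounds[1:2]) - pos[1])
        drift_end <- pos + p$intra_fixation_drift_speed * max(tt) *
          c(cos(theta), sin(theta))
      }
      nz <- length(idx)
      noise_x <- if (p$intra_fixation_noise_sd > 0) {
        rnorm(nz, 0, p$intra_fixation_noise_sd)
      } else numeric(nz)
      noise_y <- if (p$intra_fixation_noise_sd > 0) {
        rnorm(nz, 0, p$intra_fixation_noise_sd)
      } else numeric(nz)
      x[idx] <- pos[1] + p$intra_fixation_drift_speed * tt * cos(theta) + noise_x
      y[idx] <- pos[2] + p$intra_fixation_drift_speed * tt * sin(theta) + noise_y
      ev_type <- c(ev_type, "fixation")
      ev_start <- c(ev_start, ts[idx[1L]]); ev_end <- c(ev_end, ts[idx[nz]])
      ev_amp <- c(ev_amp, NA_real_)
      pos <- drift_end
      i <- idx[nz] + 1L
      if (i > n) break
      ## saccade epoch
      amp <- if (p$saccade_amplitude_sd > 0) {
        shape <- (p$saccade_amplitude_mean / p$saccade_amplitude_sd)^2
        rgamma(1, shape = shape,
               scale = p$saccade_amplitude_sd^2 / p$saccade_amplitude_mean)
      } else p$saccade_amplitude_mean
      amp <- max(amp, 1e-3)
      target <- NULL
      for (try in 1:20) {
        phi <- runif(1, 0, 2 * pi)
        cand <- pos + amp * c(cos(phi), sin(phi))
        if (cand[1] >= bounds[1] && cand[1] <= bounds[2] &&
            cand[2] >= bounds[3] && cand[2] <= bounds[4]) {
          target <- cand; break
        }
      }
      if (is.null(target)) {
        phi <- atan2(mean(bounds[3:4]) - pos[2], mean(bounds[1:2]) - pos[1])
        target <- pos + amp * c(cos(phi), sin(phi))
        target <- c(clamp(target[1], bounds[1], bounds[2]),
                    clamp(target[2], bounds[3], bounds[4]))
      }
      t_sacc <- 1.875 / p$main_sequence_slope
      k2 <- max(1L, round(t_sacc * rate))
      idx2 <- i:min(n, i + k2 - 1L)
      tau <- (seq_along(idx2)) / k2
      s <- min_jerk(pmin(tau, 1))
      chord <- target - pos
      # perpendicular bow: parabolic in the traversed path fraction
      bow_side <- sample(c(-1, 1), 1L)
      bow <- bow_side * p$saccade_curvature * amp * 4 * s * (1 - s)
      perp <- c(-chord[2], chord[1]) / max(sqrt(sum(chord^2)), 1e-12)
      x[idx2] <- pos[1] + chord[1] * s + perp[1] * bow
      y[idx2] <- pos[2] + chord[2] * s + perp[2] * bow
      ev_type <- c(ev_type, "saccade")
      ev_start <- c(ev_start, ts[i] - 1 / rate)
      ev_end <- c(ev_end, ts[idx2[length(idx2)]])
      ev_amp <- c(ev_amp, sqrt(sum((target - pos)^2)))
      pos <- target
      i <- idx2[length(idx2)] + 1L
    }
    x <- clamp(x, bounds[1], bounds[2])
    y <- clamp(y, bounds[3], bounds[4])
    ## blinks: Poisson count, uniform onsets, emitted as invalid samples
    valid <- rep.int(TRUE, n)
    if (params$blink_rate > 0) {
      n_blinks <- rpois(1, params$blink_rate * duration / 60)
      if (n_blinks > 0) {
        onsets <- sort(runif(n_blinks, 0, duration))
        for (b in onsets) {
          valid[ts >= b & ts < b + params$blink_gap_duration] <- FALSE
        }
        x[!valid] <- NA_real_; y[!valid] <- NA_real_
      }
    }
    rec <- gaze_recording(ts, x, y, valid = valid, sample_rate = rate,
                          meta = meta)
    attr(rec, "events") <- data.frame(type = ev_type, start = ev_start,
                                      end = ev_end, amplitude = ev_amp)
    rec
  })
}

# Session-level ground-truth model: deterministic mappings from fatigue
# level plus configurable Gaussian noise.  Au falls with fatigue (range of
# the simulated index is kept within [-0.5, 4]), reaction times and VAS-F
# fatigue rise, VAS-F energy falls.
simulate_ground_truth <- function(f_start, f_end, effects) {
  f_mid <- (f_start + f_end) / 2
  au <- clamp(3.2 - 2.8 * f_mid + rnorm(1, 0, effects$au_noise_sd), -0.5, 4)
  crt_mean <- function(f) 0.32 + 0.10 * f + rnorm(1, 0, effects$rt_noise_sd)
  crt_sd <- function(f) max(0.05 + 0.03 * f + rnorm(1, 0, effects$rt_noise_sd / 2), 0)
  crt_err <- function(f) rpois(1, 1 + 3 * f)
  list(au = au,
       crt_pre_mean = crt_mean(f_start), crt_pre_sd = crt_sd(f_start),
       crt_pre_errors = crt_err(f_start),
       crt_post_mean = crt_mean(f_end), crt_post_sd = crt_sd(f_end),
       crt_post_errors = crt_err(f_end),
       vasf_fatigue = clamp(1.5 + 7 * f_start +
                              rnorm(1, 0, effects$vasf_noise_sd), 0, 10),
       vasf_energy = clamp(8.5 - 7 * f_start +
                             rnorm(1, 0, effects$vasf_noise_sd), 0, 10))
}

#' Simulate one study session
#'
#' Generates the session recording with fatigue-shifted simulator
#' parameters, ramping from the scheduled fatigue level at the session
#' start to `start + within_session_increment` at its end, together with
#' the session's ground truth (Au falling, CRT mean RT and VAS-F fatigue
#' rising in the fatigue level; the post-session CRT reflects the
#' within-session increment).
#'
#' @param design A [study_design()].
#' @param participant,day,session 1-based indices within the design.
#' @param params Baseline [sim_params()].
#' @param effects A [fatigue_effects()].
#' @return A list with elements `recording` (a [gaze_recording()]) and
#'   `ground_truth` (a one-row data frame).
#' @export
simulate_session <- function(design, participant, day, session,
                             params = sim_params(),
                             effects = fatigue_effects()) {
  stopifnot(inherits(design, "study_design"))
  if (participant < 1 || participant > design$n_participants ||
      day < 1 || day > design$n_days ||
      session < 1 || session > design$sessions_per_day) {
    stop("session indices outside the study design", call. = FALSE)
  }
  f0 <- design$fatigue_schedule(participant, day, session, design)
  f0 <- clamp(f0, 0, 1)
  f1 <- clamp(f0 + design$within_session_increment, 0, 1)
  p0 <- apply_fatigue(params, effects, f0)
  p1 <- apply_fatigue(params, effects, f1)
  sd_session <- derive_seed(design$seed, participant, day, session)
  meta <- list(participant = participant, day = day, session = session)
  rec <- simulate_recording(p0, design$session_duration, seed = sd_session,
                            params_end = p1, meta = meta)
  gt <- with_seed(sd_session + 500009L,
                  simulate_ground_truth(f0, f1, effects))
  gt <- data.frame(participant = participant, day = day, session = session,
                   fatigue_level = f0, as.data.frame(gt))
  list(recording = rec, ground_truth = gt)
}

#' Simulate a full study
#'
#' Runs [simulate_session()] over every `(participant, day, session)` cell
#' of the design.  Fully reproducible from `design$seed`.
#'
#' @inheritParams simulate_session
#' @return An object of class `gaze_study`: a list with `design`, `params`,
#'   `effects`, `ground_truth` (one data-frame row per session) and
#'   `recordings` (a list parallel to the ground-truth rows).
#' @export
simulate_study <- function(design, params = sim_params(),
                           effects = fatigue_effects()) {
  stopifnot(inherits(design, "study_design"))
  n_sessions <- design$n_participants * design$n_days * design$sessions_per_day
  total_samples <- n_sessions * design$session_duration * params$sample_rate
  if (total_samples > design$sample_budget) {
    stop(sprintf(
      "design would generate %.3g samples, above the budget of %.3g; raise `sample_budget` deliberately if intended",
      total_samples, design$sample_budget), call. = FALSE)
  }
  recs <- vector("list", n_sessions)
  gts <- vector("list", n_sessions)
  i <- 0L
  for (p in seq_len(design$n_participants)) {
    for (d in seq_len(design$n_days)) {
      for (s in seq_len(design$sessions_per_day)) {
        i <- i + 1L
        ses <- simulate_session(design, p, d, s, params, effects)
        recs[[i]] <- ses$recording
        gts[[i]] <- ses$ground_truth
      }
    }
  }
  structure(list(design = design, params = params, effects = effects,
                 ground_truth = do.call(rbind, gts),
                 recordings = recs),
            class = "gaze_study")
}

#' @export
print.gaze_study <- function(x, ...) {
  cat(sprintf(
    "<gaze_study> %d participants x %d days x %d sessions (%d recordings of %.0f s)\n",
    x$design$n_participants, x$design$n_days, x$design$sessions_per_day,
    length(x$recordings), x$design$session_duration))
  invisible(x)
}
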