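#' The oculomotor characteristic catalogue
#'
#' Returns the 27 named characteristics computed per recording or window,
#' grouped as velocity-based, trajectory-based, temporal-based,
#' percentage-based, quantitative-based (per-minute counts) and
#' saccade-length-based.  `selected_characteristics()` returns the seven
#' expert-selected characteristics used by the default classifier feature
#' set (six screened in plus the expert-added average speed in the fixation
#' area).
#'
#' @return A data frame with columns `name`, `label` and `group`.
#' @export
characteristic_catalogue <- function() {
  data.frame(
    name = c(
      "avg_velocity_fixation", "min_velocity_fixation", "avg_speed_fixation",
      "avg_curvature", "min_curvature", "max_curvature",
      "min_velocity_second_interval", "modulus_avg_acceleration_second_interval",
      "max_instantaneous_velocity",
      "min_saccade_length", "max_saccade_length", "avg_saccade_length",
      "avg_saccade_duration", "max_saccade_duration", "avg_saccade_velocity",
      "pct_fixations_lt_150ms", "pct_fixations_ge_150ms",
      "pct_fixations_lt_180ms", "pct_fixations_ge_180ms",
      "pct_fixations_150_900ms",
      "total_duration_fixations_150_900ms",
      "prop_time_fixations_lt_150ms", "prop_time_fixations_150_900ms",
      "prop_time_fixations_ge_150ms",
      "false_fixations_per_minute", "fixations_gt_900ms_per_minute",
      "fixations_lt_180ms_per_minute"),
    label = c(
      "Average velocity within the fixation area, deg/s",
      "Minimum velocity within the fixation area, deg/s",
      "Average speed in the fixation area, deg/s",
      "Average curvature of the gaze trajectory",
      "Minimum curvature of the gaze trajectory",
      "Maximum curvature of the gaze trajectory",
      "Min. velocity of gaze movement in the second interval, deg/s",
      "Modulus of average acceleration in second interval, deg/s^2",
      "Maximum instantaneous gaze velocity, deg/s",
      "Minimum saccade length, deg", "Maximum saccade length, deg",
      "Average saccade length, deg",
      "Average saccade duration, s", "Maximum saccade duration, s",
      "Average saccade velocity, deg/s",
      "Percentage of fixations shorter than 150 ms, %",
      "Percentage of fixations longer than 150 ms, %",
      "Percentage of fixations shorter than 180 ms, %",
      "Percentage of fixations longer than 180 ms, %",
      "Percentage of fixations between 150 and 900 ms, %",
      "Total duration of fixations between 150 and 900 ms, s",
      "Proportion of time spent in fixations shorter than 150 ms, %",
      "Proportion of time spent in fixations between 150 and 900 ms, %",
      "Proportion of time spent in fixations longer than 150 ms, %",
      "False fixations per minute",
      "Fixations longer than 900 ms per minute",
      "Fixations shorter than 180 ms per minute"),
    group = c(
      rep("velocity", 3), rep("trajectory", 3), rep("velocity", 3),
      rep("saccade_length", 3), rep("temporal", 3),
      rep("percentage", 5), "temporal", rep("percentage", 3),
      rep("quantitative", 3)),
    stringsAsFactors = FALSE)
}

#' @rdname characteristic_catalogue
#' @export
selected_characteristics <- function() {
  c("avg_velocity_fixation", "avg_curvature", "min_curvature",
    "min_saccade_length", "pct_fixations_lt_150ms",
    "prop_time_fixations_lt_150ms", "avg_speed_fixation")
}

# Core computation from pre-computed components.  `total_duration` is the
# summed segment duration in seconds.  Duration-bin tie rule: "shorter than
# T" means duration < T, "longer than T" means duration >= T, and "between
# 150 and 900 ms" means [0.150, 0.900) -- this makes the complementary
# percentage pairs sum to exactly 100 and the three time bins partition
# total fixation time.  Per-recording values are event-weighted means over
# events (fixations, saccades, second bins), not time-weighted.
char_from_components <- function(fix, sacc, kin, total_duration,
                                 false_fixations) {
  minutes <- total_duration / 60
  nf <- nrow(fix)
  out <- setNames(rep(NA_real_, 27), characteristic_catalogue()$name)
  if (nf > 0L) {
    pos_dur <- fix$duration > 0
    vel <- fix$net_displacement[pos_dur] / fix$duration[pos_dur]
    spd <- fix$path_length[pos_dur] / fix$duration[pos_dur]
    if (length(vel)) {
      out["avg_velocity_fixation"] <- mean(vel)
      out["min_velocity_fixation"] <- min(vel)
      out["avg_speed_fixation"] <- mean(spd)
    }
    d <- fix$duration
    lt150 <- d < 0.150; ge150 <- !lt150
    lt180 <- d < 0.180; ge180 <- !lt180
    mid <- d >= 0.150 & d < 0.900
    ge900 <- d >= 0.900
    out["pct_fixations_lt_150ms"] <- 100 * sum(lt150) / nf
    out["pct_fixations_ge_150ms"] <- 100 * sum(ge150) / nf
    out["pct_fixations_lt_180ms"] <- 100 * sum(lt180) / nf
    out["pct_fixations_ge_180ms"] <- 100 * sum(ge180) / nf
    out["pct_fixations_150_900ms"] <- 100 * sum(mid) / nf
    out["total_duration_fixations_150_900ms"] <- sum(d[mid])
    tot_fix_time <- sum(d)
    if (tot_fix_time > 0) {
      out["prop_time_fixations_lt_150ms"] <- 100 * sum(d[lt150]) / tot_fix_time
      out["prop_time_fixations_150_900ms"] <- 100 * sum(d[mid]) / tot_fix_time
      out["prop_time_fixations_ge_150ms"] <- 100 * sum(d[ge150]) / tot_fix_time
    }
    out["fixations_gt_900ms_per_minute"] <- sum(ge900) / minutes
    out["fixations_lt_180ms_per_minute"] <- sum(lt180) / minutes
  }
  out["false_fixations_per_minute"] <- false_fixations / minutes
  if (!is.null(sacc) && nrow(sacc) > 0L) {
    out["min_saccade_length"] <- min(sacc$length)
    out["max_saccade_length"] <- max(sacc$length)
    out["avg_saccade_length"] <- mean(sacc$length)
    out["avg_saccade_duration"] <- mean(sacc$duration)
    out["max_saccade_duration"] <- max(sacc$duration)
    out["avg_saccade_velocity"] <- mean(sacc$mean_velocity)
  }
  # curvature statistics over per-second mean curvature: the table's
  # velocity extreme is explicitly "instantaneous", the curvature ones are
  # not, and a minimum over raw noisy triplets would be degenerate (some
  # triplet is always near-collinear)
  kc <- kin$per_second$mean_curvature
  kc <- kc[is.finite(kc)]
  if (length(kc)) {
    out["avg_curvature"] <- mean(kc)
    out["min_curvature"] <- min(kc)
    out["max_curvature"] <- max(kc)
  }
  if (nrow(kin$velocity) > 0L) {
    out["max_instantaneous_velocity"] <- max(kin$velocity$v)
  }
  ps <- kin$per_second
  if (nrow(ps) > 0L) {
    out["min_velocity_second_interval"] <- mean(ps$min_velocity)
    if (any(is.finite(ps$mean_abs_acceleration))) {
      out["modulus_avg_acceleration_second_interval"] <-
        mean(ps$mean_abs_acceleration, na.rm = TRUE)
    }
  }
  out
}

total_recording_duration <- function(rec) {
  sum(tapply(rec$t, rec$segment, function(tt) {
    if (length(tt) > 1) diff(range(tt)) else 0
  }))
}

#' Compute the characteristic vector of a recording
#'
#' Populates all 27 catalogue entries from the recording's fixations,
#' saccades and kinematics at one fixation-area diameter.  Entries that are
#' undefined on the input (no saccades, no complete second bins, ...) are
#' reported as `NA`, never silently zeroed.
#'
#' @param rec A [gaze_recording()] (cleaned automatically if needed).
#' @param fixations,saccades,kin Optional pre-computed components from
#'   [detect_fixations()], [derive_saccades()] and [compute_kinematics()]
#'   on the same recording; recomputed when `NULL`.  Components from a
#'   different recording are an error.
#' @param cfg An [event_config()]; its `area_diameter` defines the fixation
#'   area.
#' @return A named numeric vector of length 27 with attribute
#'   `area_diameter`.
#' @export
compute_characteristics <- function(rec, fixations = NULL, saccades = NULL,
                                    kin = NULL, cfg = event_config()) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (any(!rec$valid)) rec <- clean_recording(rec, cfg)
  token <- rec_token(rec)
  if (is.null(fixations)) fixations <- detect_fixations(rec, cfg)
  if (!identical(attr(fixations, "rec_token"), token)) {
    stop("fixations were not computed from this recording", call. = FALSE)
  }
  if (is.null(saccades)) saccades <- derive_saccades(rec, fixations)
  if (!identical(attr(saccades, "rec_token"), token)) {
    stop("saccades were not computed from this recording", call. = FALSE)
  }
  if (is.null(kin)) kin <- compute_kinematics(rec)
  if (!identical(kin$rec_token, token)) {
    stop("kinematics were not computed from this recording", call. = FALSE)
  }
  out <- char_from_components(fixations, saccades, kin,
                              total_recording_duration(rec),
                              attr(fixations, "false_fixations"))
  attr(out, "area_diameter") <- cfg$area_diameter
  out
}

#' Characteristic time series over sliding windows
#'
#' Computes the characteristic vector over sliding windows aligned to the
#' window end.  Windows with too little data yield `NA` entries.
#'
#' @param rec A [gaze_recording()].
#' @param window_s Window length, seconds (>= 5).
#' @param step_s Step between window ends, seconds (> 0).
#' @param cfg An [event_config()].
#' @return A data frame with a `window_end` column followed by the 27
#'   characteristics, one row per window; zero rows when the recording is
#'   shorter than one window.
#' @export
windowed_characteristics <- function(rec, window_s, step_s,
                                     cfg = event_config()) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (window_s < 5) stop("`window_s` must be at least 5 s", call. = FALSE)
  if (step_s <= 0) stop("`step_s` must be positive", call. = FALSE)
  rec <- clean_recording(rec, cfg)
  t0 <- rec$t[1]; t1 <- rec$t[length(rec$t)]
  nms <- characteristic_catalogue()$name
  if (t1 - t0 < window_s) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(nms) + 1L,
                                dimnames = list(NULL, c("window_end", nms))))
    return(out)
  }
  ends <- seq(t0 + window_s, t1 + 1e-9, by = step_s)
  rows <- lapply(ends, function(e) {
    w <- crop_recording(rec, e - window_s, e + 1e-9)
    if (is.null(w)) return(setNames(rep(NA_real_, length(nms)), nms))
    compute_characteristics(w, cfg = cfg)
  })
  out <- cbind(data.frame(window_end = ends),
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  out
}

#' Seven-number summary of a feature series
#'
#' The mean, standard deviation (denominator `n - 1`; 0 for a single
#' value), minimum, maximum and the 25th/50th/75th percentiles (linear
#' interpolation) of a numeric series.  `NA` values are dropped; a series
#' with no finite values is an error distinct from an empty series.
#'
#' @param x Numeric vector.
#' @return Named numeric vector `mean, sd, min, max, p25, p50, p75`.
#' @export
summarize_series <- function(x) {
  if (length(x) == 0L) {
    stop("empty series", call. = FALSE)
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    stop("series contains no finite values", call. = FALSE)
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
    min = min(x), max = max(x), p25 = q[1], p50 = q[2], p75 = q[3])
}

# Summaries of the raw coordinate and velocity series of one window.
coordinate_summaries <- function(rec) {
  kin <- compute_kinematics(rec)
  out <- c(summarize_series(rec$x), summarize_series(rec$y),
           if (nrow(kin$velocity)) summarize_series(kin$velocity$v) else
             setNames(rep(NA_real_, 7),
                      c("mean", "sd", "min", "max", "p25", "p50", "p75")))
  names(out) <- paste0("coord_", rep(c("x", "y", "v"), each = 7), "_",
                       rep(c("mean", "sd", "min", "max", "p25", "p50", "p75"),
                           3))
  out
}

#' Build a feature matrix from a study
#'
#' One row per session (or per sliding window when `window_s` is given),
#' with the feature sets of the classification experiments:
#' `"coordinates"` expands the raw x, y and instantaneous-velocity series
#' of each row's data into their seven summary statistics (21 columns);
#' `"selected"` is the seven expert-selected characteristics;
#' `"all"` is every catalogue characteristic whose Wilcoxon p-value against
#' the high/low mental-performance split is at most `alpha`.  Sets may be
#' combined, e.g. `c("coordinates", "selected")`.
#'
#' @param study A `gaze_study` from [simulate_study()] (or an equivalent
#'   list with `ground_truth` and `recordings`).
#' @param cfg An [event_config()]; characteristics are computed at its
#'   `area_diameter`.
#' @param feature_sets Character vector drawn from
#'   `c("coordinates", "selected", "all")`.
#' @param window_s,step_s Optional sliding-window extraction within each
#'   session; by default one row spans the whole session.
#' @param au_threshold Mental-performance threshold for the label column.
#' @param alpha Screening level used by the `"all"` set.
#' @return A data frame with key columns `participant`, `day`, `session`,
#'   `window_end`, `au`, `label` and the feature columns (attribute
#'   `feature_columns`); attribute `feature_def` records the definition for
#'   later assessment.
#' @export
build_feature_matrix <- function(study, cfg = event_config(),
                                 feature_sets = "selected",
                                 window_s = NULL, step_s = NULL,
                                 au_threshold = 1.5, alpha = 0.05) {
  unknown <- setdiff(feature_sets, c("coordinates", "selected", "all"))
  if (length(unknown)) {
    stop(sprintf("unknown feature set(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!length(feature_sets)) stop("no feature sets requested", call. = FALSE)
  gt <- study$ground_truth
  need_chars <- any(c("selected", "all") %in% feature_sets)
  need_coord <- "coordinates" %in% feature_sets
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    rec <- clean_recording(study$recordings[[i]], cfg)
    wins <- if (is.null(window_s)) {
      list(rec)
    } else {
      t0 <- rec$t[1]
      ends <- seq(t0 + window_s, rec$t[length(rec$t)] + 1e-9,
                  by = step_s %||% window_s)
      lapply(ends, function(e) crop_recording(rec, e - window_s, e + 1e-9))
    }
    ends <- if (is.null(window_s)) NA_real_ else {
      seq(rec$t[1] + window_s, rec$t[length(rec$t)] + 1e-9,
          by = step_s %||% window_s)
    }
    for (w in seq_along(wins)) {
      win <- wins[[w]]
      if (is.null(win)) next
      feats <- numeric(0)
      if (need_chars) feats <- c(feats, compute_characteristics(win, cfg = cfg))
      if (need_coord) feats <- c(feats, coordinate_summaries(win))
      rows[[length(rows) + 1L]] <- c(
        list(participant = gt$participant[i], day = gt$day[i],
             session = gt$session[i], window_end = ends[w],
             au = gt$au[i]),
        as.list(feats))
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  df$label <- label_by_mental_performance(df$au, au_threshold)
  all_chars <- characteristic_catalogue()$name
  cols <- character(0)
  if ("coordinates" %in% feature_sets) {
    cols <- c(cols, grep("^coord_", names(df), value = TRUE))
  }
  if ("selected" %in% feature_sets) {
    cols <- c(cols, selected_characteristics())
  }
  if ("all" %in% feature_sets) {
    p <- landolt_wilcoxon(df[, all_chars, drop = FALSE], df$label)
    keep <- names(p)[!is.na(p) & p <= alpha]
    cols <- c(cols, keep)
  }
  cols <- unique(cols)
  out <- df[, c("participant", "day", "session", "window_end", "au",
                "label", cols)]
  attr(out, "feature_columns") <- cols
  attr(out, "feature_def") <- list(feature_sets = feature_sets,
                                   columns = cols, cfg = cfg,
                                   window_s = window_s, step_s = step_s,
                                   au_threshold = au_threshold)
  out
}
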