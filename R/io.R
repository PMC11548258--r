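#' Construct a gaze recording
#'
#' A gaze recording is a uniformly timestamped two-dimensional gaze-position
#' series in degrees of visual angle, with a per-sample validity flag.
#' Invalid samples (tracking losses, blinks) keep their timestamps; their
#' coordinates may be `NA`.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Gaze position in degrees of visual angle, one value per sample.
#' @param valid Logical vector of per-sample validity flags.  Defaults to
#'   `is.finite(x) & is.finite(y)`.
#' @param sample_rate Nominal sampling rate in Hz.  If `NULL` it is inferred
#'   from the median inter-sample interval.  A declared rate more than 10%
#'   away from the median rate is rejected.
#' @param meta Named list of identifiers (participant, day, session, ...).
#'
#' @return An object of class `gaze_recording`: a list with elements `t`,
#'   `x`, `y`, `valid`, `sample_rate`, `meta` and (after cleaning) `segment`.
#' @export
gaze_recording <- function(t, x, y, valid = NULL, sample_rate = NULL,
                           meta = list()) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    stop("`t`, `x` and `y` must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("a recording must contain at least one sample",
                    call. = FALSE)
  if (anyNA(t)) stop("timestamps must be finite", call. = FALSE)
  if (n > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf(
        "timestamps must be strictly increasing; violation at row %d (t = %g)",
        bad[1L] + 1L, t[bad[1L] + 1L]), call. = FALSE)
    }
  }
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("`valid` must match the sample count",
                               call. = FALSE)
  valid[is.na(valid)] <- FALSE
  valid <- valid & is.finite(x) & is.finite(y)
  med_rate <- if (n > 1L) 1 / median(diff(t)) else NA_real_
  if (is.null(sample_rate)) {
    sample_rate <- med_rate
  } else if (is.finite(med_rate) &&
             abs(sample_rate - med_rate) > 0.1 * med_rate) {
    stop(sprintf(
      "declared sample_rate (%g Hz) deviates more than 10%% from the median rate (%g Hz)",
      sample_rate, med_rate), call. = FALSE)
  }
  structure(
    list(t = t, x = x, y = y, valid = valid,
         sample_rate = sample_rate, meta = meta,
         segment = rep.int(1L, n)),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %d samples, %.2f s @ %.1f Hz, %d invalid, %d segment(s)\n",
    length(x$t), diff(range(x$t)), x$sample_rate, sum(!x$valid),
    length(unique(x$segment))))
  invisible(x)
}

#' @export
length.gaze_recording <- function(x) length(x$t)

# Subset a recording to t in [from, to] (closed interval), preserving
# segment labels.
crop_recording <- function(rec, from, to) {
  keep <- rec$t >= from & rec$t <= to
  if (!any(keep)) return(NULL)
  out <- rec
  for (f in c("t", "x", "y", "valid", "segment", "interpolated")) {
    if (!is.null(rec[[f]])) out[[f]] <- rec[[f]][keep]
  }
  out
}

#' Screen geometry for unit conversion
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm) {
  for (nm in c("width_px", "height_px", "width_mm", "height_mm",
               "viewing_distance_mm")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  structure(list(width_px = width_px, height_px = height_px,
                 width_mm = width_mm, height_mm = height_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "screen_geometry")
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Angles are measured per axis about the screen centre:
#' `deg = atan(offset_mm / viewing_distance_mm) * 180 / pi`.  The full
#' arctangent form is used (no small-angle approximation), so the conversion
#' is exact at wide angles and invertible within the screen bounds.
#'
#' @param x_px,y_px Pixel coordinates (0-based, origin at the top-left).
#' @param geom A [screen_geometry()].
#' @return A list with numeric vectors `x` and `y` in degrees; positive x is
#'   rightwards and positive y is downwards, matching the pixel axes.
#' @export
pixels_to_degrees <- function(x_px, y_px, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  dx_mm <- (x_px - geom$width_px / 2) * geom$width_mm / geom$width_px
  dy_mm <- (y_px - geom$height_px / 2) * geom$height_mm / geom$height_px
  list(x = atan(dx_mm / geom$viewing_distance_mm) * 180 / pi,
       y = atan(dy_mm / geom$viewing_distance_mm) * 180 / pi)
}

#' @rdname pixels_to_degrees
#' @param x_deg,y_deg Coordinates in degrees of visual angle.
#' @export
degrees_to_pixels <- function(x_deg, y_deg, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  dx_mm <- tan(x_deg * pi / 180) * geom$viewing_distance_mm
  dy_mm <- tan(y_deg * pi / 180) * geom$viewing_distance_mm
  list(x = dx_mm * geom$width_px / geom$width_mm + geom$width_px / 2,
       y = dy_mm * geom$height_px / geom$height_mm + geom$height_px / 2)
}

#' Read and write gaze recordings
#'
#' The on-disk dialect is comma-delimited text with a `t,x,y` header and an
#' optional `valid` column; timestamps are seconds, coordinates degrees of
#' visual angle unless `units = "px"`, in which case a [screen_geometry()]
#' must be supplied (directly or through a YAML manifest sidecar).
#'
#' Rows with non-finite coordinates are kept and marked invalid rather than
#' dropped.  Non-monotone or duplicated timestamps are a format error naming
#' the offending row.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping the canonical names
#'   `t`, `x`, `y` (and optionally `valid`) to column names in the file.
#' @param units `"deg"` (default) or `"px"`.
#' @param geometry A [screen_geometry()], required when `units = "px"`.
#' @param manifest Optional path to a YAML manifest with any of the fields
#'   `columns`, `units`, `geometry` (a mapping with the five
#'   [screen_geometry()] fields) and `meta`; explicit arguments win.
#'   Defaults to `<path>.yaml` when that file exists.
#' @return A [gaze_recording()].
#' @export
read_gaze <- function(path, columns = c(t = "t", x = "x", y = "y"),
                      units = NULL, geometry = NULL, manifest = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  meta <- list()
  if (is.null(manifest) && file.exists(paste0(path, ".yaml"))) {
    manifest <- paste0(path, ".yaml")
  }
  if (!is.null(manifest)) {
    mf <- yaml::read_yaml(manifest)
    if (!is.null(mf$columns)) {
      columns <- utils::modifyList(as.list(columns), mf$columns)
      columns <- unlist(columns)
    }
    if (is.null(units)) units <- mf$units
    if (is.null(geometry) && !is.null(mf$geometry)) {
      geometry <- do.call(screen_geometry, mf$geometry)
    }
    meta <- mf$meta %||% list()
  }
  units <- units %||% "deg"
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- columns[c("t", "x", "y")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  t <- as.numeric(df[[need[["t"]]]])
  x <- as.numeric(df[[need[["x"]]]])
  y <- as.numeric(df[[need[["y"]]]])
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf("non-monotone timestamp at row %d of %s",
                   bad[1L] + 1L, path), call. = FALSE)
    }
  }
  valid <- NULL
  if (!is.na(columns["valid"] %||% NA) && columns[["valid"]] %in% names(df)) {
    valid <- as.logical(df[[columns[["valid"]]]])
  } else if ("valid" %in% names(df)) {
    valid <- as.logical(df$valid)
  }
  if (identical(units, "px")) {
    if (is.null(geometry)) {
      stop("pixel-unit gaze files require a screen geometry", call. = FALSE)
    }
    deg <- pixels_to_degrees(x, y, geometry)
    x <- deg$x; y <- deg$y
  } else if (!identical(units, "deg")) {
    stop(sprintf("unknown units: %s", units), call. = FALSE)
  }
  gaze_recording(t, x, y, valid = valid, meta = meta)
}

#' @rdname read_gaze
#' @param rec A [gaze_recording()].
#' @export
write_gaze <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  df <- data.frame(t = rec$t, x = rec$x, y = rec$y,
                   valid = rec$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

gt_columns <- c("participant", "day", "session", "fatigue_level", "au",
                "crt_pre_mean", "crt_pre_sd", "crt_pre_errors",
                "crt_post_mean", "crt_post_sd", "crt_post_errors",
                "vasf_fatigue", "vasf_energy")

#' Read and write per-session ground-truth tables
#'
#' One row per session, keyed by `(participant, day, session)`, holding the
#' Landolt mental-performance index (`au`), choice-reaction-time results
#' before and after the session (mean RT in seconds, its SD, error count),
#' and VAS-F fatigue/energy scores.  Missing test values are preserved as
#' `NA`, never silently filled.
#'
#' @param path Path to a CSV file.
#' @return A data frame of typed session records.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant", "day", "session"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("ground-truth table lacks key column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$participant, df$day, df$session, sep = "/")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate session key: %s", key[anyDuplicated(key)]),
         call. = FALSE)
  }
  for (cl in setdiff(gt_columns, c("participant", "day", "session"))) {
    if (cl %in% names(df)) df[[cl]] <- as.numeric(df[[cl]])
  }
  bad_sd <- which(is.finite(df$crt_pre_sd) & df$crt_pre_sd < 0 |
                    is.finite(df$crt_post_sd) & df$crt_post_sd < 0)
  if (length(bad_sd)) {
    stop(sprintf("negative reaction-time SD at row %d", bad_sd[1L]),
         call. = FALSE)
  }
  df
}

#' @rdname read_ground_truth
#' @param gt A ground-truth data frame as produced by [simulate_study()].
#' @export
write_ground_truth <- function(gt, path) {
  write.csv(gt, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
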