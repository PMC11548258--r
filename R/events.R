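#' Event-detection configuration
#'
#' @param area_diameter Fixation-area diameter in degrees of visual angle.
#'   The relevance analysis sweeps this over a grid from 0.1 to 2.5
#'   degrees; 1.0 is the reference value used when a single diameter is
#'   needed.
#' @param min_fixation_duration Minimum duration for a dispersion-qualified
#'   window to count as a fixation, seconds.
#' @param false_fixation_max_duration Upper duration bound for counting a
#'   dispersion-qualified window that is too short to be a fixation as a
#'   "false fixation"; must not exceed `min_fixation_duration`.
#' @param max_gap_interpolation Invalid-sample gaps up to this duration are
#'   linearly interpolated during cleaning; longer gaps split the recording
#'   into segments, seconds.
#' @return An object of class `event_config`.
#' @export
event_config <- function(area_diameter = 1.0,
                         min_fixation_duration = 0.1,
                         false_fixation_max_duration = 0.08,
                         max_gap_interpolation = 0.3) {
  stopifnot_scalar_pos(area_diameter, "area_diameter")
  stopifnot_scalar_pos(min_fixation_duration, "min_fixation_duration")
  stopifnot_scalar_pos(false_fixation_max_duration,
                       "false_fixation_max_duration", strict = FALSE)
  stopifnot_scalar_pos(max_gap_interpolation, "max_gap_interpolation",
                       strict = FALSE)
  if (false_fixation_max_duration > min_fixation_duration) {
    stop("`false_fixation_max_duration` must not exceed `min_fixation_duration`",
         call. = FALSE)
  }
  structure(list(area_diameter = area_diameter,
                 min_fixation_duration = min_fixation_duration,
                 false_fixation_max_duration = false_fixation_max_duration,
                 max_gap_interpolation = max_gap_interpolation),
            class = "event_config")
}

# Provenance token so characteristics refuse events computed from another
# recording.
rec_token <- function(rec) {
  paste(length(rec$t), format(rec$t[1], digits = 12),
        format(rec$t[length(rec$t)], digits = 12),
        format(sum(rec$x[rec$valid][1:min(50, sum(rec$valid))]), digits = 12),
        sep = "|")
}

#' Clean a gaze recording
#'
#' Linearly interpolates invalid samples inside gaps no longer than
#' `cfg$max_gap_interpolation`; longer gaps (and invalid runs at the
#' recording edges) are removed and split the recording into segments that
#' all later stages process independently, so no data are fabricated across
#' a long dropout.
#'
#' @param rec A [gaze_recording()].
#' @param cfg An [event_config()].
#' @return A `gaze_recording` containing only valid (possibly interpolated)
#'   samples, with a `segment` vector labelling independent segments.
#' @export
clean_recording <- function(rec, cfg = event_config()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(cfg, "event_config"))
  n <- length(rec$t)
  valid <- rec$valid
  x <- rec$x; y <- rec$y; t <- rec$t
  if (all(valid)) {
    out <- rec
    out$segment <- rep.int(1L, n)
    out$interpolated <- rep.int(FALSE, n)
    return(out)
  }
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- valid
  interpolated <- rep.int(FALSE, n)
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    interior <- i0 > 1L && i1 < n
    gap_dur <- if (interior) t[i1 + 1L] - t[i0 - 1L] else Inf
    if (interior && gap_dur <= cfg$max_gap_interpolation) {
      w <- (t[i0:i1] - t[i0 - 1L]) / gap_dur
      x[i0:i1] <- x[i0 - 1L] + w * (x[i1 + 1L] - x[i0 - 1L])
      y[i0:i1] <- y[i0 - 1L] + w * (y[i1 + 1L] - y[i0 - 1L])
      keep[i0:i1] <- TRUE
      interpolated[i0:i1] <- TRUE
    }
  }
  # label kept runs; every dropped interior run starts a new segment
  segment <- integer(n)
  seg <- 1L
  prev_kept <- FALSE
  rk <- rle(keep)
  ke <- cumsum(rk$lengths); ks <- ke - rk$lengths + 1L
  for (k in seq_along(rk$values)) {
    if (rk$values[k]) {
      segment[ks[k]:ke[k]] <- seg
      prev_kept <- TRUE
    } else {
      if (prev_kept) seg <- seg + 1L
      prev_kept <- FALSE
    }
  }
  out <- rec
  out$t <- t[keep]; out$x <- x[keep]; out$y <- y[keep]
  out$valid <- rep.int(TRUE, sum(keep))
  out$segment <- segment[keep]
  out$interpolated <- interpolated[keep]
  if (length(out$t)) {
    # drop empty segment ids, relabel consecutively
    out$segment <- as.integer(factor(out$segment))
  }
  out
}

#' Detect fixations with a dispersion threshold (I-DT)
#'
#' Scans each segment left to right for maximal windows whose dispersion --
#' the maximum pairwise Euclidean distance between samples, i.e. the
#' diameter of the occupied fixation area -- stays within
#' `cfg$area_diameter` and whose duration reaches
#' `cfg$min_fixation_duration`.  On a too-short qualifying window the start
#' advances one sample (classic I-DT); such windows are tallied as false
#' fixations.
#'
#' @param rec A cleaned [gaze_recording()] (see [clean_recording()]).
#' @param cfg An [event_config()].
#' @return A data frame with one row per fixation: `segment`, `start`,
#'   `end`, `duration` (s), `cx`, `cy` (centroid, deg), `dispersion` (deg),
#'   `path_length` (deg), `net_displacement` (deg).  Attributes:
#'   `false_fixations` (count), `area_diameter`, `rec_token`.
#' @export
detect_fixations <- function(rec, cfg = event_config()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(cfg, "event_config"))
  if (any(!rec$valid)) rec <- clean_recording(rec, cfg)
  segs <- unique(rec$segment)
  rows <- list()
  false_total <- 0L
  for (sg in segs) {
    sel <- rec$segment == sg
    t <- rec$t[sel]; x <- rec$x[sel]; y <- rec$y[sel]
    if (length(t) < 2L) next
    res <- idt_scan(t, x, y, cfg$area_diameter, cfg$min_fixation_duration,
                    cfg$false_fixation_max_duration)
    false_total <- false_total + res$false_fixations
    if (!length(res$start)) next
    st <- res$start; en <- res$end
    # vectorized window statistics via cumulative sums
    csx <- cumsum(x); csy <- cumsum(y)
    step <- sqrt(diff(x)^2 + diff(y)^2)
    csp <- c(0, cumsum(step))
    nsz <- en - st + 1L
    cx <- (csx[en] - csx[st] + x[st]) / nsz
    cy <- (csy[en] - csy[st] + y[st]) / nsz
    rows[[length(rows) + 1L]] <- data.frame(
      segment = sg, start = t[st], end = t[en], duration = t[en] - t[st],
      cx = cx, cy = cy, dispersion = res$dispersion,
      path_length = csp[en] - csp[st],
      net_displacement = sqrt((x[en] - x[st])^2 + (y[en] - y[st])^2))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(segment = integer(0), start = numeric(0), end = numeric(0),
               duration = numeric(0), cx = numeric(0), cy = numeric(0),
               dispersion = numeric(0), path_length = numeric(0),
               net_displacement = numeric(0))
  }
  attr(out, "false_fixations") <- false_total
  attr(out, "area_diameter") <- cfg$area_diameter
  attr(out, "rec_token") <- rec_token(rec)
  out
}

#' Derive saccades from consecutive fixations
#'
#' One saccade per consecutive fixation pair within a segment: its duration
#' is the inter-fixation interval, its length (amplitude) the Euclidean
#' angular distance between the flanking fixation centroids.  Peak velocity
#' is the maximum instantaneous sample-to-sample velocity over the
#' inter-fixation interval; mean velocity is length over duration.
#'
#' @param rec The cleaned recording the fixations came from.
#' @param fixations Output of [detect_fixations()] on `rec`.
#' @return A data frame with columns `segment`, `start`, `end`, `duration`,
#'   `length`, `peak_velocity`, `mean_velocity`; empty when fewer than two
#'   fixations share a segment.
#' @export
derive_saccades <- function(rec, fixations) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!identical(attr(fixations, "rec_token"), rec_token(rec))) {
    stop("fixations were not computed from this recording", call. = FALSE)
  }
  empty <- data.frame(segment = integer(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      length = numeric(0), peak_velocity = numeric(0),
                      mean_velocity = numeric(0))
  if (nrow(fixations) < 2L) {
    attr(empty, "rec_token") <- rec_token(rec)
    return(empty)
  }
  rows <- list()
  for (sg in unique(fixations$segment)) {
    fx <- fixations[fixations$segment == sg, , drop = FALSE]
    m <- nrow(fx)
    if (m < 2L) next
    sel <- rec$segment == sg
    t <- rec$t[sel]; x <- rec$x[sel]; y <- rec$y[sel]
    vt <- t[-length(t)]
    v <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
    st <- fx$end[-m]; en <- fx$start[-1L]
    len <- sqrt(diff(fx$cx)^2 + diff(fx$cy)^2)
    dur <- en - st
    # velocity samples with vt in [st, en)
    lo <- findInterval(st, vt, left.open = TRUE) + 1L
    hi <- findInterval(en, vt, left.open = TRUE)
    peak <- len / dur
    for (j in seq_along(st)) {
      if (lo[j] <= hi[j]) peak[j] <- max(v[lo[j]:hi[j]])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      segment = sg, start = st, end = en, duration = dur, length = len,
      peak_velocity = peak, mean_velocity = len / dur)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "rec_token") <- rec_token(rec)
  out
}

# Menger curvature of consecutive sample triplets: the reciprocal of the
# circumradius, 4 * area / (a * b * c); collinear or coincident triplets
# give 0.  Units 1/deg.
menger_curvature <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  x1 <- x[1:(n - 2)]; x2 <- x[2:(n - 1)]; x3 <- x[3:n]
  y1 <- y[1:(n - 2)]; y2 <- y[2:(n - 1)]; y3 <- y[3:n]
  area2 <- abs(x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))  # 2*area
  a <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  b <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  cc <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
  denom <- a * b * cc
  k <- ifelse(denom > 0, 2 * area2 / denom, 0)
  k
}

#' Per-sample gaze kinematics
#'
#' Instantaneous velocity is the angular distance between consecutive
#' samples over their time difference; acceleration is the modulus of the
#' change of the velocity vector over time; curvature is the Menger
#' curvature of each interior sample triplet (1/deg).  Per-second aggregates
#' (mean and minimum velocity, mean acceleration modulus, mean curvature)
#' are computed over non-overlapping 1-second bins anchored at each
#' segment's start; only complete bins are reported.  Samples fabricated by
#' gap interpolation are excluded from every kinematic estimate.
#'
#' @param rec A cleaned [gaze_recording()].
#' @return A list of class `kinematic_series` with data frames `velocity`
#'   (`t`, `v`), `acceleration` (`t`, `a`), `curvature` (`t`, `k`) and
#'   `per_second` (`segment`, `second`, `mean_velocity`, `min_velocity`,
#'   `mean_abs_acceleration`, `mean_curvature`).
#' @export
compute_kinematics <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  vel <- acc <- cur <- list()
  per_sec <- list()
  interp <- rec$interpolated %||% rep.int(FALSE, length(rec$t))
  for (sg in unique(rec$segment)) {
    sel <- rec$segment == sg
    t <- rec$t[sel]; x <- rec$x[sel]; y <- rec$y[sel]
    ip <- interp[sel]
    n <- length(t)
    if (n >= 2L) {
      dt <- diff(t)
      vx <- diff(x) / dt; vy <- diff(y) / dt
      v <- sqrt(vx^2 + vy^2)
      vt <- (t[-n] + t[-1]) / 2
      # estimates touching interpolated samples are cleaning artifacts,
      # not gaze, and are excluded
      v_ok <- !(ip[-n] | ip[-1])
      vel[[length(vel) + 1L]] <- data.frame(t = vt[v_ok], v = v[v_ok])
      a_ok <- logical(0)
      at <- numeric(0); a <- numeric(0)
      if (n >= 3L) {
        dt2 <- (t[3:n] - t[1:(n - 2)]) / 2
        a <- sqrt(diff(vx)^2 + diff(vy)^2) / dt2
        at <- t[2:(n - 1)]
        a_ok <- !(ip[1:(n - 2)] | ip[2:(n - 1)] | ip[3:n])
        acc[[length(acc) + 1L]] <- data.frame(t = at[a_ok], a = a[a_ok])
        k <- menger_curvature(x, y)
        cur[[length(cur) + 1L]] <- data.frame(t = at[a_ok], k = k[a_ok])
      }
      seg_dur <- t[n] - t[1]
      n_bins <- floor(seg_dur)
      if (n_bins >= 1L && any(v_ok)) {
        bin <- floor(vt - t[1])
        ok <- bin < n_bins & v_ok
        if (any(ok)) {
          b <- bin[ok]; vv <- v[ok]
          mean_v <- tapply(vv, b, mean)
          min_v <- tapply(vv, b, min)
          mean_a <- mean_k <- rep(NA_real_, length(mean_v))
          if (n >= 3L) {
            abin <- floor(at - t[1])
            aok <- abin < n_bins & a_ok
            if (any(aok)) {
              ma <- tapply(a[aok], abin[aok], mean)
              mean_a[match(names(ma), names(mean_v))] <- ma
              mk <- tapply(k[aok], abin[aok], mean)
              mean_k[match(names(mk), names(mean_v))] <- mk
            }
          }
          per_sec[[length(per_sec) + 1L]] <- data.frame(
            segment = sg, second = as.integer(names(mean_v)),
            mean_velocity = as.numeric(mean_v),
            min_velocity = as.numeric(min_v),
            mean_abs_acceleration = as.numeric(mean_a),
            mean_curvature = as.numeric(mean_k))
        }
      }
    }
  }
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  structure(list(
    velocity = bind0(vel, data.frame(t = numeric(0), v = numeric(0))),
    acceleration = bind0(acc, data.frame(t = numeric(0), a = numeric(0))),
    curvature = bind0(cur, data.frame(t = numeric(0), k = numeric(0))),
    per_second = bind0(per_sec, data.frame(
      segment = integer(0), second = integer(0), mean_velocity = numeric(0),
      min_velocity = numeric(0), mean_abs_acceleration = numeric(0),
      mean_curvature = numeric(0))),
    rec_token = rec_token(rec)),
    class = "kinematic_series")
}
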