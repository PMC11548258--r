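#' Label sessions by mental performance
#'
#' The Landolt-rings mental-performance index (Au) is split at a threshold:
#' `high` when `au >= threshold`, `low` otherwise.  Missing Au values give
#' `NA` and the session is excluded downstream.
#'
#' @param au Numeric Au values (the simulated index spans roughly -0.5..4).
#' @param threshold Split point, default 1.5.
#' @return A factor with levels `c("high", "low")`.
#' @export
label_by_mental_performance <- function(au, threshold = 1.5) {
  factor(ifelse(is.na(au), NA_character_,
                ifelse(au >= threshold, "high", "low")),
         levels = c("high", "low"))
}

#' Wilcoxon rank-sum screening of characteristics
#'
#' Two-sided rank-sum (Mann-Whitney) p-value per characteristic comparing
#' the high and low mental-performance groups.  The exact distribution is
#' used for combined group sizes up to 25 without ties; otherwise the
#' normal approximation with tie and continuity correction.  A
#' characteristic whose pooled values are all tied gets p = 1.
#'
#' @param matrix Data frame or matrix of session-level characteristic
#'   values (columns = characteristics).
#' @param labels Factor from [label_by_mental_performance()]; `NA` rows are
#'   dropped.
#' @return Named numeric vector of p-values (NA when a characteristic has
#'   fewer than one finite value per group).
#' @export
landolt_wilcoxon <- function(matrix, labels) {
  labels <- as.factor(labels)
  keep <- !is.na(labels)
  matrix <- as.data.frame(matrix)[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L) {
    stop("both a high and a low group are required", call. = FALSE)
  }
  g1 <- labels == levels(labels)[1L]
  vapply(matrix, function(v) {
    v <- as.numeric(v)
    a <- v[g1]; b <- v[!g1]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) return(NA_real_)
    pooled <- c(a, b)
    if (all(pooled == pooled[1L])) return(1)
    ties <- any(duplicated(pooled))
    exact <- !ties && length(pooled) <= 25L
    suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
}

#' Inner-session dynamics of a characteristic
#'
#' For each session a characteristic has a beginning value and an end value
#' (here computed on the first and last fraction of the session's
#' recording, standing in for the reaction-time task epochs that bracket a
#' session).  The statistic is the pair of proportions of sessions in which
#' the characteristic increased (end > start) and decreased (end < start),
#' and their maximum; exact ties count in neither proportion.
#'
#' `dynamics_from_blocks()` is the pure computation on start/end value
#' vectors; `inner_session_dynamics()` extracts the blocks from a study.
#'
#' @param start_values,end_values Per-session characteristic values at the
#'   session start and end; `NA` pairs are dropped.
#' @return `dynamics_from_blocks`: a list with `up`, `down`, `score`.
#' @export
dynamics_from_blocks <- function(start_values, end_values) {
  ok <- is.finite(start_values) & is.finite(end_values)
  s <- start_values[ok]; e <- end_values[ok]
  if (!length(s)) return(list(up = NA_real_, down = NA_real_,
                              score = NA_real_))
  up <- mean(e > s); down <- mean(e < s)
  list(up = up, down = down, score = max(up, down))
}

#' @rdname dynamics_from_blocks
#' @param study A `gaze_study`.
#' @param characteristics Character vector of catalogue names (default all).
#' @param cfg An [event_config()] giving the reference fixation-area
#'   diameter.
#' @param block_fraction Fraction of each session's recording used as the
#'   beginning and end blocks, default 0.1.
#' @return `inner_session_dynamics`: a data frame with one row per
#'   characteristic and columns `characteristic`, `up`, `down`, `score`.
#' @export
inner_session_dynamics <- function(study, characteristics = NULL,
                                   cfg = event_config(),
                                   block_fraction = 0.1) {
  characteristics <- characteristics %||% characteristic_catalogue()$name
  blocks <- session_block_characteristics(study, cfg, block_fraction)
  out <- lapply(characteristics, function(ch) {
    d <- dynamics_from_blocks(blocks$start[, ch], blocks$end[, ch])
    data.frame(characteristic = ch, up = d$up, down = d$down,
               score = d$score)
  })
  do.call(rbind, out)
}

# Characteristic vectors on the first and last block of every session.
session_block_characteristics <- function(study, cfg, block_fraction) {
  n <- length(study$recordings)
  nms <- characteristic_catalogue()$name
  mstart <- mend <- matrix(NA_real_, n, length(nms),
                           dimnames = list(NULL, nms))
  for (i in seq_len(n)) {
    rec <- clean_recording(study$recordings[[i]], cfg)
    t0 <- rec$t[1]; t1 <- rec$t[length(rec$t)]
    dur <- t1 - t0
    if (dur * block_fraction < 2) next  # too little data per block
    b1 <- crop_recording(rec, t0, t0 + block_fraction * dur)
    b2 <- crop_recording(rec, t1 - block_fraction * dur, t1)
    if (!is.null(b1)) mstart[i, ] <- compute_characteristics(b1, cfg = cfg)
    if (!is.null(b2)) mend[i, ] <- compute_characteristics(b2, cfg = cfg)
  }
  list(start = mstart, end = mend)
}

#' Maximal absolute correlation over fixation-area diameters
#'
#' Correlates session-level characteristic values, recomputed at each
#' diameter of the grid, with a session-level target, and returns the
#' signed correlation of maximal absolute value together with its diameter.
#' Diameters at which the characteristic is constant (or has fewer than
#' three paired observations) are skipped; if all are skipped the result is
#' `NA`.
#'
#' `max_abs_correlation()` is the pure computation on a sessions-by-
#' diameters value matrix.
#'
#' @param values_by_diameter Numeric matrix, sessions in rows, one column
#'   per grid diameter.
#' @param target Numeric vector of session-level target values.
#' @param diameter_grid Diameters corresponding to the columns.
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @return A list with `corr` and `diameter`.
#' @export
max_abs_correlation <- function(values_by_diameter, target, diameter_grid,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values_by_diameter <- as.matrix(values_by_diameter)
  stopifnot(ncol(values_by_diameter) == length(diameter_grid))
  best <- list(corr = NA_real_, diameter = NA_real_)
  for (j in seq_along(diameter_grid)) {
    v <- values_by_diameter[, j]
    ok <- is.finite(v) & is.finite(target)
    if (sum(ok) < 3L) next
    if (length(unique(v[ok])) < 2L || length(unique(target[ok])) < 2L) next
    r <- suppressWarnings(cor(v[ok], target[ok], method = method))
    if (is.na(r)) next
    if (is.na(best$corr) || abs(r) > abs(best$corr)) {
      best <- list(corr = r, diameter = diameter_grid[j])
    }
  }
  best
}

#' @rdname max_abs_correlation
#' @param study A `gaze_study`.
#' @param characteristic A catalogue name.
#' @param target `"crt_delta"` (post-session minus pre-session mean
#'   reaction time) or `"vasf_fatigue"` (the pre-session VAS-F fatigue
#'   score).
#' @param cfg An [event_config()] template (its diameter is replaced by
#'   each grid value).
#' @export
max_abs_correlation_over_diameters <- function(study, characteristic,
                                               target = c("crt_delta",
                                                          "vasf_fatigue"),
                                               diameter_grid = seq(0.1, 2.5,
                                                                   by = 0.1),
                                               method = c("spearman",
                                                          "pearson"),
                                               cfg = event_config()) {
  target <- match.arg(target)
  method <- match.arg(method)
  vals <- characteristics_by_diameter(study, diameter_grid, cfg)
  tgt <- target_values(study$ground_truth, target)
  max_abs_correlation(vals[, characteristic, ], tgt, diameter_grid, method)
}

target_values <- function(gt, target) {
  switch(target,
         crt_delta = gt$crt_post_mean - gt$crt_pre_mean,
         vasf_fatigue = gt$vasf_fatigue,
         stop(sprintf("unknown target: %s", target), call. = FALSE))
}

# sessions x characteristics x diameters array; kinematic components are
# diameter-independent and reused across the grid.
characteristics_by_diameter <- function(study, diameter_grid, cfg) {
  nms <- characteristic_catalogue()$name
  n <- length(study$recordings)
  out <- array(NA_real_, dim = c(n, length(nms), length(diameter_grid)),
               dimnames = list(NULL, nms, NULL))
  for (i in seq_len(n)) {
    rec <- clean_recording(study$recordings[[i]], cfg)
    kin <- compute_kinematics(rec)
    total_dur <- total_recording_duration(rec)
    for (j in seq_along(diameter_grid)) {
      cfg_j <- cfg
      cfg_j$area_diameter <- diameter_grid[j]
      fx <- detect_fixations(rec, cfg_j)
      sc <- derive_saccades(rec, fx)
      out[i, , j] <- char_from_components(fx, sc, kin, total_dur,
                                          attr(fx, "false_fixations"))
    }
  }
  out
}

#' Relevance configuration
#'
#' @param area_diameter Reference fixation-area diameter (deg) for the
#'   Wilcoxon and dynamics criteria.
#' @param diameter_grid Grid of diameters (deg) swept by the CRT and VAS-F
#'   correlation criteria.
#' @param method Correlation method for CRT/VAS-F, Spearman by default.
#' @param block_fraction Session fraction for the dynamics blocks.
#' @param au_threshold Mental-performance split threshold.
#' @param alpha Screening level.
#' @param event_cfg [event_config()] template.
#' @return An object of class `relevance_config`.
#' @export
relevance_config <- function(area_diameter = 1.0,
                             diameter_grid = seq(0.1, 2.5, by = 0.1),
                             method = "spearman",
                             block_fraction = 0.1,
                             au_threshold = 1.5,
                             alpha = 0.05,
                             event_cfg = event_config()) {
  event_cfg$area_diameter <- area_diameter
  structure(list(area_diameter = area_diameter,
                 diameter_grid = diameter_grid, method = method,
                 block_fraction = block_fraction,
                 au_threshold = au_threshold, alpha = alpha,
                 event_cfg = event_cfg),
            class = "relevance_config")
}

#' Compile the relevance table
#'
#' Runs all four relevance criteria over the whole catalogue: the Wilcoxon
#' rank test against the high/low mental-performance split and the
#' inner-session dynamics at the reference diameter, and the maximal
#' CRT-delta and VAS-F correlations over the diameter grid.  Rows are
#' sorted by ascending Wilcoxon p (catalogue order breaks ties).
#'
#' @param study A `gaze_study`.
#' @param cfg A [relevance_config()].
#' @return A data frame of class `relevance_table` with columns
#'   `characteristic`, `wilcoxon_p`, `dynamics_up`, `dynamics_down`,
#'   `dynamics_score`, `crt_corr`, `crt_diameter`, `vasf_corr`,
#'   `vasf_diameter`.
#' @export
compile_relevance_table <- function(study, cfg = relevance_config()) {
  stopifnot(inherits(cfg, "relevance_config"))
  nms <- characteristic_catalogue()$name
  gt <- study$ground_truth
  labels <- label_by_mental_performance(gt$au, cfg$au_threshold)
  ref_cfg <- cfg$event_cfg
  ## session-level characteristics on the full grid (reference diameter
  ## appended if absent)
  grid <- cfg$diameter_grid
  ref_in_grid <- any(abs(grid - cfg$area_diameter) < 1e-9)
  full_grid <- if (ref_in_grid) grid else c(grid, cfg$area_diameter)
  vals <- characteristics_by_diameter(study, full_grid, ref_cfg)
  ref_j <- which(abs(full_grid - cfg$area_diameter) < 1e-9)[1L]
  ref_vals <- vals[, , ref_j]
  p <- landolt_wilcoxon(as.data.frame(ref_vals), labels)
  dyn <- inner_session_dynamics(study, nms, ref_cfg, cfg$block_fraction)
  crt <- target_values(gt, "crt_delta")
  vasf <- target_values(gt, "vasf_fatigue")
  grid_j <- seq_along(grid)
  rows <- lapply(seq_along(nms), function(k) {
    mc <- max_abs_correlation(vals[, k, grid_j, drop = TRUE], crt, grid,
                              cfg$method)
    mv <- max_abs_correlation(vals[, k, grid_j, drop = TRUE], vasf, grid,
                              cfg$method)
    data.frame(characteristic = nms[k], wilcoxon_p = unname(p[k]),
               dynamics_up = dyn$up[k], dynamics_down = dyn$down[k],
               dynamics_score = dyn$score[k],
               crt_corr = mc$corr, crt_diameter = mc$diameter,
               vasf_corr = mv$corr, vasf_diameter = mv$diameter)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$wilcoxon_p), ]
  rownames(out) <- NULL
  class(out) <- c("relevance_table", "data.frame")
  out
}

#' @export
print.relevance_table <- function(x, ...) {
  cat("<relevance_table>\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Select characteristics from a relevance table
#'
#' Filters characteristics at `wilcoxon_p < alpha`, ranks the survivors by
#' ascending p, then descending dynamics score, then descending absolute
#' CRT correlation, keeps the ranked head, and unions in the expert
#' additions.  The head size and the additions are explicit configuration:
#' the final truncation in the original technique is expert judgment, not
#' computation, so by default the whole filtered ranked set is kept.
#'
#' @param table A `relevance_table`.
#' @param alpha Screening level, default 0.05.
#' @param expert_additions Characteristics added on theoretical grounds
#'   regardless of their screening result.
#' @param head_size Number of ranked characteristics kept before the
#'   expert additions; `NULL` keeps all filtered ones.
#' @return A list of class `selection_result` with elements `filtered`,
#'   `ranked`, `expert_additions`, `selected`.
#' @export
select_characteristics <- function(table, alpha = 0.05,
                                   expert_additions = character(),
                                   head_size = NULL) {
  stopifnot(is.data.frame(table), "wilcoxon_p" %in% names(table))
  unknown <- setdiff(expert_additions, characteristic_catalogue()$name)
  if (length(unknown)) {
    stop(sprintf("unknown expert addition(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(table$wilcoxon_p) & table$wilcoxon_p < alpha
  filt <- table[keep, , drop = FALSE]
  if (!nrow(filt) && !length(expert_additions)) {
    stop("no characteristic passes the screening level; review `alpha`",
         call. = FALSE)
  }
  ord <- order(filt$wilcoxon_p, -filt$dynamics_score, -abs(filt$crt_corr))
  ranked <- filt$characteristic[ord]
  head_set <- if (is.null(head_size)) ranked else head(ranked, head_size)
  structure(list(filtered = filt$characteristic,
                 ranked = ranked,
                 expert_additions = expert_additions,
                 selected = union(head_set, expert_additions)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d selected (%d filtered, %d expert)\n",
              length(x$selected), length(x$filtered),
              length(x$expert_additions)))
  cat(paste(" -", x$selected, collapse = "\n"), "\n")
  invisible(x)
}
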