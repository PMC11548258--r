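#' Assess fatigue on a streaming gaze recording
#'
#' Replays a recording as a stream: every `step_s` seconds the most recent
#' `window_s` seconds are turned into the model's feature vector (using
#' the feature definition stored at training time), pushed through the
#' stored preprocessing chain and classified.  Steps before the first full
#' window -- or windows with too little data to populate the features --
#' are reported with status `"insufficient_data"` instead of a label.
#'
#' @param model A `fatigue_model` from [grid_train()] whose training
#'   feature matrix carried a feature definition (i.e. it was built with
#'   [build_feature_matrix()]).
#' @param rec A [gaze_recording()] to replay.
#' @param window_s Sliding-window length in seconds, default 60.
#' @param step_s Step between assessments in seconds, default 1.
#' @return A data frame with one row per step: `time`, `status`
#'   (`"ok"`/`"insufficient_data"`), `label` (`high`/`low` or `NA`) and
#'   `score` (estimated probability of the fatigued class where the model
#'   family provides one).
#' @export
assess_stream <- function(model, rec, window_s = 60, step_s = 1) {
  stopifnot(inherits(model, "fatigue_model"),
            inherits(rec, "gaze_recording"))
  fdef <- model$feature_def
  if (is.null(fdef)) {
    stop(paste("the model carries no feature definition; train it on a",
               "matrix from build_feature_matrix()"), call. = FALSE)
  }
  cfg <- fdef$cfg
  rec <- clean_recording(rec, cfg)
  t0 <- rec$t[1]; t1 <- rec$t[length(rec$t)]
  times <- seq(t0 + step_s, t1 + 1e-9, by = step_s)
  n <- length(times)
  out <- data.frame(time = times,
                    status = rep("insufficient_data", n),
                    label = factor(rep(NA_character_, n),
                                   levels = model$levels),
                    score = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  need_chars <- any(c("selected", "all") %in% fdef$feature_sets)
  need_coord <- "coordinates" %in% fdef$feature_sets
  for (i in seq_len(n)) {
    e <- times[i]
    if (e - window_s < t0 - 1e-9) next
    w <- crop_recording(rec, e - window_s, e + 1e-9)
    if (is.null(w) || length(w$t) < 3L) next
    feats <- numeric(0)
    if (need_chars) feats <- c(feats, compute_characteristics(w, cfg = cfg))
    if (need_coord) feats <- c(feats, coordinate_summaries(w))
    fv <- feats[fdef$columns]
    if (anyNA(fv)) next
    xm <- matrix(fv, nrow = 1, dimnames = list(NULL, fdef$columns))
    xp <- apply_preprocess(xm, model$preprocess)
    pred <- predict_config(model$best$family, model$best$model, xp,
                           model$levels)
    out$status[i] <- "ok"
    out$label[i] <- pred
    out$score[i] <- predict_score(model$best$family, model$best$model, xp,
                                  positive = "low")
  }
  out
}
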