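test_that("duration-bin counting matches hand constructions", {
  # fixation durations 100, 200, 1000 ms at mutually distant positions
  rec <- epoch_recording(rbind(c(0, 0, 11), c(20, 0, 21), c(0, 20, 101)))
  cr <- clean_recording(rec)
  ch <- compute_characteristics(cr)
  expect_equal(unname(ch["pct_fixations_lt_150ms"]), 100 / 3,
               tolerance = 1e-9)
  expect_equal(unname(ch["pct_fixations_ge_150ms"]), 200 / 3,
               tolerance = 1e-9)
  minutes <- (length(rec$t) - 1) / 100 / 60
  expect_equal(unname(ch["fixations_gt_900ms_per_minute"]), 1 / minutes,
               tolerance = 1e-9)
  expect_equal(unname(ch["pct_fixations_150_900ms"]), 100 / 3,
               tolerance = 1e-9)
  expect_equal(unname(ch["total_duration_fixations_150_900ms"]), 0.2,
               tolerance = 1e-9)
})

test_that("speed and velocity in the fixation area differ exactly by path shape", {
  cfg <- event_config(area_diameter = 3)
  t <- (0:100) / 100
  straight <- gaze_recording(t, 2 * t, rep(0, 101))
  ch_s <- compute_characteristics(clean_recording(straight), cfg = cfg)
  expect_equal(unname(ch_s["avg_velocity_fixation"]), 2, tolerance = 1e-9)
  expect_equal(unname(ch_s["avg_speed_fixation"]), 2, tolerance = 1e-9)
  # zig-zag of equal net displacement and doubled path length
  dy <- sqrt(0.04^2 - 0.02^2)
  zig <- gaze_recording(t, 2 * t, rep(c(0, dy), length.out = 101))
  ch_z <- compute_characteristics(clean_recording(zig), cfg = cfg)
  expect_equal(unname(ch_z["avg_speed_fixation"]), 4, tolerance = 1e-3)
  expect_equal(unname(ch_z["avg_velocity_fixation"]), 2, tolerance = 1e-3)
})

test_that("complement and partition identities hold on simulated recordings", {
  for (s in 1:8) {
    rec <- clean_recording(simulate_recording(sim_params(), 20,
                                              seed = 3000 + s))
    fx <- detect_fixations(rec)
    ch <- compute_characteristics(rec, fixations = fx)
    expect_equal(unname(ch["pct_fixations_lt_150ms"] +
                          ch["pct_fixations_ge_150ms"]), 100,
                 tolerance = 1e-9)
    expect_equal(unname(ch["pct_fixations_lt_180ms"] +
                          ch["pct_fixations_ge_180ms"]), 100,
                 tolerance = 1e-9)
    # three duration bins partition total fixation time; the >= 900 ms bin
    # is recomputed independently from the fixation list
    prop_ge900 <- 100 * sum(fx$duration[fx$duration >= 0.9]) /
      sum(fx$duration)
    expect_equal(unname(ch["prop_time_fixations_lt_150ms"] +
                          ch["prop_time_fixations_150_900ms"]) + prop_ge900,
                 100, tolerance = 1e-9)
    # min <= mean <= max triples
    expect_lte(ch[["min_curvature"]], ch[["avg_curvature"]])
    expect_lte(ch[["avg_curvature"]], ch[["max_curvature"]])
    if (is.finite(ch[["min_saccade_length"]])) {
      expect_lte(ch[["min_saccade_length"]], ch[["avg_saccade_length"]])
      expect_lte(ch[["avg_saccade_length"]], ch[["max_saccade_length"]])
      expect_lte(ch[["avg_saccade_duration"]], ch[["max_saccade_duration"]])
    }
    expect_lte(ch[["min_velocity_fixation"]], ch[["avg_velocity_fixation"]])
  }
})

test_that("stretching time leaves percentages alone and halves per-minute counts", {
  rec <- epoch_recording(rbind(c(0, 0, 21), c(20, 0, 101), c(0, 20, 121)))
  slow <- gaze_recording(rec$t * 2, rec$x, rec$y, sample_rate = 50)
  ch1 <- compute_characteristics(clean_recording(rec))
  ch2 <- compute_characteristics(clean_recording(slow))
  pct <- grep("^pct_|^prop_", names(ch1), value = TRUE)
  expect_equal(ch1[pct], ch2[pct], tolerance = 1e-9)
  per_min <- c("fixations_gt_900ms_per_minute", "fixations_lt_180ms_per_minute")
  expect_equal(unname(ch1[per_min]), unname(2 * ch2[per_min]),
               tolerance = 1e-9)
})

test_that("series summaries match closed forms and the percentile oracle", {
  s <- summarize_series(rep(3.7, 10))
  expect_equal(unname(s), c(3.7, 0, 3.7, 3.7, 3.7, 3.7, 3.7))
  s2 <- summarize_series(1:100)
  expect_equal(unname(s2["mean"]), 50.5)
  expect_equal(unname(s2["p50"]), 50.5)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(5:60, 1))
    s3 <- summarize_series(x)
    expect_equal(unname(s3["p25"]), oracle_percentile(x, 0.25),
                 tolerance = 1e-12)
    expect_equal(unname(s3["p50"]), oracle_percentile(x, 0.5),
                 tolerance = 1e-12)
    expect_equal(unname(s3["p75"]), oracle_percentile(x, 0.75),
                 tolerance = 1e-12)
    expect_equal(unname(s3["sd"]), sd(x), tolerance = 1e-12)
  }
  expect_error(summarize_series(numeric(0)), "empty")
  expect_error(summarize_series(c(NA_real_, NA_real_)), "no finite")
  expect_equal(unname(summarize_series(1)["sd"]), 0)
})

test_that("window alignment and stationarity behave as specified", {
  p <- sim_params(blink_rate = 0)
  rec <- simulate_recording(p, 60, seed = 31)
  wc <- windowed_characteristics(rec, window_s = 30, step_s = 10)
  expect_equal(wc$window_end, c(30, 40, 50, 60))

  stat <- epoch_recording(cbind(0, 0, 1501))  # 15 s stationary
  ws <- windowed_characteristics(stat, window_s = 5, step_s = 5)
  expect_equal(nrow(ws), 3L)
  for (j in setdiff(names(ws), "window_end")) {
    expect_length(unique(ws[[j]]), 1L)
  }

  short <- windowed_characteristics(epoch_recording(cbind(0, 0, 600)),
                                    window_s = 30, step_s = 5)
  expect_equal(nrow(short), 0L)
})

test_that("windows inside one regime are unaffected by the other regime", {
  a <- simulate_recording(sim_params(blink_rate = 0), 30, seed = 41)
  b <- simulate_recording(sim_params(saccade_amplitude_mean = 8,
                                     blink_rate = 0), 30, seed = 42)
  comb <- gaze_recording(c(a$t, b$t + max(a$t) + 0.01), c(a$x, b$x),
                         c(a$y, b$y))
  w_comb <- windowed_characteristics(comb, window_s = 20, step_s = 5)
  w_a <- windowed_characteristics(a, window_s = 20, step_s = 5)
  inside <- w_comb$window_end <= 30
  expect_true(sum(inside) >= 3)
  expect_equal(w_comb[inside, ], w_a[seq_len(sum(inside)), ],
               tolerance = 1e-12)
})

test_that("feature matrices expose the requested sets deterministically", {
  st <- simulate_study(study_design(3, 1, 2, 20,
                                    fatigue_schedule = session_schedule,
                                    seed = 17))
  fm_sel <- build_feature_matrix(st, feature_sets = "selected")
  expect_equal(length(attr(fm_sel, "feature_columns")), 7L)
  expect_setequal(attr(fm_sel, "feature_columns"),
                  selected_characteristics())
  fm_coord <- build_feature_matrix(st, feature_sets = "coordinates")
  expect_equal(length(attr(fm_coord, "feature_columns")), 21L)
  fm_union <- build_feature_matrix(st,
                                   feature_sets = c("coordinates", "selected"))
  expect_equal(length(attr(fm_union, "feature_columns")), 28L)
  fm_sel2 <- build_feature_matrix(st, feature_sets = "selected")
  expect_identical(fm_sel, fm_sel2)
  expect_error(build_feature_matrix(st, feature_sets = "bogus"), "unknown")
})
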