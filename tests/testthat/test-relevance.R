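test_that("mental-performance labels split at the threshold", {
  expect_equal(as.character(label_by_mental_performance(c(1.5, 1.49, 4, -0.5))),
               c("high", "low", "high", "low"))
  expect_true(is.na(label_by_mental_performance(NA_real_)))
})

test_that("rank-sum screening matches the exact enumeration oracle", {
  set.seed(5)
  for (i in 1:12) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    a <- rnorm(m); b <- rnorm(n, sample(c(0, 1.5), 1))
    lab <- factor(rep(c("high", "low"), c(m, n)), levels = c("high", "low"))
    p <- landolt_wilcoxon(data.frame(v = c(a, b)), lab)
    expect_equal(unname(p), oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum screening is calibrated and powered as expected", {
  # identical distributions (one group a permutation of the other)
  set.seed(9)
  ps_null <- vapply(1:20, function(i) {
    x <- rnorm(12)
    lab <- factor(rep(c("high", "low"), each = 12))
    landolt_wilcoxon(data.frame(v = c(x, sample(x))), lab)
  }, numeric(1))
  expect_true(all(ps_null >= 0.5))
  # groups shifted by 3 pooled SDs: essentially always detected
  hits <- vapply(1:100, function(i) {
    set.seed(4000 + i)
    a <- rnorm(20); b <- rnorm(20, 3)
    lab <- factor(rep(c("high", "low"), each = 20))
    landolt_wilcoxon(data.frame(v = c(a, b)), lab) < 0.05
  }, logical(1))
  expect_gte(sum(hits), 99)
  # all-tied values give p = 1; empty group is an error
  lab2 <- factor(rep(c("high", "low"), each = 3))
  expect_equal(unname(landolt_wilcoxon(data.frame(v = rep(1, 6)), lab2)), 1)
  expect_error(landolt_wilcoxon(data.frame(v = 1:3),
                                factor(rep("high", 3),
                                       levels = c("high", "low"))),
               "both")
})

test_that("rank-sum p is invariant under monotone transforms and label swap", {
  set.seed(11)
  x <- rexp(14); y <- rexp(10, 0.5)
  lab <- factor(rep(c("high", "low"), c(14, 10)), levels = c("high", "low"))
  p0 <- landolt_wilcoxon(data.frame(v = c(x, y)), lab)
  p1 <- landolt_wilcoxon(data.frame(v = log(c(x, y))), lab)
  expect_equal(p0, p1, tolerance = 1e-12)
  swapped <- factor(ifelse(lab == "high", "low", "high"),
                    levels = c("high", "low"))
  p2 <- landolt_wilcoxon(data.frame(v = c(x, y)), swapped)
  expect_equal(unname(p0), unname(p2), tolerance = 1e-12)
})

test_that("inner-session dynamics counts direction proportions with tie rule", {
  start <- rep(0, 100)
  end <- c(rep(1, 61), rep(-1, 19), rep(0, 20))
  d <- dynamics_from_blocks(start, end)
  expect_equal(d$up, 0.61)
  expect_equal(d$down, 0.19)
  expect_equal(d$score, 0.61)
  d2 <- dynamics_from_blocks(1:10, 2:11)
  expect_equal(unlist(d2), c(up = 1, down = 0, score = 1))
  d3 <- dynamics_from_blocks(1:10, 1:10)
  expect_equal(unlist(d3), c(up = 0, down = 0, score = 0))
  # up + down <= 1 always, = 1 without ties
  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(30); e <- rnorm(30)
    di <- dynamics_from_blocks(s, e)
    expect_equal(di$up + di$down, 1)
    expect_equal(di$score, max(di$up, di$down))
  }
})

test_that("the maximal correlation over diameters finds the planted diameter", {
  set.seed(21)
  target <- rnorm(30)
  grid <- seq(0.5, 2.5, by = 0.5)
  vals <- matrix(rnorm(30 * 5, sd = 0.5), 30, 5)
  vals[, 3] <- 2 * target + 1  # exact linear function at diameter 1.5
  mc <- max_abs_correlation(vals, target, grid)
  expect_equal(mc$corr, 1)
  expect_equal(mc$diameter, 1.5)
  mc_neg <- max_abs_correlation(-vals[, 3, drop = FALSE], target, 1.0)
  expect_equal(mc_neg$corr, -1)
  # degenerate single-diameter grid reduces to a plain correlation
  v <- rnorm(30)
  mc1 <- max_abs_correlation(matrix(v), target, 0.7)
  expect_equal(mc1$corr, cor(v, target, method = "spearman"))
  # the max over the grid dominates every single diameter
  mcg <- max_abs_correlation(vals, target, grid)
  for (j in seq_along(grid)) {
    expect_gte(abs(mcg$corr),
               abs(max_abs_correlation(vals[, j, drop = FALSE], target,
                                       grid[j])$corr))
  }
  # constant characteristic columns are skipped
  const <- matrix(1, 30, 2)
  expect_true(is.na(max_abs_correlation(const, target, c(0.5, 1))$corr))
})

test_that("under independence the max correlation clears the permutation bar at the nominal rate", {
  n <- 30; n_perm <- 199
  excess <- vapply(1:200, function(s) {
    set.seed(7000 + s)
    v <- rnorm(n); tgt <- rnorm(n)
    r <- abs(cor(v, tgt, method = "spearman"))
    perm <- vapply(seq_len(n_perm), function(i) {
      abs(cor(v, sample(tgt), method = "spearman"))
    }, numeric(1))
    r > quantile(perm, 0.95)
  }, logical(1))
  expect_gt(mean(excess), 0.005)
  expect_lt(mean(excess), 0.12)
})

test_that("the relevance table covers the catalogue and respects invariants", {
  des <- study_design(6, 1, 3, 20, fatigue_schedule = session_schedule,
                      seed = 23)
  st <- simulate_study(des)
  cfg <- relevance_config(diameter_grid = seq(0.5, 2.5, by = 0.5))
  tab <- compile_relevance_table(st, cfg)
  expect_equal(nrow(tab), 27L)
  expect_setequal(tab$characteristic, characteristic_catalogue()$name)
  expect_true(!is.unsorted(tab$wilcoxon_p, na.rm = TRUE))
  ok <- !is.na(tab$wilcoxon_p)
  expect_true(all(tab$wilcoxon_p[ok] >= 0 & tab$wilcoxon_p[ok] <= 1))
  expect_true(all(tab$dynamics_up + tab$dynamics_down <= 1 + 1e-12,
                  na.rm = TRUE))
  expect_true(all(abs(tab$crt_corr) <= 1, na.rm = TRUE))
  expect_true(all(tab$crt_diameter %in% cfg$diameter_grid |
                    is.na(tab$crt_diameter)))
})

test_that("selection filters, ranks and unions expert additions", {
  tab <- data.frame(
    characteristic = characteristic_catalogue()$name,
    wilcoxon_p = c(seq(0.001, 0.04, length.out = 10),
                   seq(0.1, 0.9, length.out = 17)),
    dynamics_up = 0.6, dynamics_down = 0.2, dynamics_score = 0.6,
    crt_corr = 0.5, crt_diameter = 1, vasf_corr = 0.3, vasf_diameter = 1)
  # the expert-added characteristic screens poorly by construction
  tab$wilcoxon_p[tab$characteristic == "avg_speed_fixation"] <- 0.5
  # the original configuration: screening level 0.05, head of 6, one
  # expert addition -> a seven-element selected set
  sel <- select_characteristics(tab, alpha = 0.05,
                                expert_additions = "avg_speed_fixation",
                                head_size = 6)
  expect_length(sel$selected, 7L)
  all_sel <- select_characteristics(tab, alpha = 1.0)
  expect_length(all_sel$selected, 27L)
  none <- tab; none$wilcoxon_p <- 0.5
  expect_error(select_characteristics(none, alpha = 0.05), "alpha")
  s2 <- select_characteristics(none, alpha = 0.05,
                               expert_additions = "avg_curvature")
  expect_equal(s2$selected, "avg_curvature")
  expect_error(select_characteristics(tab, expert_additions = "nope"),
               "unknown")
  # ranking is by p, then dynamics score, then |CRT|
  tab2 <- tab[1:3, ]
  tab2$wilcoxon_p <- c(0.01, 0.01, 0.001)
  tab2$dynamics_score <- c(0.9, 0.5, 0.1)
  sel2 <- select_characteristics(tab2, alpha = 0.05)
  expect_equal(sel2$ranked,
               tab2$characteristic[c(3, 1, 2)])
})

test_that("inner-session dynamics recover the planted within-session ramp", {
  # fixation durations lengthen within every session; the end-block value
  # of the short-fixation share should fall in most sessions
  des <- study_design(8, 1, 2, 30,
                      fatigue_schedule = function(p, d, s, dn) 0.1,
                      within_session_increment = 0.8, seed = 29)
  st <- simulate_study(des)
  dyn <- inner_session_dynamics(st, "prop_time_fixations_lt_150ms",
                                block_fraction = 0.25)
  expect_gt(dyn$down, dyn$up)
  expect_equal(dyn$score, max(dyn$up, dyn$down))
})
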