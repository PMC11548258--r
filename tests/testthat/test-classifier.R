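test_that("z-score normalization uses the population convention and is idempotent", {
  z <- zscore_normalize(matrix(c(1, 2, 3), ncol = 1,
                               dimnames = list(NULL, "a")))
  expect_equal(as.numeric(z$matrix), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-9)
  set.seed(2)
  m <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  z1 <- zscore_normalize(m)
  z2 <- zscore_normalize(z1$matrix)
  expect_equal(z2$matrix, z1$matrix, tolerance = 1e-10)
  # replaying the stored parameters reproduces the fit exactly
  replay <- zscore_normalize(m, params = z1$params)
  expect_identical(replay$matrix, z1$matrix)
  expect_error(zscore_normalize(cbind(m, d = rep(1, 20))), "zero-variance")
})

test_that("quasi-constant removal matches a direct frequency count", {
  m <- cbind(const = rep(1, 100), mostly0 = c(rep(0, 99), 1),
             ok = rnorm(100))
  out <- remove_quasi_constant(m, 0.99)
  expect_equal(colnames(out), "ok")
  out2 <- remove_quasi_constant(m, 0.995)
  expect_equal(colnames(out2), c("mostly0", "ok"))
  expect_error(remove_quasi_constant(m[, 1, drop = FALSE], 0.5), "all features")
  set.seed(3)
  for (i in 1:5) {
    mm <- matrix(sample(0:3, 200, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)), 50, 4)
    colnames(mm) <- paste0("c", 1:4)
    thr <- runif(1, 0.5, 0.9)
    got <- tryCatch(colnames(remove_quasi_constant(mm, thr)),
                    error = function(e) character(0))
    want <- colnames(mm)[vapply(seq_len(4), function(j) {
      max(table(mm[, j])) / 50 < thr
    }, logical(1))]
    expect_equal(got, want)
  }
})

test_that("Kendall-correlation removal matches the pair-counting oracle", {
  set.seed(4)
  x <- rnorm(25)
  m <- cbind(a = x, b = x, c = exp(x), d = rnorm(25))
  out <- remove_kendall_correlated(m, 0.9)
  expect_equal(colnames(out), c("a", "d"))  # duplicate and monotone copy dropped
  for (i in 1:5) {
    mm <- matrix(rnorm(20 * 5), 20, 5)
    mm[, 2] <- mm[, 1] + rnorm(20, sd = 0.1)
    colnames(mm) <- paste0("c", 1:5)
    thr <- runif(1, 0.4, 0.95)
    got <- colnames(remove_kendall_correlated(mm, thr))
    # replicate the left-to-right scan with the brute-force tau
    kept <- 1L
    for (j in 2:5) {
      taus <- abs(vapply(kept, function(k) {
        oracle_kendall_tau(mm[, j], mm[, k])
      }, numeric(1)))
      if (all(taus < thr)) kept <- c(kept, j)
    }
    expect_equal(got, colnames(mm)[kept])
  }
})

test_that("PCA keeps the smallest component count reaching the variance target", {
  set.seed(5)
  u <- rnorm(30); v <- rnorm(4)
  rank1 <- u %*% t(v)
  pr <- pca_reduce(rank1, 0.95)
  expect_equal(pr$transform$k, 1L)
  iso <- matrix(rnorm(40 * 5), 40, 5)
  pr_full <- pca_reduce(iso, 1.0)
  expect_equal(pr_full$transform$k, 5L)
  expect_error(pca_reduce(iso, 0), "variance_kept")
  # reconstruction error is non-increasing in the component count
  zc <- scale(iso, scale = FALSE)
  pc <- prcomp(iso)
  errs <- vapply(1:5, function(k) {
    rec <- pc$x[, 1:k, drop = FALSE] %*% t(pc$rotation[, 1:k, drop = FALSE])
    sum((zc - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # the stored transform projects new data identically
  again <- pca_reduce(iso, transform = pr_full$transform)
  expect_equal(again$matrix, pr_full$matrix, tolerance = 1e-12)
})

test_that("the model grid enumerates the configured families", {
  g <- model_grid()
  expect_equal(sum(g$family == "random_forest"), 10L)
  expect_equal(sum(g$family == "decision_tree"), 2L)
  expect_equal(sum(g$family == "knn"), 20L)
  expect_equal(sum(g$family == "mlp"), 20L)
  expect_equal(sum(g$family == "svm"), 4L)
  expect_equal(nrow(model_grid("random_forest")), 10L)
})

test_that("well-separated classes are classified perfectly by every family", {
  set.seed(6)
  n <- 40
  x <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 8), n, 3))
  colnames(x) <- paste0("f", 1:3)
  lab <- factor(rep(c("high", "low"), each = n), levels = c("high", "low"))
  cfg <- pipeline_config(test_per_class = 10, cv_folds = 5, seed = 3,
                         pca_variance_kept = NA)
  for (fam in c("random_forest", "decision_tree", "knn",
                "logistic_regression", "svm")) {
    m <- grid_train(x, lab, families = fam, cfg = cfg)
    expect_equal(m$best$split_accuracy, 1,
                 info = fam)
    expect_equal(m$best$split_f1, 1, info = fam)
  }
  m_mlp <- grid_train(x, lab, families = "mlp", cfg = cfg)
  expect_equal(m_mlp$best$split_accuracy, 1)
})

test_that("classification metrics match their closed forms", {
  lv <- c("high", "low")
  pred <- factor(rep(c("low", "high", "low", "high"), c(80, 20, 20, 80)), lv)
  act <- factor(rep(c("low", "low", "high", "high"), c(80, 20, 20, 80)), lv)
  met <- classification_metrics(pred, act)
  expect_equal(met$accuracy, 0.8)
  expect_equal(met$f1, 0.8)
  # degenerate single-class predictions on balanced data
  allpos <- factor(rep("low", 100), lv)
  bal <- factor(rep(lv, 50), lv)
  m1 <- classification_metrics(allpos, bal)
  expect_equal(m1$accuracy, 0.5)
  expect_equal(m1$f1, 2 / 3)
  allneg <- factor(rep("high", 100), lv)
  m2 <- classification_metrics(allneg, bal)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$f1, 0)
  perfect <- classification_metrics(bal, bal)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
})

test_that("the pipeline is deterministic under a fixed seed", {
  set.seed(7)
  x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  lab <- factor(rep(c("high", "low"), 100), levels = c("high", "low"))
  cfg <- pipeline_config(test_per_class = 30, cv_folds = 5, seed = 11)
  m1 <- grid_train(x, lab, families = c("random_forest", "decision_tree"),
                   cfg = cfg)
  m2 <- grid_train(x, lab, families = c("random_forest", "decision_tree"),
                   cfg = cfg)
  expect_identical(m1$report, m2$report)
  expect_identical(m1$best$value, m2$best$value)
})

test_that("evaluate_model applies the stored transforms to held-out data", {
  set.seed(8)
  n <- 60
  x <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 6), n, 3))
  colnames(x) <- paste0("f", 1:3)
  lab <- factor(rep(c("high", "low"), each = n), levels = c("high", "low"))
  cfg <- pipeline_config(test_per_class = 15, cv_folds = 5, seed = 2)
  m <- grid_train(x, lab, families = "random_forest", cfg = cfg)
  xt <- rbind(matrix(rnorm(30, 0), 10, 3), matrix(rnorm(30, 6), 10, 3))
  colnames(xt) <- paste0("f", 1:3)
  labt <- factor(rep(c("high", "low"), each = 10), levels = c("high", "low"))
  met <- evaluate_model(m, xt, labt)
  expect_equal(met$accuracy, 1)
  bad <- xt; colnames(bad) <- paste0("g", 1:3)
  expect_error(evaluate_model(m, bad, labt), "mismatch")
})
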