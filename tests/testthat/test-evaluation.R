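test_that("accuracy counts matching samples", {
  expect_equal(marker_accuracy(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.75)
  expect_equal(marker_accuracy(rep(1, 5), rep(1, 5)), 1)
  expect_equal(marker_accuracy(c(1, 0), c(0, 1)), 0)
  expect_error(marker_accuracy(c(1, 0), c(1, 0, 0)), "lengths")
  # accuracy and mismatch fraction are complementary
  set.seed(41)
  a <- rbinom(100, 1, 0.5); b <- rbinom(100, 1, 0.5)
  expect_equal(marker_accuracy(a, b) + mean(a != b), 1)
})

test_that("phi correlation handles perfect, inverse and degenerate markers", {
  expect_equal(marker_correlation(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(marker_correlation(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_equal(marker_correlation(rep(1, 4), rep(1, 4)), 1)
  expect_equal(marker_correlation(rep(1, 4), c(1, 1, 0, 1)), 0)
  set.seed(42)
  a <- rbinom(10000, 1, 0.5); b <- rbinom(10000, 1, 0.5)
  expect_lt(abs(marker_correlation(a, b)), 3 / sqrt(10000))
})

test_that("threshold sweep metrics equal direct per-sample evaluation", {
  set.seed(43)
  for (rep in 1:10) {
    score <- sample(round(rnorm(60), 1))  # deliberate ties
    truth <- rbinom(60, 1, 0.4)
    gammas <- c(-Inf, sort(runif(15, -2, 2)), score[4], Inf)
    got <- imudetect:::threshold_metrics(score, truth, gammas)
    ref <- oracle_threshold_metrics(score, truth, gammas)
    expect_equal(got$accuracy, unname(ref[, "accuracy"]))
    expect_equal(got$correlation, unname(ref[, "correlation"]))
  }
})

test_that("ROC curves span (0,0) to (1,1) and AUC follows threshold symmetry", {
  score <- c(0.1, 0.2, 0.8, 0.9)
  truth <- c(0, 0, 1, 1)
  roc <- roc_points(score, truth)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_equal(roc_auc(roc), 1)

  const <- roc_points(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(roc_auc(const), 0.5)

  set.seed(44)
  s <- rnorm(200); y <- rbinom(200, 1, 0.5)
  expect_equal(roc_auc(roc_points(-s, y)), 1 - roc_auc(roc_points(s, y)),
               tolerance = 1e-12)
  expect_error(roc_points(s, rep(1, 200)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic and pROC agrees", {
  expect_equal(roc_auc(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(roc_auc(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
  set.seed(45)
  for (rep in 1:8) {
    score <- sample(round(rnorm(300), 1))  # with ties
    truth <- rbinom(300, 1, 0.5)
    auc <- roc_auc(roc_points(score, truth))
    expect_equal(auc, oracle_mw_auc(score, truth), tolerance = 1e-9)
  }
  score <- rnorm(500); truth <- rbinom(500, 1, 0.5)
  auc_proc <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                             direction = "<")))
  expect_equal(roc_auc(roc_points(score, truth)), auc_proc,
               tolerance = 1e-9)
  # random scores against random labels sit at chance level
  set.seed(46)
  s <- rnorm(10000); y <- rbinom(10000, 1, 0.5)
  expect_equal(roc_auc(roc_points(s, y)), 0.5, tolerance = 0.02)
})

test_that("vertical ROC averaging preserves curves and mixes areas linearly", {
  step <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  diag <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  same <- average_roc(list(step, step))
  expect_equal(same$auc, 1, tolerance = 1e-6)
  mix <- average_roc(list(step, diag))
  expect_equal(mix$auc, 0.75, tolerance = 0.01)
  expect_true(all(diff(mix$curve$tpr) >= -1e-12))
})

test_that("grid search finds the separating configuration on a clean fixture", {
  # burst runs to the end of the recording: every active sample's frame is
  # then fully active, so a threshold at the full-burst statistic separates
  # the classes exactly
  rec <- burst_recording(from = 120, to = 300, rate = 40)
  gs <- grid_search(rec, "ared", grid = list(windows = c(2L, 4L, 8L),
                                             shifts = 1L,
                                             orders = NA_integer_),
                    noise = noise_profile(1e-4, 1))
  expect_equal(gs$best$accuracy, 1.0)
  expect_equal(gs$best_correlation, 1.0)
})

test_that("grid search honors singleton grids and improves with refinement", {
  set.seed(47)
  rec <- synth_imu(n_activities = 2)
  single <- grid_search(rec, "shod",
                        grid = list(windows = 7L, shifts = 1L,
                                    orders = NA_integer_))
  expect_equal(single$best$window, 7)
  wider <- grid_search(rec, "shod",
                       grid = list(windows = c(3L, 7L, 15L), shifts = 1L,
                                   orders = NA_integer_))
  expect_gte(wider$best$accuracy, single$best$accuracy)
  norec <- synth_imu(n_activities = 2)
  norec$truth_marker <- NULL
  expect_error(grid_search(norec, "shod"), "truth")
})

test_that("Monte-Carlo summaries are seed-reproducible and match direct formulas", {
  grids <- list(amvd = list(windows = c(5L, 10L), shifts = 1L,
                            orders = NA_integer_))
  b1 <- monte_carlo("amvd", n_runs = 3, seed = 5, grids = grids,
                    n_activities = 3)
  b2 <- monte_carlo("amvd", n_runs = 3, seed = 5, grids = grids,
                    n_activities = 3)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$runs, b2$runs)
  acc <- b1$runs$accuracy
  expect_equal(b1$summary$accuracy, mean(acc))
  expect_equal(b1$summary$accuracy_sd, sd(acc))  # unbiased denominator
})

test_that("the combined-sensor detector outperforms moving variance on synthesized signals", {
  b <- monte_carlo(c("shod", "amvd"), n_runs = 5, seed = 6,
                   n_activities = 5)
  s <- b$summary
  expect_gt(s$accuracy[s$detector == "SHOD"],
            s$accuracy[s$detector == "AMVD"])
})
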