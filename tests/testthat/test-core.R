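test_that("input combination modes compute the expected per-sample series", {
  rec <- imu_recording(matrix(c(3, 4, 0), 1, 3), matrix(c(0, 2, 0), 1, 3), 50)
  expect_equal(input_combination(rec, "acc"), 5)
  expect_equal(input_combination(rec, "ang"), 2)
  expect_equal(input_combination(rec, "sum"), 7)
  expect_equal(input_combination(rec, "prod"), 10)

  rec2 <- imu_recording(matrix(c(1, 0, 0), 1, 3), matrix(c(0, 2, 0), 1, 3), 50)
  expect_equal(input_combination(rec2, "sum"), 3)
  expect_equal(input_combination(rec2, "prod"), 2)

  rec3 <- imu_recording(matrix(rnorm(30), 10, 3), matrix(0, 10, 3), 50)
  expect_equal(input_combination(rec3, "prod"), rep(0, 10))

  expect_error(input_combination(rec, "magnitude"), "unknown")
})

test_that("recording container enforces its invariants", {
  expect_error(imu_recording(matrix(0, 5, 3), matrix(0, 4, 3), 50), "same")
  expect_error(imu_recording(matrix(0, 5, 2), matrix(0, 5, 3), 50), "3 columns")
  expect_error(imu_recording(matrix(0, 5, 3), matrix(0, 5, 3), -1), "fs")
  expect_error(imu_recording(matrix(0, 5, 3), matrix(0, 5, 3), 50,
                             truth_marker = c(0, 1, 2, 0, 1)), "0 or 1")
  expect_error(imu_recording(matrix(0, 5, 3), matrix(0, 5, 3), 50,
                             truth_marker = c(0, 1)), "length")
})

test_that("threshold_marker broadcasts frame decisions onto samples", {
  f <- imu_fom(c(0.1, 0.9, 0.1), 1:3, window = 1, shift = 1)
  expect_equal(threshold_marker(f, 0.5, 3), c(0L, 1L, 0L))
  # equality counts as active
  expect_equal(threshold_marker(f, 0.9, 3), c(0L, 1L, 0L))
  expect_equal(threshold_marker(f, 0.90000001, 3), c(0L, 0L, 0L))
  # all-static when gamma above everything
  expect_equal(threshold_marker(f, 2, 3), c(0L, 0L, 0L))

  # a frame owns `shift` samples from its start; trailing samples inherit
  # the last decision
  f2 <- imu_fom(c(1, 0, 1), frame_starts = c(1, 4, 7), window = 4, shift = 3)
  expect_equal(threshold_marker(f2, 0.5, 12),
               c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))

  expect_error(imu_fom(numeric(0), integer(0), 1, 1), "nonempty")
})

test_that("raising the threshold never turns a static sample active", {
  set.seed(42)
  for (rep in 1:20) {
    v <- rnorm(30)
    f <- imu_fom(v, seq_along(v), 1, 1)
    gammas <- sort(rnorm(8))
    prev <- threshold_marker(f, gammas[1], 30)
    for (g in gammas[-1]) {
      cur <- threshold_marker(f, g, 30)
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("run_detector returns a full-length marker for every detector", {
  set.seed(7)
  rec <- synth_imu(n_activities = 2)
  t_n <- n_samples(rec)
  for (m in c("amvd", "amd", "ared", "shod", "frd", "fsd", "ltsd",
              "mbgtd", "mbcd")) {
    cfg <- detector_config(window = 8, threshold = 1,
                           shift = if (m %in% c("fsd", "ltsd")) 4L else 1L,
                           input_mode = "prod")
    det <- run_detector(rec, m, cfg)
    expect_length(det$marker, t_n)
    expect_true(all(det$marker %in% c(0L, 1L)), label = m)
  }
})

test_that("a static noiseless recording is classified all-static, and a zero threshold marks everything active", {
  rec <- static_recording()
  for (m in c("amvd", "amd", "ared", "shod")) {
    det <- run_detector(rec, m, detector_config(window = 10, threshold = 0.5))
    expect_equal(det$marker, rep(0L, n_samples(rec)), label = m)
    det0 <- run_detector(rec, m, detector_config(window = 10, threshold = 0))
    expect_equal(det0$marker, rep(1L, n_samples(rec)), label = m)
    expect_true(all(det0$fom$values >= 0))
  }
})

test_that("run_detector rejects short recordings and warns on ignored shift", {
  rec <- static_recording(t_n = 5)
  expect_error(run_detector(rec, "shod", detector_config(window = 10)),
               "shorter")
  rec2 <- static_recording()
  expect_warning(
    run_detector(rec2, "amvd", detector_config(window = 10, shift = 5)),
    "ignored")
})

test_that("detector figure of merit localizes a synthetic activity burst", {
  rec <- burst_recording(from = 120, to = 200, rate = 40)
  noise <- noise_profile(1e-4, 1)
  det <- run_detector(rec, "shod", detector_config(window = 10, threshold = 100),
                      noise = noise)
  expect_true(all(det$marker[130:190] == 1))
  expect_true(all(det$marker[1:100] == 0))
  expect_true(all(det$marker[230:300] == 0))
  # frames fully inside the burst match the direct formula
  v <- oracle_shod(rec$accel, rec$gyro, 10, 1e-4, 1)
  expect_equal(det$fom$values, v, tolerance = 1e-12)
})
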