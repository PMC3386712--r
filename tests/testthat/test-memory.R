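test_that("MBGTD scores step buffers and scales with the data", {
  expect_equal(as.numeric(mbgtd_fom(rep(2.5, 8))), 0)
  v <- mbgtd_fom(c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(v), 1)
  expect_equal(attr(v, "split"), c(1L, 4L))
  set.seed(31)
  x <- rnorm(10)
  expect_equal(as.numeric(mbgtd_fom(3 * x)), 3 * as.numeric(mbgtd_fom(x)),
               tolerance = 1e-12)
  expect_error(mbgtd_fom(1), "2 samples")
})

test_that("MBGTD and its sliding scan match brute-force split enumeration", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(3:15, 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 50), 1))
    expect_equal(as.numeric(mbgtd_fom(x)), oracle_mbgtd(x),
                 tolerance = 1e-10)
  }
  x <- rnorm(80)
  v <- sliding_memory_detector(x, 8, "mbgtd")$fom$values
  for (k in c(1, 37, 73))
    expect_equal(v[k], oracle_mbgtd(x[k:(k + 7)]), tolerance = 1e-10)
})

test_that("Parzen weights and densities follow the Gaussian kernel", {
  expect_equal(parzen_weight(1.7, 1.7, 0.3), 1)
  expect_equal(parzen_weight(0, 0.3, 0.3), exp(-0.5))
  expect_error(parzen_weight(0, 1, 0), "positive")
  set.seed(33)
  smp <- rnorm(200)
  grid <- seq(-6, 6, by = 0.01)
  dens <- parzen_density(grid, smp, 0.3)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 0.02)
})

test_that("MBCD scores distribution changes and ignores translations", {
  expect_equal(as.numeric(mbcd_fom(rep(1, 6), lambda = 0.5)), 0)
  v <- mbcd_fom(c(0, 0, 0, 5, 5, 5), lambda = 0.5)
  expect_gt(as.numeric(v), 0)
  expect_equal(attr(v, "split")[2], 4L)
  set.seed(34)
  x <- rnorm(9)
  expect_equal(as.numeric(mbcd_fom(x + 100, lambda = 0.4)),
               as.numeric(mbcd_fom(x, lambda = 0.4)), tolerance = 1e-9)
  expect_error(mbcd_fom(c(1, 2), lambda = 1), "3 samples")
  expect_error(mbcd_fom(rnorm(5), lambda = -1), "positive")
})

test_that("MBCD and its sliding scan match brute-force evaluation of the split ratio", {
  set.seed(35)
  for (rep in 1:25) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    lam <- runif(1, 0.2, 2)
    expect_equal(as.numeric(mbcd_fom(x, lambda = lam)),
                 oracle_mbcd(x, lam), tolerance = 1e-10)
  }
  x <- c(rnorm(30), rnorm(30, mean = 4))
  v <- sliding_memory_detector(x, 7, "mbcd", lambda = 0.8)$fom$values
  for (k in c(1, 27, 50))
    expect_equal(v[k], oracle_mbcd(x[k:(k + 6)], 0.8), tolerance = 1e-10)
})

test_that("an i.i.d. buffer scores well below a buffer containing a 5-sigma step", {
  set.seed(36)
  iid <- replicate(500, as.numeric(mbcd_fom(rnorm(8), lambda = 1)))
  stepped <- replicate(500, {
    as.numeric(mbcd_fom(c(rnorm(4), rnorm(4, mean = 5)), lambda = 1))
  })
  expect_lt(quantile(iid, 0.95), median(stepped))
  # MBGTD separates the same way
  iid_g <- replicate(200, as.numeric(mbgtd_fom(rnorm(8))))
  step_g <- replicate(200,
    as.numeric(mbgtd_fom(c(rnorm(4), rnorm(4, mean = 5)))))
  expect_lt(quantile(iid_g, 0.95), median(step_g))
})

test_that("classic CUSUM accumulates log-likelihood ratios and alarms on changes", {
  p <- function(x) dnorm(x)
  res <- cusum_classic(rnorm(50), p, p, h = 1)
  expect_equal(res$g, rep(0, 50))
  expect_true(is.na(res$alarm))
  # single sample with likelihood ratio e
  r1 <- cusum_classic(0, function(x) rep(1, length(x)),
                      function(x) rep(exp(1), length(x)), h = 0.5)
  expect_equal(r1$g, 1)
  expect_equal(r1$alarm, 1L)
  expect_true(all(r1$g >= 0))
  expect_error(cusum_classic(c(-1, 50), function(x) dnorm(x),
                             function(x) dnorm(x, 3), h = 1), "positive")
})

test_that("CUSUM alarms promptly after a simulated mean shift", {
  set.seed(37)
  hits <- 0L
  for (rep in 1:200) {
    x <- c(rnorm(49), rnorm(30, mean = 3))
    res <- cusum_classic(x, function(v) pmax(dnorm(v), 1e-300),
                         function(v) pmax(dnorm(v, mean = 3), 1e-300),
                         h = 8)
    if (!is.na(res$alarm) && res$alarm >= 50 && res$alarm <= 60)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("sliding memory detection localizes a step and sizes its output", {
  x <- c(rep(0.5, 60), rep(8, 60)) + rnorm(120, sd = 0.01)
  out <- sliding_memory_detector(x, 10, "mbgtd", gamma = 1)
  expect_length(out$fom$values, 111)
  expect_length(out$marker, 120)
  # the straddling buffers carry the maximum statistic
  expect_true(abs(which.max(out$fom$values) - 56) <= 5)
  # static noiseless series stays quiet
  quiet <- sliding_memory_detector(rep(1, 50), 6, "mbgtd", gamma = 0.5)
  expect_equal(quiet$marker, rep(0L, 50))
})
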