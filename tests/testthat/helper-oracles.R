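# Independent brute-force oracles: naive double/triple loops written
# directly from the defining formulas, no shared code with the package
# implementations they check.

oracle_amvd <- function(accel, window) {
  t_n <- nrow(accel)
  vapply(seq_len(t_n - window + 1L), function(i) {
    fr <- accel[i:(i + window - 1L), , drop = FALSE]
    ctr <- colMeans(fr)
    acc <- 0
    for (k in seq_len(window)) acc <- acc + sum((fr[k, ] - ctr)^2)
    acc / window
  }, numeric(1))
}

oracle_amd <- function(accel, window, sigma_a2) {
  t_n <- nrow(accel)
  vapply(seq_len(t_n - window + 1L), function(i) {
    acc <- 0
    for (k in i:(i + window - 1L))
      acc <- acc + (sqrt(sum(accel[k, ]^2)) - 1)^2
    acc / (sigma_a2 * window)
  }, numeric(1))
}

oracle_ared <- function(gyro, window, sigma_w2) {
  t_n <- nrow(gyro)
  vapply(seq_len(t_n - window + 1L), function(i) {
    acc <- 0
    for (k in i:(i + window - 1L)) acc <- acc + sum(gyro[k, ]^2)
    acc / (sigma_w2 * window)
  }, numeric(1))
}

oracle_shod <- function(accel, gyro, window, sigma_a2, sigma_w2) {
  t_n <- nrow(accel)
  vapply(seq_len(t_n - window + 1L), function(i) {
    fr <- accel[i:(i + window - 1L), , drop = FALSE]
    gr <- gyro[i:(i + window - 1L), , drop = FALSE]
    ctr <- colMeans(fr)
    nrm <- sqrt(sum(ctr^2))
    acc <- 0
    for (k in seq_len(window)) {
      dev <- if (nrm == 0) sum(fr[k, ]^2)
             else sum((fr[k, ] - ctr / nrm)^2)
      acc <- acc + dev / sigma_a2 + sum(gr[k, ]^2) / sigma_w2
    }
    acc / window
  }, numeric(1))
}

# O(N^2) DFT magnitude of one zero-padded frame
oracle_dft_mag <- function(frame, nfft) {
  x <- c(frame, rep(0, nfft - length(frame)))
  vapply(0:(nfft - 1L), function(l) {
    Mod(sum(x * exp(-2i * pi * l * (0:(nfft - 1L)) / nfft)))
  }, numeric(1))
}

# MBGTD: direct enumeration of all (i, j) splits with explicit double sums
oracle_mbgtd <- function(x) {
  n <- length(x)
  best <- -Inf
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    acc <- 0
    for (k in i:(j - 1L)) for (l in j:n) acc <- acc + abs(x[k] - x[l])
    best <- max(best, acc / ((j - i) * (n - j + 1L)))
  }
  best
}

# MBCD: direct evaluation of the split log-likelihood ratio
oracle_mbcd <- function(x, lambda) {
  n <- length(x)
  w <- function(a, b) exp(-0.5 * ((a - b) / lambda)^2)
  best <- -Inf
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    s <- 0
    for (l in j:n) {
      post <- mean(vapply(j:n, function(k) w(x[l], x[k]), numeric(1)))
      pre <- mean(vapply(i:(j - 1L), function(k) w(x[l], x[k]), numeric(1)))
      s <- s + log(max(post, 1e-300) / max(pre, 1e-300))
    }
    best <- max(best, s)
  }
  best
}

# AUC via the Mann-Whitney U statistic (rank formulation, ties averaged)
oracle_mw_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# accuracy/phi at thresholds by direct per-sample comparison
oracle_threshold_metrics <- function(score, truth, gammas) {
  t(vapply(gammas, function(g) {
    est <- as.integer(score >= g)
    tp <- sum(est == 1 & truth == 1); tn <- sum(est == 0 & truth == 0)
    fp <- sum(est == 1 & truth == 0); fn <- sum(est == 0 & truth == 1)
    acc <- (tp + tn) / length(truth)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    phi <- if (length(unique(est)) == 1L) {
      if (all(est == truth)) 1 else 0
    } else if (den > 0) (tp * tn - fp * fn) / den else 0
    c(accuracy = acc, correlation = phi)
  }, numeric(2)))
}

# small deterministic fixtures ------------------------------------------------

static_recording <- function(t_n = 200, fs = 50) {
  imu_recording(matrix(rep(c(0, 0, 1), each = t_n), t_n, 3),
                matrix(0, t_n, 3), fs = fs,
                truth_marker = rep(0L, t_n))
}

# static recording with one noiseless constant-rate gyro burst
burst_recording <- function(t_n = 300, from = 120, to = 200, rate = 40,
                            fs = 50) {
  gyro <- matrix(0, t_n, 3)
  gyro[from:to, 1] <- rate
  truth <- integer(t_n)
  truth[from:to] <- 1L
  imu_recording(matrix(rep(c(0, 0, 1), each = t_n), t_n, 3), gyro,
                fs = fs, truth_marker = truth)
}
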