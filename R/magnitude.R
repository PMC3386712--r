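# Time-domain magnitude detectors. All four framed statistics slide sample
# by sample (shift 1): their per-frame cost is O(1) via cumulative sums, and
# dense sliding gives maximal temporal resolution.

# running sum of v over windows of length w; returns length(v) - w + 1 values
running_sum <- function(v, w) {
  cs <- cumsum(v)
  n <- length(v)
  cs[seq.int(w, n)] - c(0, cs)[seq.int(w, n) - w + 1L]
}

#' Acceleration moving variance detector (AMVD) figure of merit
#'
#' Per frame of N samples, the mean squared deviation of the acceleration
#' vector from the frame's vector mean:
#' \deqn{V(n) = \frac{1}{N} \sum_{k} \lVert a_k - \bar a_n \rVert^2.}
#' Sensitive to any fluctuation of the acceleration, but blind to constant
#' signals (including a rotated but steady gravity vector).
#'
#' @param accel T x 3 acceleration matrix in g.
#' @param window frame length N in samples (>= 2).
#' @return An [imu_fom()] with one value per frame, shift 1.
#' @export
amvd_fom <- function(accel, window) {
  accel <- as.matrix(accel)
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 for a variance")
  n <- nrow(accel)
  starts <- frame_start_grid(n, window, 1L)
  s2 <- running_sum(rowSums(accel * accel), window)
  mx <- running_sum(accel[, 1L], window) / window
  my <- running_sum(accel[, 2L], window) / window
  mz <- running_sum(accel[, 3L], window) / window
  v <- s2 / window - (mx * mx + my * my + mz * mz)
  imu_fom(pmax(v, 0), starts, window, 1L)  # clamp fp round-off
}

#' Acceleration magnitude detector (AMD) figure of merit
#'
#' Per frame, the mean squared deviation of the acceleration magnitude from
#' gravity, scaled by the acceleration noise variance:
#' \deqn{V(n) = \frac{1}{\sigma_a^2 N} \sum_k (\lVert a_k \rVert - g)^2,}
#' with g = 1 in g-units. Misses movements with no specific force (pure
#' rotations).
#'
#' @inheritParams amvd_fom
#' @param sigma_a2 acceleration noise variance in g^2 (> 0).
#' @return An [imu_fom()], shift 1.
#' @export
amd_fom <- function(accel, window, sigma_a2) {
  accel <- as.matrix(accel)
  window <- as.integer(window)
  if (sigma_a2 <= 0) stop("sigma_a2 must be positive")
  n <- nrow(accel)
  starts <- frame_start_grid(n, window, 1L)
  r <- (row_norms(accel) - 1)^2
  imu_fom(running_sum(r, window) / (sigma_a2 * window), starts, window, 1L)
}

#' Angular rate energy detector (ARED) figure of merit
#'
#' Per frame, the mean squared magnitude of the angular-rate vector scaled
#' by the gyroscope noise variance:
#' \deqn{V(n) = \frac{1}{\sigma_\omega^2 N} \sum_k \lVert \omega_k \rVert^2.}
#' Misses movements with no rotation (pure translations).
#'
#' @param gyro T x 3 angular-rate matrix in deg/s.
#' @param window frame length N in samples.
#' @param sigma_w2 angular-rate noise variance in (deg/s)^2 (> 0).
#' @return An [imu_fom()], shift 1.
#' @export
ared_fom <- function(gyro, window, sigma_w2) {
  gyro <- as.matrix(gyro)
  window <- as.integer(window)
  if (sigma_w2 <= 0) stop("sigma_w2 must be positive")
  n <- nrow(gyro)
  starts <- frame_start_grid(n, window, 1L)
  imu_fom(running_sum(rowSums(gyro * gyro), window) / (sigma_w2 * window),
          starts, window, 1L)
}

#' Stance hypothesis optimal detector (SHOD) figure of merit
#'
#' Combines both sensors. Per frame, gravity is assumed to point along the
#' frame-mean specific-force direction \eqn{u_n = \bar a_n / \lVert \bar a_n
#' \rVert} and the statistic is
#' \deqn{V(n) = \frac{1}{N} \sum_k \left( \frac{1}{\sigma_a^2}
#'   \lVert a_k - g\, u_n \rVert^2 + \frac{1}{\sigma_\omega^2}
#'   \lVert \omega_k \rVert^2 \right).}
#' When a frame's mean acceleration is exactly zero the gravity direction is
#' undefined and the acceleration term degenerates to \eqn{\lVert a_k
#' \rVert^2} for that frame.
#'
#' @inheritParams amd_fom
#' @param gyro T x 3 angular-rate matrix in deg/s.
#' @param sigma_w2 angular-rate noise variance in (deg/s)^2 (> 0).
#' @return An [imu_fom()], shift 1.
#' @export
shod_fom <- function(accel, gyro, window, sigma_a2, sigma_w2) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  window <- as.integer(window)
  if (sigma_a2 <= 0 || sigma_w2 <= 0) stop("noise variances must be positive")
  if (nrow(accel) != nrow(gyro)) stop("accel and gyro lengths differ")
  n <- nrow(accel)
  starts <- frame_start_grid(n, window, 1L)
  sa2 <- running_sum(rowSums(accel * accel), window)
  sx <- running_sum(accel[, 1L], window)
  sy <- running_sum(accel[, 2L], window)
  sz <- running_sum(accel[, 3L], window)
  ssum <- sqrt(sx * sx + sy * sy + sz * sz)  # ||sum_k a_k||
  # sum_k ||a_k - g u_n||^2 = sum ||a_k||^2 - 2 g u_n . sum a_k + N g^2,
  # and u_n is parallel to sum a_k, so u_n . sum a_k = ||sum a_k||.
  acc_term <- sa2 - 2 * ssum + window
  degenerate <- ssum == 0
  if (any(degenerate)) acc_term[degenerate] <- sa2[degenerate]
  sw2 <- running_sum(rowSums(gyro * gyro), window)
  imu_fom(pmax(acc_term, 0) / (sigma_a2 * window) + sw2 / (sigma_w2 * window),
          starts, window, 1L)
}

#' Filtered rectifier detector (FRD) figure of merit
#'
#' The input series is high-pass filtered (removing gravity / slow drift),
#' rectified, and low-pass filtered into a smooth activity envelope; the
#' envelope itself is the per-sample figure of merit. Both filters are
#' Butterworth. Causal application (the default) reproduces the latency this
#' detector shows in practice: the envelope lags activity onsets and decays
#' after offsets. Zero-phase (forward-backward) application is available
#' for offline use.
#'
#' @param x scalar input series (any [input_combination()] mode).
#' @param fs sampling rate in Hz.
#' @param hpf_cutoff,lpf_cutoff cutoffs in Hz of the two cascaded filters;
#'   each must lie in (0, fs/2).
#' @param order Butterworth order of both filters (1-8).
#' @param zero_phase apply each filter forward-backward.
#' @return An [imu_fom()] with one value per sample (window 1, shift 1).
#' @export
frd_fom <- function(x, fs, hpf_cutoff = 0.3, lpf_cutoff = 0.5, order = 2L,
                    zero_phase = FALSE) {
  x <- as.numeric(x)
  if (hpf_cutoff <= 0 || hpf_cutoff >= fs / 2 ||
      lpf_cutoff <= 0 || lpf_cutoff >= fs / 2)
    stop("filter cutoffs must lie in (0, fs/2)")
  if (order < 1L || order > 8L) stop("filter order must be in [1, 8]")
  apply_filt <- function(flt, v) {
    if (zero_phase) signal::filtfilt(flt, v)
    else as.numeric(signal::filter(flt, v))
  }
  hp <- signal::butter(order, hpf_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(order, lpf_cutoff / (fs / 2), type = "low")
  v <- apply_filt(lp, abs(apply_filt(hp, x)))
  imu_fom(v, seq_along(v), 1L, 1L)
}
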