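#' Inertial recording container
#'
#' Bundles synchronized triaxial accelerometer and gyroscope series with the
#' sampling rate and an optional ground-truth activity marker. Accelerations
#' are expressed in g (gravity = 1 exactly), angular rates in deg/s; these
#' units match MEMS datasheet full-scale ranges and keep the gravity
#' subtraction of the acceleration-magnitude detector dimensionless.
#'
#' @param accel numeric matrix, T x 3, acceleration in g.
#' @param gyro numeric matrix, T x 3, angular rate in deg/s.
#' @param fs sampling rate in Hz (> 0).
#' @param truth_marker optional length-T vector with values in \{0, 1\}
#'   (1 = active, 0 = static).
#' @return An object of class `imu_recording`: a list with elements
#'   `accel`, `gyro`, `fs`, `truth_marker` (possibly `NULL`).
#' @examples
#' rec <- imu_recording(matrix(c(0, 0, 1), 10, 3, byrow = TRUE),
#'                      matrix(0, 10, 3), fs = 50)
#' n_samples(rec)
#' @export
imu_recording <- function(accel, gyro, fs, truth_marker = NULL) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must have 3 columns (x, y, z)")
  if (nrow(accel) != nrow(gyro))
    stop("accel and gyro must have the same number of samples")
  if (nrow(accel) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (!is.null(truth_marker)) {
    truth_marker <- as.integer(truth_marker)
    if (length(truth_marker) != nrow(accel))
      stop("truth_marker length must equal the number of samples")
    if (!all(truth_marker %in% c(0L, 1L)))
      stop("truth_marker values must be 0 or 1")
  }
  structure(
    list(accel = unname(accel), gyro = unname(gyro), fs = as.numeric(fs),
         truth_marker = truth_marker),
    class = "imu_recording"
  )
}

#' Number of samples in a recording
#' @param rec an [imu_recording()].
#' @return Integer sample count T.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  nrow(rec$accel)
}

#' @export
print.imu_recording <- function(x, ...) {
  t_sec <- n_samples(x) / x$fs
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s)%s\n",
              n_samples(x), x$fs, t_sec,
              if (is.null(x$truth_marker)) "" else
                sprintf(", truth marker (%.0f%% active)",
                        100 * mean(x$truth_marker))))
  invisible(x)
}

#' Euclidean norm per sample of a 3-column matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m * m))

#' Combine accelerometer and gyroscope magnitudes into one scalar series
#'
#' The flexible-input detectors (FRD, FSD, LTSD, MBGTD, MBCD) operate on a
#' scalar series derived from the two sensor magnitudes. Four combinations
#' are supported: the acceleration magnitude, the angular-rate magnitude,
#' and their sum and product. Units are mixed for `sum`/`prod`; no rescaling
#' is applied, the detector threshold absorbs the scale.
#'
#' @param rec an [imu_recording()].
#' @param mode one of `"acc"`, `"ang"`, `"sum"`, `"prod"`.
#' @return Numeric vector of length T.
#' @examples
#' rec <- imu_recording(matrix(c(3, 4, 0), 1, 3), matrix(c(0, 2, 0), 1, 3), 50)
#' input_combination(rec, "acc")   # 5
#' input_combination(rec, "prod")  # 5 * 2 = 10
#' @export
input_combination <- function(rec, mode = c("acc", "ang", "sum", "prod")) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length(mode) != 1L || !mode %in% c("acc", "ang", "sum", "prod"))
    stop("unknown input combination mode: ",
         paste(setdiff(mode, c("acc", "ang", "sum", "prod")), collapse = ", "))
  a <- row_norms(rec$accel)
  w <- row_norms(rec$gyro)
  switch(mode, acc = a, ang = w, sum = a + w, prod = a * w)
}
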