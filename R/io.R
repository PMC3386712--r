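# Plain-text I/O. One CSV dialect throughout: header
# t,ax,ay,az,gx,gy,gz[,marker], comma separated, decimal point.

#' Read an inertial recording from CSV
#'
#' Expects columns `t` (seconds), `ax,ay,az` (g), `gx,gy,gz` (deg/s) and an
#' optional binary `marker` column which becomes the ground-truth marker.
#' The sampling rate is inferred from the median time step unless given.
#'
#' @param path CSV file path.
#' @param fs optional sampling rate override in Hz.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("time column must be strictly increasing in ", path)
  if (is.null(fs)) {
    if (nrow(df) < 2L)
      stop("cannot infer fs from a single sample; pass fs explicitly")
    fs <- 1 / stats::median(diff(df$t))
  }
  marker <- NULL
  if ("marker" %in% names(df)) {
    bad <- which(!df$marker %in% c(0, 1))
    if (length(bad))
      stop(sprintf("non-binary marker value at data line %d of %s",
                   bad[1L], path))
    marker <- as.integer(df$marker)
  }
  imu_recording(as.matrix(df[, c("ax", "ay", "az")]),
                as.matrix(df[, c("gx", "gy", "gz")]),
                fs = fs, truth_marker = marker)
}

#' Write an inertial recording to CSV
#'
#' @param rec an [imu_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- n_samples(rec)
  df <- data.frame(t = (seq_len(n) - 1L) / rec$fs,
                   ax = rec$accel[, 1L], ay = rec$accel[, 2L],
                   az = rec$accel[, 3L],
                   gx = rec$gyro[, 1L], gy = rec$gyro[, 2L],
                   gz = rec$gyro[, 3L])
  if (!is.null(rec$truth_marker)) df$marker <- rec$truth_marker
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a binary activity marker to CSV (`t,marker`)
#'
#' @param marker binary vector.
#' @param fs sampling rate in Hz.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(marker, fs, path) {
  utils::write.csv(
    data.frame(t = (seq_along(marker) - 1L) / fs,
               marker = as.integer(marker)),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a figure of merit to CSV (`frame_start,V`)
#'
#' @param fom an [imu_fom()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fom_csv <- function(fom, path) {
  stopifnot(inherits(fom, "imu_fom"))
  utils::write.csv(data.frame(frame_start = fom$frame_starts,
                              V = fom$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a flat YAML experiment configuration
#'
#' Recognized keys (all optional unless a step needs them): `seed`,
#' `n_runs`, `n_activities`, `detectors` (list of method specs such as
#' `shod` or `fsd-prod`), `fs`, `noise_sigma_a`, `noise_sigma_w`,
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$detectors)) {
    known <- vapply(cfg$detectors,
                    function(d) strsplit(tolower(d), "-")[[1L]][1L], "")
    bad <- setdiff(known, DETECTOR_IDS)
    if (length(bad)) stop("unknown detector id(s): ",
                          paste(bad, collapse = ", "))
  }
  cfg
}
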