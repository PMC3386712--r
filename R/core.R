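#' Figure-of-merit container
#'
#' Holds the detector statistic `V(n)` per decision instant together with
#' the sample index (1-based) at which each frame starts and the window /
#' shift used, so decisions can be mapped back onto samples.
#'
#' @param values numeric vector of detector statistics, one per frame.
#' @param frame_starts integer vector, 1-based start sample of each frame;
#'   strictly increasing, same length as `values`.
#' @param window frame length in samples.
#' @param shift frame advance in samples.
#' @return An object of class `imu_fom`.
#' @export
imu_fom <- function(values, frame_starts, window, shift) {
  values <- as.numeric(values)
  frame_starts <- as.integer(frame_starts)
  if (length(values) == 0L) stop("figure of merit must be nonempty")
  if (length(frame_starts) != length(values))
    stop("frame_starts and values must have equal length")
  if (length(frame_starts) > 1L && any(diff(frame_starts) <= 0L))
    stop("frame_starts must be strictly increasing")
  structure(list(values = values, frame_starts = frame_starts,
                 window = as.integer(window), shift = as.integer(shift)),
            class = "imu_fom")
}

#' @export
print.imu_fom <- function(x, ...) {
  cat(sprintf("<imu_fom> %d frames (window %d, shift %d), V in [%.4g, %.4g]\n",
              length(x$values), x$window, x$shift,
              min(x$values), max(x$values)))
  invisible(x)
}

frame_start_grid <- function(n, window, shift) {
  if (n < window) stop("recording shorter than the analysis window")
  seq.int(1L, n - window + 1L, by = shift)
}

#' Per-sample decision scores from a framed figure of merit
#'
#' Broadcasts each frame's statistic to the samples that frame is
#' responsible for: a frame owns the `shift` samples beginning at its start
#' index; samples before the first frame start take the first value and
#' samples after the last owned sample inherit the last value. This mapping
#' is causal and gap-free, and makes per-sample thresholding equivalent to
#' thresholding the returned score vector.
#'
#' @param fom an [imu_fom()].
#' @param n total number of samples T (must cover the last frame start).
#' @return Numeric vector of length `n`.
#' @export
fom_sample_scores <- function(fom, n) {
  stopifnot(inherits(fom, "imu_fom"))
  n <- as.integer(n)
  m <- length(fom$values)
  if (n < fom$frame_starts[m])
    stop("n is smaller than the last frame start")
  owner <- findInterval(seq_len(n), fom$frame_starts)
  owner[owner < 1L] <- 1L  # samples before the first frame start
  fom$values[owner]
}

#' Threshold a figure of merit into a binary activity marker
#'
#' A decision instant with statistic greater than or equal to the threshold
#' is marked active (1); strictly below, static (0). Frame decisions are
#' broadcast to samples via [fom_sample_scores()].
#'
#' @param fom an [imu_fom()].
#' @param gamma decision threshold, in the units of the figure of merit.
#' @param n total number of samples T of the output marker.
#' @return Integer vector of length `n` with values in \{0, 1\}.
#' @examples
#' f <- imu_fom(c(0.1, 0.9, 0.1), 1:3, window = 1, shift = 1)
#' threshold_marker(f, 0.5, 3)  # 0 1 0
#' @export
threshold_marker <- function(fom, gamma, n) {
  as.integer(fom_sample_scores(fom, n) >= gamma)
}

#' Noise profile of a recording
#'
#' The acceleration-magnitude, angular-rate-energy and stance-hypothesis
#' detectors scale their statistics by the noise variances of the two
#' sensors. These are treated as known scaling factors; when not supplied
#' they are estimated as the sample variance of the magnitude residual
#' (\eqn{\lVert a \rVert - 1} g for the accelerometer, \eqn{\lVert \omega
#' \rVert} for the gyroscope) over an initial stretch of the recording that
#' is assumed static.
#'
#' @param rec an [imu_recording()].
#' @param seconds length of the initial stretch used for estimation.
#' @return A list of class `noise_profile` with `sigma_a2` (g^2) and
#'   `sigma_w2` ((deg/s)^2), both floored at 1e-10.
#' @export
estimate_noise_profile <- function(rec, seconds = 1) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- max(2L, min(n_samples(rec), as.integer(round(seconds * rec$fs))))
  idx <- seq_len(n)
  ra <- row_norms(rec$accel[idx, , drop = FALSE]) - 1
  rw <- row_norms(rec$gyro[idx, , drop = FALSE])
  noise_profile(max(stats::var(ra), 1e-10), max(stats::var(rw), 1e-10))
}

#' @rdname estimate_noise_profile
#' @param sigma_a2 acceleration noise variance in g^2 (> 0).
#' @param sigma_w2 angular-rate noise variance in (deg/s)^2 (> 0).
#' @export
noise_profile <- function(sigma_a2, sigma_w2) {
  if (sigma_a2 <= 0 || sigma_w2 <= 0)
    stop("noise variances must be positive")
  structure(list(sigma_a2 = sigma_a2, sigma_w2 = sigma_w2),
            class = "noise_profile")
}

#' Detector configuration
#'
#' Collects every tunable parameter of the nine detectors in one place.
#' Parameters not used by a given detector are ignored by [run_detector()]
#' (with a warning when a non-default value would be dropped).
#'
#' @param window frame length N in samples.
#' @param threshold decision threshold gamma, in the units of the detector's
#'   figure of merit.
#' @param shift frame advance in samples (spectral detectors; the dense
#'   detectors always use 1).
#' @param nfft FFT resolution for the spectral detectors.
#' @param envelope_order long-term spectral envelope order J (LTSD): the
#'   envelope is the per-band maximum over frames n-J .. n+J.
#' @param hpf_cutoff,lpf_cutoff FRD high-pass / low-pass cutoffs in Hz.
#'   They belong to two separate cascaded filters; each must lie in
#'   (0, fs/2) but they need not be ordered.
#' @param filter_order FRD Butterworth order (1-8).
#' @param zero_phase if `TRUE` the FRD filters are applied forward-backward
#'   (no latency); the default `FALSE` is causal, which is what a real-time
#'   detector would use and what produces the characteristic onset/offset
#'   shifts of this detector.
#' @param parzen_lambda Parzen kernel standard deviation for MBCD; `NULL`
#'   selects Silverman's rule per buffer.
#' @param input_mode input combination for the flexible-input detectors,
#'   see [input_combination()].
#' @param noise_frames number of leading frames used to estimate the noise
#'   spectrum of the spectral detectors.
#' @param window_fn frame taper for the spectral detectors.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(window = 10L, threshold = 1, shift = 1L,
                            nfft = 512L, envelope_order = 1L,
                            hpf_cutoff = 0.3, lpf_cutoff = 0.5,
                            filter_order = 2L, zero_phase = FALSE,
                            parzen_lambda = NULL,
                            input_mode = "acc", noise_frames = 10L,
                            window_fn = c("rectangular", "hann")) {
  window <- as.integer(window); shift <- as.integer(shift)
  if (window < 1L) stop("window must be >= 1")
  if (shift < 1L || shift > window) stop("shift must lie in [1, window]")
  if (nfft < window) stop("nfft must be >= window")
  if (envelope_order < 0L) stop("envelope_order must be >= 0")
  if (!is.null(parzen_lambda) && parzen_lambda <= 0)
    stop("parzen_lambda must be positive")
  structure(list(window = window, threshold = threshold, shift = shift,
                 nfft = as.integer(nfft),
                 envelope_order = as.integer(envelope_order),
                 hpf_cutoff = hpf_cutoff, lpf_cutoff = lpf_cutoff,
                 filter_order = as.integer(filter_order),
                 zero_phase = zero_phase, parzen_lambda = parzen_lambda,
                 input_mode = match.arg(input_mode,
                                        c("acc", "ang", "sum", "prod")),
                 noise_frames = as.integer(noise_frames),
                 window_fn = match.arg(window_fn)),
            class = "detector_config")
}

DETECTOR_IDS <- c("amvd", "amd", "ared", "shod", "frd",
                  "fsd", "ltsd", "mbgtd", "mbcd")

#' Run a detector on a recording
#'
#' Common front end for the nine detectors: computes the figure of merit
#' with a sliding window over the input signal, then thresholds it into a
#' per-sample binary activity marker. Deterministic given its inputs.
#'
#' @param rec an [imu_recording()].
#' @param method detector id, one of `"amvd"`, `"amd"`, `"ared"`, `"shod"`,
#'   `"frd"`, `"fsd"`, `"ltsd"`, `"mbgtd"`, `"mbcd"` (case-insensitive).
#' @param cfg a [detector_config()].
#' @param noise a `noise_profile`; estimated from the first second of the
#'   recording when `NULL` (magnitude detectors only).
#' @return A list of class `imu_detection` with elements `fom`
#'   ([imu_fom()]), `marker` (integer vector of length T) and `method`.
#' @examples
#' rec <- synth_imu(n_activities = 2, seed = 1)
#' det <- run_detector(rec, "shod", detector_config(window = 10, threshold = 5))
#' mean(det$marker == rec$truth_marker)
#' @export
run_detector <- function(rec, method, cfg = detector_config(), noise = NULL) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cfg, "detector_config"))
  method <- match.arg(tolower(method), DETECTOR_IDS)
  n <- n_samples(rec)
  if (method != "frd" && n < cfg$window)
    stop("recording shorter than the analysis window")
  dense <- method %in% c("amvd", "amd", "ared", "shod", "mbgtd", "mbcd")
  if (dense && cfg$shift != 1L) {
    warning(sprintf("'%s' slides sample by sample; shift = %d ignored",
                    method, cfg$shift))
    cfg$shift <- 1L
  }
  if (is.null(noise) && method %in% c("amd", "ared", "shod"))
    noise <- estimate_noise_profile(rec)
  fom <- switch(
    method,
    amvd = amvd_fom(rec$accel, cfg$window),
    amd = amd_fom(rec$accel, cfg$window, noise$sigma_a2),
    ared = ared_fom(rec$gyro, cfg$window, noise$sigma_w2),
    shod = shod_fom(rec$accel, rec$gyro, cfg$window,
                    noise$sigma_a2, noise$sigma_w2),
    frd = frd_fom(input_combination(rec, cfg$input_mode), rec$fs,
                  hpf_cutoff = cfg$hpf_cutoff, lpf_cutoff = cfg$lpf_cutoff,
                  order = cfg$filter_order, zero_phase = cfg$zero_phase),
    fsd = ,
    ltsd = {
      x <- input_combination(rec, cfg$input_mode)
      sf <- framed_spectrum(x, cfg$window, cfg$shift, cfg$nfft, cfg$window_fn)
      ns <- estimate_noise_spectrum(sf, cfg$noise_frames)
      if (method == "fsd") fsd_fom(sf, ns)
      else ltsd_fom(ltse(sf, cfg$envelope_order), ns)
    },
    mbgtd = ,
    mbcd = {
      x <- input_combination(rec, cfg$input_mode)
      sliding_memory_detector(x, cfg$window, method, cfg$threshold,
                              lambda = cfg$parzen_lambda)$fom
    })
  structure(list(fom = fom, marker = threshold_marker(fom, cfg$threshold, n),
                 method = method, config = cfg),
            class = "imu_detection")
}

#' @export
print.imu_detection <- function(x, ...) {
  cat(sprintf("<imu_detection> %s: %d frames, %.1f%% of samples active\n",
              toupper(x$method), length(x$fom$values), 100 * mean(x$marker)))
  invisible(x)
}
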