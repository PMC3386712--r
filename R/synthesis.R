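# Synthesizer of accelerometer-like and gyroscope-like signals for seven
# basic activity kinds, with exact ground-truth markers. Activities carry
# distinct amplitude/frequency signatures; every non-static kind (including
# the two degenerate kinds) is marked active. Static instants have
# acceleration magnitude exactly 1 g before noise.

ACTIVITY_KINDS <- c("walking", "sit_stand", "lay_stand", "running",
                    "jumping", "no_accel_const_gyro", "no_gyro_const_accel")

# Draw weights of the activity repertoire, mirroring the composition of a
# typical stop-and-go exercise circuit (walking dominates, postural
# transitions are common, the two degenerate single-sensor kinds are
# occasional robustness probes).
ACTIVITY_WEIGHTS <- c(walking = 3, sit_stand = 1, lay_stand = 2,
                      running = 1, jumping = 1, no_accel_const_gyro = 1,
                      no_gyro_const_accel = 1)

#' Synthesizer configuration
#'
#' Study conditions for the signal synthesizer. Defaults: 50 Hz sampling,
#' white Gaussian noise of 0.02 g / 1 deg/s per axis, hard saturation at
#' +/- 3 g and +/- 500 deg/s (typical MEMS full-scale ranges), gravity on
#' the z axis, and per-kind intensity ranges consistent with ordinary human
#' gait: walking 1.4-2.5 Hz at 0.3-0.8 g, running 2.5-3.5 Hz at 0.8-2 g,
#' jumping 1.5-2.5 Hz impulse trains at 1.5-3 g, postural transitions lasting
#' 1.5-3 s, gyroscope envelopes 30-300 deg/s. Activity segments last 2-6 s
#' and static segments 2-5 s, all drawn uniformly.
#'
#' @param fs sampling rate in Hz.
#' @param noise_sigma_a,noise_sigma_w per-axis white-noise standard
#'   deviations, in g and deg/s (>= 0).
#' @param accel_range,gyro_range clip limits (+/-), in g and deg/s.
#' @param gravity_axis axis the gravity vector lies on between transitions.
#' @param static_duration,activity_duration  min/max segment durations (s).
#' @param intensity_ranges named list of per-kind sampling intervals; each
#'   entry may override `amp_a` (g), `amp_w` (deg/s), `freq` (Hz),
#'   `duration` (s). Partial overrides merge over the defaults.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 50, noise_sigma_a = 0.02, noise_sigma_w = 1,
                         accel_range = 3, gyro_range = 500,
                         gravity_axis = c("z", "x", "y"),
                         static_duration = c(2, 5),
                         activity_duration = c(2, 6),
                         intensity_ranges = list()) {
  if (fs <= 0) stop("fs must be positive")
  if (noise_sigma_a < 0 || noise_sigma_w < 0)
    stop("noise sigmas must be >= 0")
  defaults <- list(
    walking = list(amp_a = c(0.3, 0.8), amp_w = c(30, 300),
                   freq = c(1.4, 2.5)),
    running = list(amp_a = c(0.8, 2.0), amp_w = c(30, 300),
                   freq = c(2.5, 3.5)),
    jumping = list(amp_a = c(1.5, 3.0), amp_w = c(30, 300),
                   freq = c(1.5, 2.5)),
    sit_stand = list(amp_a = c(0.3, 1.0), amp_w = c(30, 300),
                     freq = c(0, 0), duration = c(1.5, 3)),
    lay_stand = list(amp_a = c(0.3, 1.0), amp_w = c(30, 300),
                     freq = c(0, 0), duration = c(1.5, 3)),
    no_accel_const_gyro = list(amp_a = c(0, 0), amp_w = c(30, 300),
                               freq = c(0, 0), duration = c(1, 3)),
    no_gyro_const_accel = list(amp_a = c(0.3, 1.0), amp_w = c(0, 0),
                               freq = c(0, 0), duration = c(1, 3))
  )
  for (kind in names(intensity_ranges)) {
    if (!kind %in% ACTIVITY_KINDS) stop("unknown activity kind: ", kind)
    defaults[[kind]] <- utils::modifyList(defaults[[kind]],
                                          intensity_ranges[[kind]])
  }
  structure(list(fs = fs, noise_sigma_a = noise_sigma_a,
                 noise_sigma_w = noise_sigma_w, accel_range = accel_range,
                 gyro_range = gyro_range,
                 gravity_axis = match.arg(gravity_axis),
                 static_duration = static_duration,
                 activity_duration = activity_duration,
                 intensity_ranges = defaults),
            class = "synth_config")
}

#' Activity segment specification
#'
#' One homogeneous stretch of signal: its kind, duration, envelope
#' amplitudes, fundamental frequency and gravity axis. Kinds other than
#' `"static"` are marked active, including the two degenerate kinds
#' (constant angular rate with no specific acceleration, and constant
#' acceleration with no angular rate), which exist to probe detectors that
#' rely on a single sensor.
#'
#' @param kind `"static"` or one of the seven activity kinds.
#' @param duration_s segment duration in seconds (> 0).
#' @param amp_a acceleration envelope amplitude in g (>= 0).
#' @param amp_w angular-rate envelope amplitude in deg/s (>= 0).
#' @param freq_hz fundamental frequency in Hz (>= 0).
#' @param gravity_axis `"x"`, `"y"` or `"z"`.
#' @return A list of class `activity_segment`.
#' @export
activity_segment <- function(kind, duration_s, amp_a = 0, amp_w = 0,
                             freq_hz = 0, gravity_axis = "z") {
  if (!kind %in% c("static", ACTIVITY_KINDS))
    stop("unknown activity kind: ", kind)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (amp_a < 0 || amp_w < 0 || freq_hz < 0)
    stop("amplitudes and frequency must be >= 0")
  structure(list(kind = kind, duration_s = duration_s, amp_a = amp_a,
                 amp_w = amp_w, freq_hz = freq_hz,
                 gravity_axis = match.arg(gravity_axis, c("x", "y", "z"))),
            class = "activity_segment")
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

# raised-cosine on/off ramp applied to oscillatory activity envelopes;
# humans do not start or stop instantaneously. Ramp is capped at 0.15 s or
# a quarter of the segment.
edge_ramp <- function(t_len, fs) {
  ramp_n <- min(as.integer(round(0.15 * fs)), t_len %/% 4L)
  env <- rep(1, t_len)
  if (ramp_n >= 1L) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
    env[seq_len(ramp_n)] <- up
    env[t_len + 1L - seq_len(ramp_n)] <- up
  }
  env
}

# smooth unit lobe on [0, 1]: sin^2(pi u)
lobe <- function(u) sin(pi * u)^2

# Gait-like gyroscope oscillation: the angular-velocity vector swings along
# a fixed random spatial direction and reverses each half-cycle (the limb
# stops and turns back), passing near zero at every reversal; a small
# incoherent wobble keeps the reversals from being exact zeros.
gait_gyro <- function(n, tt, env, amp_w, freq_hz) {
  dir <- stats::rnorm(3L)
  dir <- dir / sqrt(sum(dir^2))
  ph <- stats::runif(1L, 0, 2 * pi)
  main <- amp_w * env * sin(2 * pi * freq_hz * tt + ph)
  g <- outer(main, dir)
  ph_j <- stats::runif(3L, 0, 2 * pi)
  for (ax in 1:3)
    g[, ax] <- g[, ax] + 0.05 * amp_w * env *
      sin(2 * pi * 2 * freq_hz * tt + ph_j[ax])
  g
}

#' Synthesize one activity segment
#'
#' Builds the noiseless waveform template of the segment's kind, adds
#' gravity (+1 g) on the gravity axis, then adds white Gaussian noise and
#' applies hard clipping at the configured sensor ranges. Templates:
#' walking/running are band-limited periodic bursts (fundamental plus a
#' half-amplitude second harmonic, random per-axis phases) with a gyroscope
#' oscillation at the same fundamental; postural transitions are one smooth
#' biphasic accelerometer transient with a single gyroscope lobe, and the
#' lay/stand transition additionally rotates the gravity vector to a
#' horizontal axis and back; jumping is a periodic raised-cosine impulse
#' cycle on the vertical axis: a ground-contact impulse (30% of the cycle),
#' a free-fall flight lobe where specific force drops toward zero (40%),
#' then quiet stance, with the gyroscope oscillating throughout.
#'
#' @param spec an [activity_segment()].
#' @param cfg a [synth_config()].
#' @return List with `accel` (n x 3, g), `gyro` (n x 3, deg/s) and `marker`
#'   (length n, 0/1).
#' @export
synthesize_segment <- function(spec, cfg) {
  stopifnot(inherits(spec, "activity_segment"), inherits(cfg, "synth_config"))
  n <- max(1L, as.integer(round(spec$duration_s * cfg$fs)))
  tt <- (seq_len(n) - 1L) / cfg$fs
  g_ax <- axis_index(spec$gravity_axis)
  accel <- matrix(0, n, 3L)
  gyro <- matrix(0, n, 3L)
  gravity <- matrix(0, n, 3L)
  gravity[, g_ax] <- 1

  kind <- spec$kind
  if (kind %in% c("walking", "running")) {
    env <- edge_ramp(n, cfg$fs)
    ph_a <- stats::runif(3L, 0, 2 * pi)
    ph_h <- stats::runif(3L, 0, 2 * pi)
    for (ax in 1:3) {
      accel[, ax] <- spec$amp_a * env *
        (sin(2 * pi * spec$freq_hz * tt + ph_a[ax]) +
           0.5 * sin(4 * pi * spec$freq_hz * tt + ph_h[ax]))
    }
    gyro <- gyro + gait_gyro(n, tt, env, spec$amp_w, spec$freq_hz)
  } else if (kind == "jumping") {
    env <- edge_ramp(n, cfg$fs)
    period <- 1 / max(spec$freq_hz, 1e-6)
    phase <- (tt %% period) / period
    # jump cycle: ground-contact impulse (push-off + landing, 30% of the
    # cycle), then flight where the accelerometer reads free fall (specific
    # force ~ 0, i.e. -1 g against gravity), then quiet stance.
    imp <- ifelse(phase < 0.3, lobe(phase / 0.3), 0)
    flight <- ifelse(phase >= 0.3 & phase < 0.7, lobe((phase - 0.3) / 0.4), 0)
    accel[, g_ax] <- env * (spec$amp_a * imp - flight)
    lat <- setdiff(1:3, g_ax)
    accel[, lat[1L]] <- 0.2 * spec$amp_a * env * imp
    # the body keeps swinging between landings: continuous gyro oscillation
    gyro <- gyro + gait_gyro(n, tt, env, spec$amp_w, spec$freq_hz)
  } else if (kind %in% c("sit_stand", "lay_stand")) {
    u <- (seq_len(n) - 0.5) / n
    # biphasic vertical transient: push off, then decelerate. Acts along
    # the instantaneous gravity direction (the body accelerates vertically),
    # so it modulates the specific-force magnitude directly.
    bi <- ifelse(u < 0.5, lobe(2 * u), -lobe(2 * u - 1))
    rot_ax <- setdiff(1:3, g_ax)[1L]
    if (kind == "lay_stand") {
      # gravity tilts to a horizontal axis and back (lie down, stand up);
      # the gyroscope reads the tilt rate on the remaining axis.
      theta <- (pi / 2) * lobe(u)
      gravity[, g_ax] <- cos(theta)
      gravity[, rot_ax] <- sin(theta)
      spin_ax <- setdiff(1:3, c(g_ax, rot_ax))
      gyro[, spin_ax] <- (180 / pi) * c(diff(theta) * cfg$fs, 0)
    } else {
      gyro[, rot_ax] <- spec$amp_w * lobe(u)
    }
    gravity <- gravity * (1 + spec$amp_a * bi)
  } else if (kind == "no_accel_const_gyro") {
    ax_w <- sample.int(3L, 1L)
    gyro[, ax_w] <- spec$amp_w * sign(stats::runif(1L) - 0.5)
  } else if (kind == "no_gyro_const_accel") {
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    accel <- accel + matrix(spec$amp_a * dir, n, 3L, byrow = TRUE)
  } else if (kind != "static") {
    stop("unknown activity kind: ", kind)
  }

  accel <- accel + gravity
  if (cfg$noise_sigma_a > 0)
    accel <- accel + matrix(stats::rnorm(3L * n, 0, cfg$noise_sigma_a), n, 3L)
  if (cfg$noise_sigma_w > 0)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, cfg$noise_sigma_w), n, 3L)
  accel <- pmin(pmax(accel, -cfg$accel_range), cfg$accel_range)
  gyro <- pmin(pmax(gyro, -cfg$gyro_range), cfg$gyro_range)
  list(accel = accel, gyro = gyro,
       marker = rep(if (kind == "static") 0L else 1L, n))
}

runif_range <- function(range) stats::runif(1L, range[1L], range[2L])

#' Draw a random activity sequence
#'
#' Alternates static and activity segments so that every activity is
#' preceded and followed by a static rest, as in a stop-and-go exercise
#' circuit. Kinds are drawn uniformly from the seven-kind repertoire;
#' amplitudes, frequencies and durations are drawn uniformly from the
#' configured intensity ranges.
#'
#' @param cfg a [synth_config()].
#' @param n_activities number of activity segments (>= 1); the sequence has
#'   `2 * n_activities + 1` segments in total.
#' @return List of [activity_segment()]s.
#' @export
random_activity_sequence <- function(cfg = synth_config(), n_activities = 8L) {
  stopifnot(inherits(cfg, "synth_config"))
  n_activities <- as.integer(n_activities)
  if (n_activities < 1L) stop("n_activities must be >= 1")
  specs <- vector("list", 2L * n_activities + 1L)
  mk_static <- function()
    activity_segment("static", runif_range(cfg$static_duration),
                     gravity_axis = cfg$gravity_axis)
  specs[[1L]] <- mk_static()
  for (i in seq_len(n_activities)) {
    kind <- sample(ACTIVITY_KINDS, 1L,
                   prob = ACTIVITY_WEIGHTS[ACTIVITY_KINDS])
    rng <- cfg$intensity_ranges[[kind]]
    dur <- runif_range(if (is.null(rng$duration)) cfg$activity_duration
                       else rng$duration)
    specs[[2L * i]] <- activity_segment(
      kind, dur,
      amp_a = runif_range(rng$amp_a), amp_w = runif_range(rng$amp_w),
      freq_hz = runif_range(rng$freq), gravity_axis = cfg$gravity_axis)
    specs[[2L * i + 1L]] <- mk_static()
  }
  specs
}

#' Synthesize a recording from a list of segment specifications
#'
#' Concatenates the segments' accelerometer, gyroscope and marker blocks
#' into one [imu_recording()] with the ground-truth marker populated.
#'
#' @param specs nonempty list of [activity_segment()]s.
#' @param cfg a [synth_config()].
#' @return An [imu_recording()] with `truth_marker`.
#' @export
synthesize_recording <- function(specs, cfg = synth_config()) {
  if (length(specs) == 0L) stop("specs must be nonempty")
  blocks <- lapply(specs, synthesize_segment, cfg = cfg)
  imu_recording(
    accel = do.call(rbind, lapply(blocks, `[[`, "accel")),
    gyro = do.call(rbind, lapply(blocks, `[[`, "gyro")),
    fs = cfg$fs,
    truth_marker = unlist(lapply(blocks, `[[`, "marker"))
  )
}

#' Synthesize a random activity recording
#'
#' Convenience wrapper: draws a random activity sequence and synthesizes it.
#'
#' @param cfg a [synth_config()].
#' @param n_activities number of activity segments.
#' @param seed optional integer seed for reproducibility.
#' @return An [imu_recording()] with `truth_marker`.
#' @examples
#' rec <- synth_imu(n_activities = 3, seed = 42)
#' rec
#' @export
synth_imu <- function(cfg = synth_config(), n_activities = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  synthesize_recording(random_activity_sequence(cfg, n_activities), cfg)
}
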