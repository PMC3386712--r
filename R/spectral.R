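# Frequency-domain detectors: framed amplitude spectrum, long-term spectral
# envelope, and the LTSD / FSD figures of merit. Borrowed from voice
# activity detection, where tracking the spectral envelope against a noise
# spectrum is robust at low SNR.

#' Framed amplitude spectrum
#'
#' Segments a scalar series into frames of `window` samples advanced by
#' `shift`, optionally tapers each frame, zero-pads to `nfft` points and
#' takes the DFT magnitude. The default taper is rectangular; frames are
#' typically far shorter than `nfft`, so zero-padding interpolates the
#' spectrum onto the full `nfft`-bin grid.
#'
#' @param x scalar input series.
#' @param window frame length in samples.
#' @param shift frame advance in samples.
#' @param nfft FFT resolution (>= window).
#' @param window_fn `"rectangular"` or `"hann"`.
#' @return An object of class `spectral_frames`: list with `X` (nfft x M
#'   nonnegative magnitude matrix, one column per frame), `frame_starts`,
#'   `window`, `shift`, `nfft`.
#' @export
framed_spectrum <- function(x, window, shift = 1L, nfft = 512L,
                            window_fn = c("rectangular", "hann")) {
  x <- as.numeric(x)
  window <- as.integer(window); shift <- as.integer(shift)
  nfft <- as.integer(nfft)
  window_fn <- match.arg(window_fn)
  if (nfft < window) stop("nfft must be >= window")
  if (shift < 1L || shift > window) stop("shift must lie in [1, window]")
  starts <- frame_start_grid(length(x), window, shift)
  frames <- matrix(x[outer(0:(window - 1L), starts, "+")], nrow = window)
  if (window_fn == "hann" && window > 1L) {
    taper <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1L)) / (window - 1L))
    frames <- frames * taper
  }
  padded <- matrix(0, nrow = nfft, ncol = ncol(frames))
  padded[seq_len(window), ] <- frames
  structure(list(X = Mod(stats::mvfft(padded)), frame_starts = starts,
                 window = window, shift = shift, nfft = nfft),
            class = "spectral_frames")
}

#' Average noise spectrum from the leading frames
#'
#' The reference spectrum `N(l)` is the per-band mean magnitude over the
#' first `noise_frame_count` frames, which are assumed static (recordings
#' are expected to begin at rest). To avoid division blow-ups on noiseless
#' synthetic channels, bands are floored at `1e-12 * max(N)` (or at 1e-12
#' when the input is identically zero).
#'
#' @param sf a [framed_spectrum()] result.
#' @param noise_frame_count number of leading frames to average (>= 1).
#' @return Numeric vector of length `nfft`, strictly positive.
#' @export
estimate_noise_spectrum <- function(sf, noise_frame_count = 10L) {
  stopifnot(inherits(sf, "spectral_frames"))
  k <- as.integer(noise_frame_count)
  if (k < 1L) stop("noise_frame_count must be >= 1")
  if (k > ncol(sf$X)) stop("fewer frames available than noise_frame_count")
  ns <- rowMeans(sf$X[, seq_len(k), drop = FALSE])
  top <- max(ns)
  if (top == 0) ns[] <- 1e-12 else ns <- pmax(ns, 1e-12 * top)
  ns
}

#' Long-term spectral envelope (LTSE)
#'
#' Per band, the running maximum of the frame spectra over a symmetric
#' neighborhood of `order` frames on each side (truncated at the
#' boundaries):
#' \deqn{LTSE_J(l, n) = \max_{j = -J..J} X(l, n + j).}
#' Order 0 returns the frame spectra unchanged.
#'
#' @param sf a [framed_spectrum()] result.
#' @param order envelope order J (>= 0).
#' @return An object of class `spectral_envelope`: list with `LTSE`
#'   (nfft x M matrix), `order`, and the framing metadata of `sf`.
#' @export
ltse <- function(sf, order = 1L) {
  stopifnot(inherits(sf, "spectral_frames"))
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  x <- sf$X
  m <- ncol(x)
  env <- x
  for (j in seq_len(min(order, m - 1L))) {
    left <- seq_len(m - j)
    env[, left] <- pmax(env[, left], x[, left + j])
    env[, left + j] <- pmax(env[, left + j], x[, left])
  }
  structure(list(LTSE = env, order = order, frame_starts = sf$frame_starts,
                 window = sf$window, shift = sf$shift, nfft = sf$nfft),
            class = "spectral_envelope")
}

ltsd_core <- function(mag, noise, frame_starts, window, shift) {
  if (any(noise <= 0)) stop("noise spectrum must be strictly positive")
  v <- 10 * log10(colMeans((mag / noise)^2))
  imu_fom(v, frame_starts, window, shift)
}

#' Long-term spectral detector (LTSD) figure of merit
#'
#' Per frame, the band-averaged squared ratio of the long-term spectral
#' envelope to the noise spectrum, in decibels:
#' \deqn{V(n) = 10 \log_{10}\!\left( \frac{1}{N_{FFT}} \sum_{l}
#'   \frac{LTSE^2(l, n)}{N^2(l)} \right).}
#' Values can be negative (envelope below the noise reference).
#'
#' @param env a [ltse()] result.
#' @param noise noise spectrum `N(l)`, length `nfft`, strictly positive
#'   (see [estimate_noise_spectrum()]).
#' @return An [imu_fom()] in dB.
#' @export
ltsd_fom <- function(env, noise) {
  stopifnot(inherits(env, "spectral_envelope"))
  ltsd_core(env$LTSE, noise, env$frame_starts, env$window, env$shift)
}

#' Framed spectrum detector (FSD) figure of merit
#'
#' Identical to [ltsd_fom()] but uses each frame's own spectrum instead of
#' the long-term envelope; equivalently, LTSD at envelope order 0.
#'
#' @param sf a [framed_spectrum()] result.
#' @inheritParams ltsd_fom
#' @return An [imu_fom()] in dB.
#' @export
fsd_fom <- function(sf, noise) {
  stopifnot(inherits(sf, "spectral_frames"))
  ltsd_core(sf$X, noise, sf$frame_starts, sf$window, sf$shift)
}
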