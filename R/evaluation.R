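# Evaluation: per-sample accuracy and phi correlation against ground truth,
# ROC/AUC, per-signal grid-search optimization of detector parameters, and
# the Monte-Carlo benchmarking driver.

#' Per-sample detection accuracy
#'
#' Fraction of samples where the estimated marker equals the ground truth.
#'
#' @param est,truth binary vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
marker_accuracy <- function(est, truth) {
  if (length(est) != length(truth)) stop("marker lengths differ")
  mean(est == truth)
}

#' Correlation coefficient of two binary markers
#'
#' Pearson's r on the binary vectors (the phi coefficient). When either
#' vector is constant the coefficient is undefined; by convention it is 1
#' when the two vectors are identical and 0 otherwise.
#'
#' @inheritParams marker_accuracy
#' @return Coefficient in `[-1, 1]`.
#' @export
marker_correlation <- function(est, truth) {
  if (length(est) != length(truth)) stop("marker lengths differ")
  if (stats::var(est) == 0 || stats::var(truth) == 0)
    return(if (all(est == truth)) 1 else 0)
  stats::cor(est, truth)
}

# threshold grid spanning the observed figure-of-merit range: log-spaced
# when the statistic is strictly positive (magnitude/memory detectors span
# decades), linear otherwise (dB-scale statistics are already logarithmic).
threshold_grid <- function(v, n = 40L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite figure-of-merit values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  if (lo > 0) exp(seq(log(lo), log(hi), length.out = n))
  else seq(lo, hi, length.out = n)
}

# accuracy and phi at each threshold, computed from class-sorted scores.
# Decision rule: score >= gamma -> active.
threshold_metrics <- function(score, truth, gammas) {
  if (length(score) != length(truth)) stop("score/truth lengths differ")
  s1 <- sort(score[truth == 1])
  s0 <- sort(score[truth == 0])
  p <- length(s1); nn <- length(s0); tot <- p + nn
  fn <- as.numeric(findInterval(gammas, s1, left.open = TRUE))  # #(s1 < g)
  tn <- as.numeric(findInterval(gammas, s0, left.open = TRUE))
  tp <- p - fn; fp <- nn - tn
  acc <- (tp + tn) / tot
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  phi <- ifelse(denom > 0, (tp * tn - fp * fn) / denom, 0)
  # constant estimated marker: phi defined as 1 iff identical to truth
  est_const <- (tp + fp) %in% c(0L, tot)
  phi[est_const] <- ifelse(acc[est_const] == 1, 1, 0)
  data.frame(threshold = gammas, accuracy = acc, correlation = phi)
}

#' ROC curve of per-sample scores against a binary truth marker
#'
#' Sweeps the decision threshold over every distinct score value (plus
#' sentinels), computing the per-sample true- and false-positive rates
#' under the rule score >= threshold -> active. The curve starts at (0, 0)
#' and ends at (1, 1), with nondecreasing FPR.
#'
#' @param score per-sample decision scores (e.g. [fom_sample_scores()]).
#' @param truth binary ground-truth marker; must contain both classes.
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(score, truth) {
  if (length(score) != length(truth)) stop("score/truth lengths differ")
  p <- sum(truth == 1); nn <- sum(truth == 0)
  if (p == 0L || nn == 0L)
    stop("truth marker must contain both classes for a ROC curve")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / nn), tpr = c(0, tp / p))
}

#' Area under a ROC curve (trapezoidal)
#'
#' @param roc a `data.frame` with `fpr` and `tpr` columns ordered by
#'   nondecreasing `fpr`, as returned by [roc_points()] or [average_roc()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  fpr <- roc$fpr; tpr <- roc$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Vertically average ROC curves
#'
#' Interpolates each curve's TPR on a fixed FPR grid and averages across
#' curves, the standard construction for a mean ROC over replicates.
#'
#' @param curves list of ROC `data.frame`s (see [roc_points()]).
#' @param fpr_grid FPR evaluation grid.
#' @return List with `curve` (`data.frame` of `fpr`, `tpr`) and `auc` of
#'   the mean curve.
#' @export
average_roc <- function(curves, fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(curves) == 0L) stop("need at least one ROC curve")
  tprs <- vapply(curves, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = fpr_grid, rule = 2,
                  ties = max)$y
  }, numeric(length(fpr_grid)))
  curve <- data.frame(fpr = fpr_grid, tpr = rowMeans(as.matrix(tprs)))
  list(curve = curve, auc = roc_auc(curve))
}

#' Default parameter grid for a detector
#'
#' Windows in samples; shifts only for the spectral detectors; envelope
#' orders only for LTSD. The magnitude detectors sweep a dense window grid
#' up to 40 plus a sparse tail to 100 samples (the acceleration-magnitude
#' detector optimizes at windows near two seconds); the spectral grid is
#' log-like in both window and shift; the memory-based buffers are kept at
#' or below 20 samples, where the split-scan cost is modest and past which
#' their optima do not move.
#'
#' @param method detector id.
#' @return List with `windows`, `shifts`, `orders` (entries may be `NA`).
#' @export
default_grid <- function(method) {
  method <- match.arg(tolower(method), DETECTOR_IDS)
  switch(
    method,
    amvd = ,
    amd = ,
    ared = ,
    shod = list(windows = c(2:40, 50L, 60L, 80L, 100L), shifts = 1L,
                orders = NA_integer_),
    frd = list(windows = NA_integer_, shifts = NA_integer_,
               orders = NA_integer_),
    fsd = list(windows = c(2:6, 8L, 10L, 13L, 16L, 20L, 26L, 32L, 40L),
               shifts = c(1:3, 5L, 7L, 10L, 14L, 20L),
               orders = NA_integer_),
    ltsd = list(windows = c(2:6, 8L, 10L, 13L, 16L, 20L, 26L, 32L, 40L),
                shifts = c(1:3, 5L, 7L, 10L, 14L, 20L),
                orders = 0:3),
    mbgtd = ,
    mbcd = list(windows = c(3:6, 8L, 10L, 12L, 16L, 20L), shifts = 1L,
                orders = NA_integer_)
  )
}

# figure of merit for one parameter combination (no thresholding)
compute_fom <- function(rec, method, window, shift, order, input_mode,
                        noise, base_cfg) {
  switch(
    method,
    amvd = amvd_fom(rec$accel, window),
    amd = amd_fom(rec$accel, window, noise$sigma_a2),
    ared = ared_fom(rec$gyro, window, noise$sigma_w2),
    shod = shod_fom(rec$accel, rec$gyro, window,
                    noise$sigma_a2, noise$sigma_w2),
    frd = frd_fom(input_combination(rec, input_mode), rec$fs,
                  hpf_cutoff = base_cfg$hpf_cutoff,
                  lpf_cutoff = base_cfg$lpf_cutoff,
                  order = base_cfg$filter_order,
                  zero_phase = base_cfg$zero_phase),
    fsd = ,
    ltsd = {
      x <- input_combination(rec, input_mode)
      sf <- framed_spectrum(x, window, shift, base_cfg$nfft,
                            base_cfg$window_fn)
      ns <- estimate_noise_spectrum(sf, min(base_cfg$noise_frames,
                                            ncol(sf$X)))
      if (method == "fsd") fsd_fom(sf, ns)
      else ltsd_fom(ltse(sf, order), ns)
    },
    mbgtd = ,
    mbcd = {
      x <- input_combination(rec, input_mode)
      sliding_memory_detector(x, window, method, gamma = 0,
                              lambda = base_cfg$parzen_lambda)$fom
    })
}

#' Grid-search the parameters of a detector on one recording
#'
#' Sweeps window length (and, per detector, frame shift and envelope order)
#' over the grid; at each point the decision threshold is swept over values
#' spanning that figure of merit's observed range, and per-sample accuracy
#' and phi correlation against the recording's ground-truth marker are
#' computed. The maximum accuracy and maximum correlation over the grid are
#' recorded, together with the parameters attaining the accuracy maximum.
#' Ties in accuracy are broken toward smaller window, then smaller
#' threshold (lower detection latency).
#'
#' @param rec an [imu_recording()] with `truth_marker`.
#' @param method detector id (see [run_detector()]).
#' @param input_mode input combination for the flexible-input detectors.
#' @param grid list with `windows`, `shifts`, `orders`; defaults to
#'   [default_grid()].
#' @param n_thresholds thresholds per grid point.
#' @param noise a `noise_profile`; estimated from the recording when `NULL`.
#' @param base_cfg a [detector_config()] supplying the non-swept parameters
#'   (FFT size, FRD filters, Parzen bandwidth rule, ...).
#' @param keep_scores if `TRUE`, the per-sample score vector at the
#'   accuracy-optimal window/shift/order is returned (for ROC analysis).
#' @return A list of class `grid_search_result`: `best` (named list with
#'   `accuracy`, `correlation`, `window`, `shift`, `order`, `threshold`),
#'   `best_correlation` (maximum over the whole grid), `results` (full
#'   `data.frame` of the grid), and optionally `scores`.
#' @export
grid_search <- function(rec, method, input_mode = "acc", grid = NULL,
                        n_thresholds = 40L, noise = NULL,
                        base_cfg = detector_config(),
                        keep_scores = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(rec$truth_marker))
    stop("grid_search requires a ground-truth marker")
  method <- match.arg(tolower(method), DETECTOR_IDS)
  if (is.null(grid)) grid <- default_grid(method)
  if (is.null(noise) && method %in% c("amd", "ared", "shod"))
    noise <- estimate_noise_profile(rec)
  n <- n_samples(rec)
  truth <- rec$truth_marker

  combos <- expand.grid(window = grid$windows, shift = grid$shifts,
                        order = grid$orders, KEEP.OUT.ATTRS = FALSE)
  ok <- is.na(combos$shift) | is.na(combos$window) |
    combos$shift <= combos$window
  combos <- combos[ok & (is.na(combos$window) | combos$window <= n), ,
                   drop = FALSE]
  if (nrow(combos) == 0L) stop("empty parameter grid for this recording")

  score_metrics <- function(fom, w, s, o) {
    score <- fom_sample_scores(fom, n)
    met <- threshold_metrics(score, truth,
                             threshold_grid(fom$values, n_thresholds))
    met$window <- w; met$shift <- s; met$order <- o
    met
  }
  rows <- list()
  if (method == "ltsd") {
    # the envelope max commutes with the per-band squared noise ratio, so
    # the ratio matrix is built once per (window, shift) and the envelope
    # grown incrementally across orders
    x <- input_combination(rec, input_mode)
    orders <- sort(unique(combos$order))
    ws <- unique(combos[, c("window", "shift")])
    for (ri in seq_len(nrow(ws))) {
      w <- ws$window[ri]; s <- ws$shift[ri]
      sf <- framed_spectrum(x, w, s, base_cfg$nfft, base_cfg$window_fn)
      ns <- estimate_noise_spectrum(sf, min(base_cfg$noise_frames,
                                            ncol(sf$X)))
      r <- (sf$X / ns)^2
      env <- r
      m <- ncol(r)
      for (j in 0:max(orders)) {
        if (j > 0L && j < m) {
          left <- seq_len(m - j)
          env[, left] <- pmax(env[, left], r[, left + j])
          env[, left + j] <- pmax(env[, left + j], r[, left])
        }
        if (j %in% orders) {
          fom <- imu_fom(10 * log10(colMeans(env)), sf$frame_starts, w, s)
          rows[[length(rows) + 1L]] <- score_metrics(fom, w, s, j)
        }
      }
    }
  } else {
    for (ci in seq_len(nrow(combos))) {
      w <- combos$window[ci]; s <- combos$shift[ci]; o <- combos$order[ci]
      fom <- compute_fom(rec, method, w, if (is.na(s)) 1L else s,
                         if (is.na(o)) 0L else o, input_mode, noise,
                         base_cfg)
      rows[[ci]] <- score_metrics(fom, w, s, o)
    }
  }
  results <- do.call(rbind, rows)

  # accuracy-optimal point; ties toward smaller window, then threshold
  ord <- order(-results$accuracy,
               if (all(is.na(results$window))) seq_len(nrow(results))
               else results$window,
               results$threshold)
  top <- results[ord[1L], ]
  best <- list(accuracy = top$accuracy, correlation = top$correlation,
               window = top$window, shift = top$shift, order = top$order,
               threshold = top$threshold)
  out <- list(best = best, best_correlation = max(results$correlation),
              results = results, method = method, input_mode = input_mode)
  if (keep_scores) {
    fom <- compute_fom(rec, method, top$window,
                       if (is.na(top$shift)) 1L else top$shift,
                       if (is.na(top$order)) 0L else top$order,
                       input_mode, noise, base_cfg)
    out$scores <- fom_sample_scores(fom, n)
  }
  structure(out, class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<grid_search_result> %s%s: accuracy %.4f (phi %.4f) at window %s, threshold %.4g%s%s\n",
    toupper(x$method),
    if (x$method %in% c("frd", "fsd", "ltsd", "mbgtd", "mbcd"))
      paste0("-", toupper(x$input_mode)) else "",
    b$accuracy, b$correlation,
    ifelse(is.na(b$window), "-", b$window), b$threshold,
    if (!is.na(b$shift)) sprintf(", shift %d", b$shift) else "",
    if (!is.na(b$order)) sprintf(", order %d", b$order) else ""))
  invisible(x)
}

parse_method_spec <- function(spec) {
  parts <- strsplit(tolower(spec), "-", fixed = TRUE)[[1L]]
  method <- match.arg(parts[1L], DETECTOR_IDS)
  mode <- if (length(parts) > 1L)
    match.arg(parts[2L], c("acc", "ang", "sum", "prod")) else "acc"
  list(method = method, input_mode = mode,
       label = if (method %in% c("frd", "fsd", "ltsd", "mbgtd", "mbcd"))
         paste0(toupper(method), "-", toupper(mode)) else toupper(method))
}

#' Monte-Carlo benchmark of detectors on synthesized recordings
#'
#' At every repetition a fresh activity recording is synthesized and every
#' requested detector is grid-search optimized on it; the per-signal maxima
#' of accuracy and correlation, and the optimizing parameter values, are
#' collected and summarized as mean and (unbiased) standard deviation
#' across repetitions. Fully reproducible: per-repetition seeds are derived
#' deterministically from the master seed.
#'
#' @param methods character vector of detector specs; flexible-input
#'   detectors take their input mode as a suffix, e.g. `"shod"`,
#'   `"fsd-prod"`, `"ltsd-sum"`.
#' @param n_runs number of Monte-Carlo repetitions (>= 2).
#' @param cfg a [synth_config()].
#' @param n_activities activity segments per synthesized recording.
#' @param seed master seed.
#' @param grids optional named list (by method spec) of grid overrides.
#' @param roc_specs subset of `methods` for which per-run ROC curves are
#'   collected (threshold sweep at the accuracy-optimal window).
#' @param n_thresholds thresholds per grid point.
#' @param base_cfg a [detector_config()] supplying non-swept parameters.
#' @return A list of class `imu_benchmark`: `summary` (one row per
#'   detector: mean/sd of max accuracy, max correlation and optimal
#'   parameters), `runs` (per-run results), `roc` (named list: per spec,
#'   the vertically averaged ROC and its AUC), `n_runs`, `seed`.
#' @examples
#' \donttest{
#' bench <- monte_carlo(c("shod", "amvd"), n_runs = 3, seed = 7)
#' bench$summary
#' }
#' @export
monte_carlo <- function(methods, n_runs = 50L, cfg = synth_config(),
                        n_activities = 8L, seed = 1L, grids = list(),
                        roc_specs = character(), n_thresholds = 40L,
                        base_cfg = detector_config()) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  specs <- lapply(methods, parse_method_spec)
  labels <- vapply(specs, `[[`, "", "label")
  roc_labels <- vapply(lapply(roc_specs, parse_method_spec), `[[`, "",
                       "label")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  rows <- list()
  roc_store <- stats::setNames(
    replicate(length(roc_labels), vector("list", n_runs), simplify = FALSE),
    roc_labels)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    rec <- synth_imu(cfg, n_activities)
    noise <- estimate_noise_profile(rec)
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      want_roc <- sp$label %in% roc_labels
      gs <- grid_search(rec, sp$method, sp$input_mode,
                        grid = grids[[methods[si]]],
                        n_thresholds = n_thresholds, noise = noise,
                        base_cfg = base_cfg, keep_scores = want_roc)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, detector = sp$label,
        accuracy = gs$best$accuracy, correlation = gs$best_correlation,
        window = gs$best$window, shift = gs$best$shift,
        order = gs$best$order, threshold = gs$best$threshold)
      if (want_roc)
        roc_store[[sp$label]][[r]] <- roc_points(gs$scores,
                                                 rec$truth_marker)
    }
  }
  runs <- do.call(rbind, rows)

  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  summary_df <- do.call(rbind, lapply(unique(labels), function(lab) {
    d <- runs[runs$detector == lab, ]
    data.frame(detector = lab,
               accuracy = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
               correlation = mean(d$correlation),
               correlation_sd = stats::sd(d$correlation),
               window = mean(d$window), window_sd = stats::sd(d$window),
               threshold = mean(d$threshold),
               threshold_sd = stats::sd(d$threshold),
               shift = mean(d$shift), shift_sd = stats::sd(d$shift))
  }))
  roc_avg <- lapply(roc_store, average_roc)
  structure(list(summary = summary_df, runs = runs, roc = roc_avg,
                 n_runs = n_runs, seed = seed),
            class = "imu_benchmark")
}

#' @export
print.imu_benchmark <- function(x, ...) {
  cat(sprintf("<imu_benchmark> %d Monte-Carlo runs (seed %d)\n",
              x$n_runs, x$seed))
  df <- x$summary
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-12s accuracy %.4f +/- %.4f  phi %.4f +/- %.4f\n",
                df$detector[i], df$accuracy[i], df$accuracy_sd[i],
                df$correlation[i], df$correlation_sd[i]))
  for (lab in names(x$roc))
    cat(sprintf("  %-12s mean-ROC AUC %.4f\n", lab, x$roc[[lab]]$auc))
  invisible(x)
}
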