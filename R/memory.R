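# Memory-based change detectors over a sliding buffer of the last N scalar
# readings. Both score every split of the buffer into two adjacent
# sub-windows and report the best split's statistic; a change of signal
# regime inside the buffer produces a large value regardless of where the
# change falls. The single-buffer functions below are plain-R reference
# implementations; the sliding scans used by run_detector() are compiled
# (see src/) because they cost O(N^2)-O(N^3) per sample.

#' Memory-based graph-theoretic detector (MBGTD) statistic of one buffer
#'
#' For every split index pair (i, j) with 1 <= i < j <= N, the average
#' Euclidean distance between the sub-windows \eqn{x_i..x_{j-1}} and
#' \eqn{x_j..x_N}:
#' \deqn{C_{i,j} = \frac{\sum_{k=i}^{j-1} \sum_{l=j}^{N} d_{k,l}}
#'   {(j - i)(N - j + 1)},}
#' and the statistic is the maximum over all splits.
#'
#' @param x numeric buffer of N >= 2 scalar samples.
#' @return Scalar V >= 0, with attribute `split = c(i, j)` giving the
#'   winning split.
#' @examples
#' mbgtd_fom(c(0, 0, 0, 1, 1, 1))  # 1, split at i = 1, j = 4
#' @export
mbgtd_fom <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("buffer must contain at least 2 samples")
  d <- abs(outer(x, x, "-"))
  best <- -Inf; best_split <- c(NA_integer_, NA_integer_)
  for (j in 2:n) {
    # suffix sums over the second window, per first-window sample k
    a <- rowSums(d[, j:n, drop = FALSE])  # A(k) = sum_{l=j}^{N} d_kl
    num <- rev(cumsum(rev(a[1:(j - 1L)])))  # num[i] = sum_{k=i}^{j-1} A(k)
    cij <- num / ((j - seq_len(j - 1L)) * (n - j + 1L))
    i_star <- which.max(cij)
    if (cij[i_star] > best) {
      best <- cij[i_star]
      best_split <- c(i_star, j)
    }
  }
  structure(best, split = best_split)
}

#' Gaussian Parzen kernel weight and density estimate
#'
#' The kernel weight for a pair of samples at distance r with bandwidth
#' lambda is \eqn{w = \exp(-\tfrac12 (r/\lambda)^2)}; it equals 1 at zero
#' distance and exp(-0.5) at distance lambda. `parzen_density()` is the
#' corresponding kernel density estimate at evaluation points `at`:
#' \deqn{\hat p(x) = \frac{1}{N \lambda \sqrt{2\pi}} \sum_i w(x, x_i).}
#'
#' @param x_l,x_k sample values (vectorized).
#' @param lambda kernel standard deviation (> 0).
#' @return `parzen_weight`: weights in (0, 1]. `parzen_density`: density
#'   values at `at`.
#' @export
parzen_weight <- function(x_l, x_k, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  exp(-0.5 * (abs(x_l - x_k) / lambda)^2)
}

#' @rdname parzen_weight
#' @param at evaluation points.
#' @param samples observed samples the estimate is built from.
#' @export
parzen_density <- function(at, samples, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  n <- length(samples)
  vapply(at, function(x0) sum(parzen_weight(x0, samples, lambda)),
         numeric(1)) / (n * lambda * sqrt(2 * pi))
}

#' Silverman's bandwidth for a buffer
#' @noRd
silverman_lambda <- function(x) {
  max(1.06 * stats::sd(x) * length(x)^(-1 / 5), 1e-6)
}

#' Memory-based CUSUM detector (MBCD) statistic of one buffer
#'
#' CUSUM-type log-likelihood ratio where the pre- and post-change densities
#' of the two sub-windows are Parzen estimates. For a split (i, j):
#' \deqn{S_{i,j} = \sum_{l=j}^{N} \log \frac{\frac{1}{N-j+1}
#'   \sum_{k=j}^{N} w_{l,k}}{\frac{1}{j-i} \sum_{k=i}^{j-1} w_{l,k}},}
#' with \eqn{w_{l,k}} the Parzen kernel weight of the sample pair; the
#' statistic is the maximum over all splits. Kernel-weight sums are floored
#' at 1e-300 before the logarithm so distant sub-windows do not produce
#' infinities.
#'
#' @param x numeric buffer of N >= 3 scalar samples.
#' @param lambda Parzen bandwidth; `NULL` selects Silverman's rule
#'   \eqn{1.06\, sd(x)\, N^{-1/5}} (floored at 1e-6).
#' @return Scalar V with attribute `split = c(i, j)`.
#' @export
mbcd_fom <- function(x, lambda = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("buffer must contain at least 3 samples")
  if (is.null(lambda)) lambda <- silverman_lambda(x)
  if (lambda <= 0) stop("lambda must be positive")
  w <- parzen_weight(outer(x, x, "-"), 0, lambda)
  best <- -Inf; best_split <- c(NA_integer_, NA_integer_)
  # weight sums are accumulated directly (never by differencing running
  # sums): kernel weights underflow to ~0 for distant samples and
  # cancellation would swamp the log-ratios
  for (j in 2:n) {
    ls <- j:n
    post <- pmax(rowSums(w[ls, j:n, drop = FALSE]) / (n - j + 1L), 1e-300)
    pre_sum <- rep(0, length(ls))
    for (i in (j - 1L):1L) {
      pre_sum <- pre_sum + w[ls, i]
      pre <- pmax(pre_sum / (j - i), 1e-300)
      s <- sum(log(post / pre))
      if (s > best) {
        best <- s
        best_split <- c(i, j)
      }
    }
  }
  structure(best, split = best_split)
}

#' Classic CUSUM change detector with known densities
#'
#' Reference cumulative-sum detector: accumulates the log-likelihood ratio
#' of each reading under the post-change vs pre-change densities,
#' \deqn{s_i = \ln \frac{p_1(x_i)}{p_0(x_i)}, \quad S_k = \sum_{i \le k}
#'   s_i, \quad g_k = S_k - \min_{0 \le j \le k} S_j \quad (S_0 = 0),}
#' (equivalently \eqn{g_k = \max(0, g_{k-1} + s_k)}),
#' and alarms at the first k with \eqn{g_k \ge h}. Serves as the
#' known-distribution limit that [mbcd_fom()] approximates with Parzen
#' estimates.
#'
#' @param x numeric series.
#' @param p0,p1 density functions (vectorized), strictly positive on `x`.
#' @param h alarm threshold (> 0).
#' @return List with `alarm` (first alarm index, `NA` if none), `g`
#'   (decision statistic, nonnegative) and `S` (cumulative log-likelihood).
#' @export
cusum_classic <- function(x, p0, p1, h) {
  x <- as.numeric(x)
  d0 <- p0(x); d1 <- p1(x)
  if (any(d0 <= 0) || any(d1 <= 0))
    stop("densities must be strictly positive on the data")
  s <- log(d1 / d0)
  big_s <- cumsum(s)
  g <- big_s - pmin(cummin(big_s), 0)  # running min over S_0 = 0, S_1, ...
  alarm <- which(g >= h)[1L]
  list(alarm = if (is.na(alarm)) NA_integer_ else alarm, g = g, S = big_s)
}

#' Sliding memory-based detection over a scalar series
#'
#' Applies [mbgtd_fom()] or [mbcd_fom()] to every length-`window` buffer of
#' the series advanced by one sample (compiled scan), then thresholds the
#' resulting figure of merit into a per-sample marker.
#'
#' @param x scalar input series (see [input_combination()]).
#' @param window buffer length N in samples.
#' @param method `"mbgtd"` or `"mbcd"`.
#' @param gamma decision threshold.
#' @param lambda Parzen bandwidth for MBCD. `NULL` (the default) fixes the
#'   bandwidth for the whole series at the series' standard deviation
#'   (floored at 1e-6): static buffers then have pairwise distances far
#'   below `lambda`, weights near 1 and a statistic near 0, while buffers
#'   inside an activity spread at the `lambda` scale and score high. (A
#'   bandwidth re-estimated per buffer would make the statistic
#'   scale-invariant and blind to steady activity.)
#' @return List with `fom` (an [imu_fom()], one value per buffer position)
#'   and `marker` (length of `x`).
#' @export
sliding_memory_detector <- function(x, window, method = c("mbgtd", "mbcd"),
                                    gamma = 1, lambda = NULL) {
  x <- as.numeric(x)
  method <- match.arg(method)
  window <- as.integer(window)
  min_n <- if (method == "mbgtd") 2L else 3L
  if (window < min_n)
    stop(sprintf("window must be >= %d for %s", min_n, method))
  if (length(x) < window) stop("series shorter than the buffer window")
  if (method == "mbcd" && is.null(lambda))
    lambda <- max(stats::sd(x), 1e-6)
  v <- if (method == "mbgtd") mbgtd_series(x, window)
       else mbcd_series(x, window, lambda)
  fom <- imu_fom(v, frame_start_grid(length(x), window, 1L), window, 1L)
  list(fom = fom, marker = threshold_marker(fom, gamma, length(x)))
}
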