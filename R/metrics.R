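#' Threshold-crossing spike detection
#'
#' Detects spikes in a high-pass (or reconstructed) trace as excursions
#' below `k_sigma * sigma` (default -6 SD of the background noise).
#' Contiguous sub-threshold samples form an event; events separated by
#' less than `dead_time_ms` are merged, and each event is timestamped at
#' its most negative sample (the spike's negative peak).
#'
#' @param x Numeric trace.
#' @param sigma Background-noise SD on the same scale as `x` (> 0); see
#'   [noise_sigma()].
#' @param fs Sampling rate, Hz.
#' @param k_sigma Threshold multiple, negative (default -6).
#' @param dead_time_ms Merge window between threshold crossings, ms.
#' @return Integer vector of 1-based sample indices, strictly
#'   increasing.
#' @export
detect_spikes <- function(x, sigma, fs, k_sigma = -6, dead_time_ms = 1) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  if (k_sigma >= 0) stop("k_sigma must be negative")
  if (dead_time_ms <= 0) stop("dead_time_ms must be positive")
  x <- as.numeric(x)
  thr <- k_sigma * sigma
  below <- which(x < thr)
  if (length(below) == 0L) return(integer(0))
  dead <- max(1L, as.integer(round(dead_time_ms / 1000 * fs)))
  brk <- which(diff(below) >= dead)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(below))
  vapply(seq_along(starts), function(i) {
    idx <- below[starts[i]:ends[i]]
    idx[which.min(x[idx])]
  }, integer(1))
}

#' Match ground-truth and reconstructed spike trains
#'
#' One-to-one matching of reconstructed to ground-truth timestamps
#' within a tolerance (default +/-500 microseconds). The matching is the
#' optimal non-crossing assignment: among all one-to-one pairings within
#' tolerance it maximises the number of matches and, among those,
#' minimises the total absolute time difference (dynamic programme over
#' the two sorted trains). Matched pairs are true positives; unmatched
#' reconstructed spikes are false positives, unmatched ground-truth
#' spikes false negatives.
#'
#' @param gt_times Sorted ground-truth spike sample indices.
#' @param rec_times Sorted reconstructed spike sample indices.
#' @param fs Sampling rate, Hz.
#' @param tolerance_us Matching tolerance in microseconds (default 500).
#' @return An object of class `"match_result"`: list with `pairs`
#'   (two-column matrix of matched `gt`/`rec` sample indices),
#'   `fp_times`, `fn_times`, `delays_us` (signed, rec - gt),
#'   `hit_rate` = TP / (TP + FN), `precision` = TP / (TP + FP), and the
#'   `tolerance_us` used. `hit_rate`/`precision` are `NaN` when their
#'   denominator is zero.
#' @examples
#' m <- match_trains(c(2500), c(2510, 3750), fs = 25000)
#' m$hit_rate; m$precision; m$delays_us
#' @export
match_trains <- function(gt_times, rec_times, fs, tolerance_us = 500) {
  gt_times <- as.numeric(gt_times)
  rec_times <- as.numeric(rec_times)
  if (is.unsorted(gt_times, strictly = FALSE)) stop("gt_times must be sorted")
  if (is.unsorted(rec_times, strictly = FALSE)) stop("rec_times must be sorted")
  tol <- tolerance_us * 1e-6 * fs   # tolerance in samples
  n <- length(gt_times)
  m <- length(rec_times)
  # DP over prefixes: maximise matches, then minimise summed |dt|.
  # Non-crossing pairings are sufficient for optimality on a line.
  best_n <- matrix(0L, n + 1L, m + 1L)
  best_c <- matrix(0, n + 1L, m + 1L)
  move <- matrix(0L, n + 1L, m + 1L)  # 1 = skip gt, 2 = skip rec, 3 = pair
  for (i in seq_len(n + 1L) - 1L) {
    for (j in seq_len(m + 1L) - 1L) {
      if (i == 0L && j == 0L) next
      bn <- -1L; bc <- Inf; mv <- 0L
      if (i > 0L) {
        bn <- best_n[i, j + 1L]; bc <- best_c[i, j + 1L]; mv <- 1L
      }
      if (j > 0L) {
        cn <- best_n[i + 1L, j]; cc <- best_c[i + 1L, j]
        if (cn > bn || (cn == bn && cc < bc)) { bn <- cn; bc <- cc; mv <- 2L }
      }
      if (i > 0L && j > 0L) {
        d <- abs(rec_times[j] - gt_times[i])
        if (d <= tol) {
          cn <- best_n[i, j] + 1L; cc <- best_c[i, j] + d
          if (cn > bn || (cn == bn && cc < bc)) { bn <- cn; bc <- cc; mv <- 3L }
        }
      }
      best_n[i + 1L, j + 1L] <- bn
      best_c[i + 1L, j + 1L] <- bc
      move[i + 1L, j + 1L] <- mv
    }
  }
  pi_ <- n; pj <- m
  gi <- integer(0); rj <- integer(0)
  while (pi_ > 0L || pj > 0L) {
    mv <- move[pi_ + 1L, pj + 1L]
    if (mv == 3L) {
      gi <- c(pi_, gi); rj <- c(pj, rj)
      pi_ <- pi_ - 1L; pj <- pj - 1L
    } else if (mv == 1L) {
      pi_ <- pi_ - 1L
    } else {
      pj <- pj - 1L
    }
  }
  tp <- length(gi)
  delays <- (rec_times[rj] - gt_times[gi]) / fs * 1e6
  structure(
    list(
      pairs = cbind(gt = gt_times[gi], rec = rec_times[rj]),
      fp_times = rec_times[setdiff(seq_len(m), rj)],
      fn_times = gt_times[setdiff(seq_len(n), gi)],
      delays_us = delays,
      hit_rate = if (n > 0) tp / n else NaN,
      precision = if (m > 0) tp / m else NaN,
      tolerance_us = tolerance_us
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FP %d, FN %d | hit rate %.3f, precision %.3f (tol %g us)\n",
    nrow(x$pairs), length(x$fp_times), length(x$fn_times),
    x$hit_rate, x$precision, x$tolerance_us
  ))
  invisible(x)
}

# Window extraction around ground-truth timestamps: -pre to +post ms,
# inclusive of the peak sample. Returns NULL when support is incomplete.
extract_window <- function(trace, center, fs, pre_ms, post_ms) {
  pre <- as.integer(round(pre_ms / 1000 * fs))
  post <- as.integer(round(post_ms / 1000 * fs))
  lo <- center - pre
  hi <- center + post
  if (lo < 1L || hi > length(trace)) return(NULL)
  trace[lo:hi]
}

#' Normalised RMS error of reconstructed spike waveforms
#'
#' For each matched ground-truth timestamp, compares the ground-truth
#' and reconstructed traces point by point over a window from
#' `-pre_ms` to `+post_ms` (default -1 to +2 ms) around the timestamp,
#' and normalises the RMS error by the ground-truth window's
#' peak-to-peak amplitude. Windows with zero peak-to-peak amplitude, or
#' without full support inside the trace, are skipped with a warning.
#'
#' @param gt_trace Ground-truth trace.
#' @param rec_trace Reconstructed trace (same length and scale).
#' @param gt_times Matched ground-truth spike sample indices.
#' @param fs Sampling rate, Hz.
#' @param pre_ms,post_ms Window extent around the timestamp, ms.
#' @return List with `per_spike` (NRMSE per usable spike) and `mean`.
#' @export
waveform_nrmse <- function(gt_trace, rec_trace, gt_times, fs,
                           pre_ms = 1, post_ms = 2) {
  if (length(gt_trace) != length(rec_trace)) {
    stop("traces must have equal length")
  }
  vals <- numeric(0)
  skipped <- 0L
  for (n0 in gt_times) {
    g <- extract_window(gt_trace, n0, fs, pre_ms, post_ms)
    r <- extract_window(rec_trace, n0, fs, pre_ms, post_ms)
    if (is.null(g) || is.null(r)) { skipped <- skipped + 1L; next }
    ptp <- max(g) - min(g)
    if (ptp == 0) { skipped <- skipped + 1L; next }
    vals <- c(vals, sqrt(mean((g - r)^2)) / ptp)
  }
  if (skipped > 0L) {
    warning(sprintf("%d spike window(s) skipped (no support or flat)", skipped))
  }
  list(per_spike = vals, mean = if (length(vals)) mean(vals) else NaN)
}

#' Mean signed timing delay of matched spikes
#'
#' @param match A `"match_result"` from [match_trains()].
#' @return Mean of the signed delays (reconstructed minus ground truth)
#'   in microseconds.
#' @export
mean_time_delay <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (length(match$delays_us) == 0L) stop("no matched pairs")
  mean(match$delays_us)
}

#' Average spike waveform aligned on ground-truth timestamps
#'
#' Sample-wise mean of trace windows (default -1 to +2 ms) extracted
#' around ground-truth timestamps — alignment is always on the
#' ground-truth peaks, so ground-truth and reconstructed averages are
#' directly superimposable.
#'
#' @inheritParams waveform_nrmse
#' @param trace Trace to average from (ground truth or reconstruction).
#' @param times Ground-truth spike sample indices (matched spikes).
#' @return Numeric vector: the mean waveform. Errors if no window has
#'   full support.
#' @export
average_waveform <- function(trace, times, fs, pre_ms = 1, post_ms = 2) {
  wins <- lapply(times, extract_window, trace = trace, fs = fs,
                 pre_ms = pre_ms, post_ms = post_ms)
  wins <- wins[!vapply(wins, is.null, logical(1))]
  if (length(wins) == 0L) stop("no spike window with full support")
  colMeans(do.call(rbind, wins))
}
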