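#' Firing-rate histogram of a spike train
#'
#' Counts spikes in half-open bins `[i*bin, (i+1)*bin)` of width
#' `bin_ms` (default 50 ms) over `[0, duration)`.
#'
#' @param times Spike times in seconds (or sample indices with
#'   `fs` supplied), all within `[0, duration)`.
#' @param duration Total duration, seconds.
#' @param bin_ms Bin width, ms.
#' @param fs If given, `times` are 1-based sample indices converted via
#'   `(times - 1) / fs`.
#' @return Integer vector of counts; sums to `length(times)`.
#' @export
rate_histogram <- function(times, duration, bin_ms = 50, fs = NULL) {
  if (!is.null(fs)) times <- (as.numeric(times) - 1) / fs
  if (any(times < 0)) stop("negative spike times")
  if (any(times >= duration)) stop("spike times must lie within [0, duration)")
  bin <- bin_ms / 1000
  n_bins <- ceiling(duration / bin)
  counts <- tabulate(floor(times / bin) + 1L, nbins = n_bins)
  counts
}

#' Pearson correlation matrix of binned spike trains
#'
#' Functional-connectivity summary: each electrode's spike train is
#' binned into a rate histogram ([rate_histogram()], default 50 ms
#' bins) and the Pearson correlation coefficient is computed between
#' the histograms of every electrode pair. Electrodes with a constant
#' histogram (no spikes, or uniform) have undefined coefficients; those
#' entries are set to `NA` and flagged.
#'
#' @param trains List of spike-time vectors (seconds, or samples with
#'   `fs`).
#' @param duration Duration, seconds.
#' @param bin_ms Bin width, ms.
#' @param fs Optional sampling rate when `trains` hold sample indices.
#' @return A symmetric matrix with unit diagonal (class
#'   `"correlation_matrix"`), attribute `"bin_ms"`; `NA` marks
#'   undefined pairs.
#' @export
correlation_matrix <- function(trains, duration, bin_ms = 50, fs = NULL) {
  K <- length(trains)
  if (K < 2L) stop("need at least two electrodes")
  H <- vapply(trains, rate_histogram, integer(ceiling(duration / (bin_ms / 1000))),
              duration = duration, bin_ms = bin_ms, fs = fs)
  if (nrow(H) < 2L) stop("need at least two bins")
  sds <- apply(H, 2, stats::sd)
  R <- suppressWarnings(stats::cor(H))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  structure(R, class = c("correlation_matrix", "matrix"),
            bin_ms = bin_ms)
}

#' PCA + K-means spike sorting
#'
#' Centres the spike waveforms (no variance scaling: amplitude is
#' informative), projects them onto the first two principal
#' components, and clusters the (PC1, PC2) scores with K-means
#' (`k` of 2 or 3 by convention; Hartigan-Wong with multiple restarts
#' under a fixed seed).
#'
#' @param waveforms Matrix, one spike waveform per row (equal lengths).
#' @param k Number of clusters (>= 2; 2 or 3 in typical use).
#' @param seed Seed making the clustering deterministic.
#' @return An object of class `"sorting_result"`: list with
#'   `pc_scores` (n x 2), `labels` (1..k), `centers`, `k`, and
#'   `degenerate` (`TRUE` when the waveforms have zero variance).
#' @export
sort_spikes <- function(waveforms, k = 2, seed = 1L) {
  waveforms <- as.matrix(waveforms)
  n <- nrow(waveforms)
  if (k > n) stop("k must not exceed the number of spikes")
  ctr <- scale(waveforms, center = TRUE, scale = FALSE)
  sv <- La.svd(ctr, nu = 0, nv = 2)
  degenerate <- sv$d[1] < 1e-12
  if (degenerate) {
    warning("zero-variance waveforms: clustering is degenerate")
    scores <- matrix(0, n, 2)
    labels <- rep(1L, n)
    centers <- matrix(0, k, 2)
  } else {
    scores <- ctr %*% t(sv$vt)[, 1:2, drop = FALSE]
    km <- with_seed(seed, stats::kmeans(scores, centers = k, nstart = 10))
    labels <- km$cluster
    centers <- km$centers
  }
  colnames(scores) <- c("PC1", "PC2")
  structure(list(pc_scores = scores, labels = as.integer(labels),
                 centers = centers, k = as.integer(k),
                 degenerate = degenerate),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("<sorting_result> %d spike(s) in %d cluster(s)%s\n",
              nrow(x$pc_scores), x$k,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Best-permutation clustering accuracy
#'
#' Agreement fraction between predicted and reference labels, maximised
#' over all relabelings (label identities are arbitrary in clustering).
#' Differing label cardinalities are handled by permuting over the
#' union of labels.
#'
#' @param pred_labels,ref_labels Equal-length label vectors.
#' @return Fraction in `[1/k, 1]`.
#' @export
clustering_accuracy <- function(pred_labels, ref_labels) {
  if (length(pred_labels) != length(ref_labels)) {
    stop("label vectors must have equal length")
  }
  pu <- unique(pred_labels)
  ru <- unique(ref_labels)
  labs <- union(pu, ru)
  best <- 0
  for (pm in perms(labs)) {
    mapped <- pm[match(pred_labels, labs)]
    best <- max(best, mean(mapped == ref_labels))
  }
  best
}

#' Short-time Fourier spectrogram
#'
#' One-sided power spectrogram with a Hamming window. Defaults follow
#' the low-rate LFP analysis convention: 3125 Hz input, 1250-sample
#' window, 1125-sample overlap (125-sample hop = 40 ms). By default the
#' transform length equals the window length; `n_freq` instead requests
#' a fixed number of one-sided bins (transform length
#' `2 * (n_freq - 1)`, with the windowed frame zero-padded or
#' truncated), a compatibility convention for analyses that specify the
#' bin count directly.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz (default 3125).
#' @param window Window length in samples (default 1250).
#' @param overlap Overlap between consecutive windows, samples
#'   (default 1125; must be < `window`).
#' @param n_freq Optional number of one-sided frequency bins.
#' @return List with `power` (frequency x time matrix of one-sided
#'   power `|X|^2`), `freq` (Hz), `time` (s, frame centres), `window`,
#'   `hop`.
#' @export
stft_spectrogram <- function(x, fs = 3125, window = 1250, overlap = 1125,
                             n_freq = NULL) {
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (overlap >= window) stop("overlap must be smaller than the window")
  if (length(x) < window) stop("signal shorter than the window")
  hop <- window - overlap
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(window - 1)) / (window - 1))
  nfft <- if (is.null(n_freq)) window else 2L * (as.integer(n_freq) - 1L)
  nbins <- nfft %/% 2L + 1L
  starts <- seq.int(1L, length(x) - window + 1L, by = hop)
  P <- matrix(0, nbins, length(starts))
  for (i in seq_along(starts)) {
    frame <- x[starts[i]:(starts[i] + window - 1L)] * ham
    if (nfft > window) {
      frame <- c(frame, numeric(nfft - window))
    } else if (nfft < window) {
      frame <- frame[seq_len(nfft)]
    }
    X <- stats::fft(frame)
    P[, i] <- Mod(X[seq_len(nbins)])^2
  }
  list(power = P,
       freq = (seq_len(nbins) - 1L) * fs / nfft,
       time = (starts - 1L + window / 2) / fs,
       window = window, hop = hop)
}
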