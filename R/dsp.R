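#' Split a wideband trace into low-pass and high-pass bands
#'
#' Separates an extracellular voltage trace into a local-field-potential
#' band (low-pass) and a spike band (high-pass) around a common cutoff.
#' The default is the zero-phase fourth-order Butterworth split used for
#' building training pairs: the filter is run forward and backward, so the
#' effective magnitude response is \eqn{|H(\omega)|^2} with zero phase
#' delay, and the low- and high-pass outputs are power-complementary
#' (their sum reproduces the input away from the trace edges).
#'
#' `mode = "ideal"` instead zeroes Fourier coefficients above (low-pass)
#' or at-and-below (high-pass) the cutoff, giving a brick-wall partition
#' of the spectrum whose two outputs sum to the input exactly. This is
#' the ablation switch for studying how much reconstruction relies on
#' residual above-cutoff energy leaking through a realisable filter.
#'
#' @param x Numeric vector, voltage trace in microvolts.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 200).
#' @param order Butterworth order (default 4). Ignored for `mode = "ideal"`.
#' @param mode `"zero_phase"` (forward-backward Butterworth, default) or
#'   `"ideal"` (brick-wall FFT partition).
#' @return A list with components `lpf` and `hpf`, each the length of `x`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, by = 1 / 2500))
#' bands <- butter_split(x, fs = 2500)
#' max(abs(bands$lpf + bands$hpf - x))
#' @export
butter_split <- function(x, fs, cutoff = 200, order = 4,
                         mode = c("zero_phase", "ideal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  if (fs <= 0) stop("fs must be positive")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and fs/2")
  }
  if (order < 1) stop("order must be >= 1")
  if (length(x) <= 3 * order) stop("signal too short for the filter order")

  if (mode == "ideal") {
    n <- length(x)
    X <- stats::fft(x)
    k <- 0:(n - 1)
    freq <- pmin(k, n - k) * fs / n
    lp <- X
    lp[freq > cutoff] <- 0
    lpf <- Re(stats::fft(lp, inverse = TRUE)) / n
    return(list(lpf = lpf, hpf = x - lpf))
  }

  wc <- cutoff / (fs / 2)
  blp <- signal::butter(order, wc, type = "low")
  bhp <- signal::butter(order, wc, type = "high")
  # transient length scales with fs/cutoff; pad generously so interior
  # samples see steady state
  padlen <- min(length(x) - 1L, max(9L * order, ceiling(12 * fs / cutoff)))
  list(
    lpf = zero_phase_filter(blp$b, blp$a, x, padlen),
    hpf = zero_phase_filter(bhp$b, bhp$a, x, padlen)
  )
}

# Direct-form IIR filter with zero initial conditions: FIR stage through
# stats::filter(convolution), AR stage through stats::filter(recursive).
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  v <- v[nb:length(v)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

# Forward-backward filtering with odd (anti-symmetric) edge extension.
zero_phase_filter <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Subsample a trace by an integer factor
#'
#' Keeps every `M`-th sample starting at the first, i.e. `x[1], x[1+M],
#' ...`. No anti-alias filtering is applied here: the pipeline order is
#' filter first, then subsample, so the preceding low-pass stage is the
#' only band limitation (deliberately leaving residual above-cutoff
#' energy from a realisable filter in place).
#'
#' @param x Numeric vector.
#' @param M Positive integer subsampling factor.
#' @return Numeric vector of length `ceiling(length(x) / M)`.
#' @export
downsample_signal <- function(x, M) {
  if (length(M) != 1L || !is.finite(M) || M < 1 || M != round(M)) {
    stop("M must be a positive integer")
  }
  M <- as.integer(M)
  if (M == 1L) return(as.numeric(x))
  as.numeric(x)[seq.int(1L, length(x), by = M)]
}

#' Fourier-method band-limited interpolation
#'
#' Upsamples a trace by an integer factor `L` by zero-padding its
#' discrete Fourier transform (splitting the Nyquist coefficient for
#' even-length inputs). The interpolant is the unique trigonometric
#' polynomial through the samples, so the original samples are
#' reproduced exactly at stride `L` for any input.
#'
#' @param x Numeric vector (length >= 1).
#' @param L Positive integer interpolation factor.
#' @return Numeric vector of length `L * length(x)`.
#' @examples
#' x <- sin(2 * pi * 3 * (0:63) / 64)
#' y <- fourier_resample(x, 8)
#' max(abs(y[seq(1, length(y), by = 8)] - x))
#' @export
fourier_resample <- function(x, L) {
  if (length(x) == 0L) stop("empty signal")
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != round(L)) {
    stop("L must be a positive integer")
  }
  L <- as.integer(L)
  x <- as.numeric(x)
  if (L == 1L) return(x)
  n <- length(x)
  if (n == 1L) return(rep(x, L))
  X <- stats::fft(x)
  m <- n * L
  Y <- complex(m)
  if (n %% 2L == 0L) {
    nh <- n %/% 2L
    Y[1:nh] <- X[1:nh]
    Y[nh + 1L] <- X[nh + 1L] / 2
    Y[m - nh + 1L] <- X[nh + 1L] / 2
    if (nh > 1L) Y[(m - nh + 2L):m] <- X[(nh + 2L):n]
  } else {
    nh <- (n - 1L) %/% 2L
    Y[1:(nh + 1L)] <- X[1:(nh + 1L)]
    Y[(m - nh + 1L):m] <- X[(nh + 2L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Robust noise standard deviation of a spike-band trace
#'
#' Estimates the background-noise SD of a high-pass trace as
#' `median(|x|) / 0.6745`, the median-absolute-deviation estimator that
#' is consistent for Gaussian noise and nearly insensitive to sparse
#' large-amplitude spikes. This is the sigma referenced by the -6 SD
#' detection threshold and the -5 SD normalisation mask.
#'
#' @param x Numeric vector (high-pass band), microvolts.
#' @return Estimated noise SD (same units as `x`). Zero for an all-zero
#'   trace; threshold-based consumers reject sigma = 0.
#' @export
noise_sigma <- function(x) {
  stats::median(abs(as.numeric(x))) / 0.6745
}

#' Normalise an (interpolated low-pass, high-pass) training pair
#'
#' Both members of a pair are divided by a single per-electrode scale:
#' the maximum absolute value of the high-pass trace over its
#' *background-noise* samples. Background is defined deterministically
#' as every sample farther than `mask_ms` (default 2 ms) from any
#' crossing of -5 sigma, with sigma from [noise_sigma()]; this excludes
#' spikes so the scale does not depend on spike amplitude. Multiplying
#' both sequences by `scale` recovers microvolts.
#'
#' @param lpf_interp Interpolated low-pass input sequence (same length
#'   as `hpf`).
#' @param hpf High-pass ground-truth sequence, microvolts.
#' @param fs Sampling rate in Hz.
#' @param sigma Optional noise SD in microvolts; estimated from `hpf`
#'   when `NULL`.
#' @param mask_ms Half-width of the exclusion window around -5 sigma
#'   crossings, in ms.
#' @param electrode_id Optional identifier carried along.
#' @return An object of class `"normalized_pair"`: a list with
#'   `lpf_input`, `hpf_gt`, `scale` (microvolts), `sigma` (microvolts),
#'   `fs`, `electrode_id`.
#' @export
normalize_pair <- function(lpf_interp, hpf, fs, sigma = NULL,
                           mask_ms = 2, electrode_id = NULL) {
  lpf_interp <- as.numeric(lpf_interp)
  hpf <- as.numeric(hpf)
  if (length(lpf_interp) != length(hpf)) {
    stop("lpf_interp and hpf must have equal length")
  }
  if (is.null(sigma)) sigma <- noise_sigma(hpf)
  n <- length(hpf)
  covered <- rep(FALSE, n)
  if (sigma > 0) {
    cross <- which(hpf < -5 * sigma)
    if (length(cross) > 0L) {
      half <- as.integer(round(mask_ms / 1000 * fs))
      starts <- pmax(1L, cross - half)
      ends <- pmin(n, cross + half)
      d <- tabulate(starts, n + 1L) - tabulate(ends + 1L, n + 1L)
      covered <- cumsum(d)[1:n] > 0
    }
  }
  if (all(covered)) stop("no background-noise samples available for scaling")
  scale <- max(abs(hpf[!covered]))
  if (scale == 0) stop("background scale is zero; cannot normalise")
  structure(
    list(
      lpf_input = lpf_interp / scale,
      hpf_gt = hpf / scale,
      scale = scale,
      sigma = sigma,
      fs = fs,
      electrode_id = electrode_id
    ),
    class = "normalized_pair"
  )
}

#' @export
print.normalized_pair <- function(x, ...) {
  cat(sprintf(
    "<normalized_pair> electrode %s: %d samples @ %g Hz, scale %.3f uV, sigma %.3f uV\n",
    if (is.null(x$electrode_id)) "?" else as.character(x$electrode_id),
    length(x$hpf_gt), x$fs, x$scale, x$sigma
  ))
  invisible(x)
}

#' Preprocess one electrode into a normalised training pair
#'
#' Runs the full preprocessing chain on a wideband trace: band split at
#' `cutoff`, subsample the low band by `M`, re-upsample by `L` (equal to
#' `M` by default so input and ground truth share one time base) with
#' the Fourier method, trim to the original length, and normalise the
#' pair by the high-band background-noise maximum.
#'
#' @param x Wideband trace, microvolts.
#' @param fs Sampling rate, Hz.
#' @param M Integer subsampling factor (1, 8, 16 and 25 are the factors
#'   studied; any positive integer is accepted).
#' @param L Interpolation factor, defaults to `M`.
#' @inheritParams butter_split
#' @param electrode_id Optional identifier carried into the pair.
#' @return A `"normalized_pair"` (see [normalize_pair()]) with
#'   attributes `M`, `L`, `cutoff`, `mode` attached.
#' @export
preprocess_channel <- function(x, fs, M, L = M, cutoff = 200, order = 4,
                               mode = c("zero_phase", "ideal"),
                               electrode_id = NULL) {
  mode <- match.arg(mode)
  bands <- butter_split(x, fs, cutoff = cutoff, order = order, mode = mode)
  ds <- downsample_signal(bands$lpf, M)
  up <- fourier_resample(ds, L)
  n <- length(x)
  if (length(up) < n) stop("interpolated input shorter than trace")
  pair <- normalize_pair(up[1:n], bands$hpf, fs, electrode_id = electrode_id)
  attr(pair, "M") <- as.integer(M)
  attr(pair, "L") <- as.integer(L)
  attr(pair, "cutoff") <- cutoff
  attr(pair, "mode") <- mode
  pair
}

#' Preprocess every channel of a recording
#'
#' @param rec A `"recording"` object (see [simulate_recording()] or
#'   [read_recording()]).
#' @inheritParams preprocess_channel
#' @return A list of `"normalized_pair"` objects, one per channel.
#' @export
preprocess_recording <- function(rec, M, L = M, cutoff = 200, order = 4,
                                 mode = c("zero_phase", "ideal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "recording"))
  lapply(seq_len(nrow(rec$signal)), function(ch) {
    preprocess_channel(rec$signal[ch, ], rec$fs, M = M, L = L,
                       cutoff = cutoff, order = order, mode = mode,
                       electrode_id = rec$channel_ids[ch])
  })
}
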