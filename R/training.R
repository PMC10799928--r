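#' Training control parameters
#'
#' @param epochs Training epochs.
#' @param steps_per_epoch Optimiser steps per epoch. Default scales to
#'   the data: total usable windows divided by `B`, capped at 100.
#' @param B Batch size (must be even when `sfws = TRUE`).
#' @param W Window length in samples (must equal the model's `T`).
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates. The defaults are the
#'   conventional (0.9, 0.999); short small-model runs converge faster
#'   with `beta2 = 0.99`.
#' @param clip Global gradient-norm clipping threshold (`Inf` disables
#'   clipping). Clipping suppresses the occasional unstable step in
#'   short high-learning-rate runs.
#' @param stride Sliding hop used at reconstruction time.
#' @param sfws Spike-focused window selection: when `TRUE`, the first
#'   half of every batch is anchored on a ground-truth spike peak with
#'   uniform jitter; when `FALSE` (ablation) all windows are uniform
#'   random.
#' @param seed Seed for batch sampling (and weight init in
#'   [spike_sr()]).
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(epochs = 200, steps_per_epoch = NULL, B = 16,
                          W = 128, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                          clip = Inf, stride = 64, sfws = TRUE, seed = 1L) {
  B <- as.integer(B); W <- as.integer(W)
  if (sfws && B %% 2L != 0L) stop("B must be even when sfws is on")
  if (stride > W) stop("stride must not exceed W")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    stop("beta1 and beta2 must lie in (0, 1)")
  }
  structure(
    list(epochs = as.integer(epochs), steps_per_epoch = steps_per_epoch,
         B = B, W = W, lr = lr, beta1 = beta1, beta2 = beta2, clip = clip,
         stride = as.integer(stride), sfws = isTRUE(sfws),
         seed = as.integer(seed)),
    class = "train_control"
  )
}

#' Index ground-truth spike peaks across electrodes
#'
#' Runs threshold detection (see [detect_spikes()]) on the normalised
#' high-pass ground-truth trace of every electrode and records the peak
#' positions that spike-focused window selection anchors on.
#'
#' @param pairs List of `"normalized_pair"` objects.
#' @param k_sigma,dead_time_ms Detection parameters.
#' @return An object of class `"spike_index"`: list with `peaks` (per
#'   electrode integer vectors of 1-based peak samples), `n_samples`,
#'   `sigma` (per electrode, normalised scale) and `K`.
#' @export
index_spikes <- function(pairs, k_sigma = -6, dead_time_ms = 1) {
  stopifnot(length(pairs) > 0L)
  peaks <- vector("list", length(pairs))
  n_samples <- integer(length(pairs))
  sigmas <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    stopifnot(inherits(pr, "normalized_pair"))
    sig <- noise_sigma(pr$hpf_gt)
    if (sig <= 0) stop("noise sigma is zero; cannot index spikes")
    peaks[[k]] <- detect_spikes(pr$hpf_gt, sig, pr$fs,
                                k_sigma = k_sigma,
                                dead_time_ms = dead_time_ms)
    n_samples[k] <- length(pr$hpf_gt)
    sigmas[k] <- sig
  }
  structure(list(peaks = peaks, n_samples = n_samples, sigma = sigmas,
                 K = length(pairs)),
            class = "spike_index")
}

#' @export
print.spike_index <- function(x, ...) {
  cat(sprintf("<spike_index> %d electrode(s), %s spikes\n",
              x$K, format(sum(lengths(x$peaks)), big.mark = ",")))
  invisible(x)
}

#' Sample one training batch with spike-focused window selection
#'
#' With `sfws` on, the first `B/2` windows are anchored: an electrode
#' (uniform among electrodes with spikes) and one of its spikes are
#' drawn, a jitter `tau` is drawn uniformly from the integers in
#' `(-W/2, W/2]`, and the window covers samples
#' `[n + tau - W/2, n + tau + W/2)` — which always contains the peak
#' `n`, at position `W/2 - tau` (0-based) inside the window. The
#' remaining windows start uniformly at random anywhere in any
#' electrode. Windows that would cross a trace end are redrawn. Uses
#' the current RNG state; seed externally for reproducibility.
#'
#' @param pairs List of `"normalized_pair"` objects.
#' @param index The matching [index_spikes()] result.
#' @param control A [train_control()].
#' @return List with `input` and `gt` (`B x W` matrices), `windows` (a
#'   data frame with one row per window: `electrode`, `start` — the
#'   1-based first sample of the window), and `anchors` (data frame for
#'   the anchored half: `electrode`, `spike`, `tau`, `peak_pos` —
#'   1-based peak position within the window).
#' @export
sample_sfws_batch <- function(pairs, index, control) {
  B <- control$B; W <- control$W
  K <- index$K
  if (any(index$n_samples < W)) stop("trace shorter than the window length")
  inp <- matrix(0, B, W)
  gt <- matrix(0, B, W)
  win_electrode <- integer(B)
  win_start <- integer(B)
  n_anchor <- if (control$sfws) B %/% 2L else 0L
  anchors <- NULL
  if (n_anchor > 0L) {
    with_spikes <- which(lengths(index$peaks) > 0L)
    if (length(with_spikes) == 0L) stop("no spikes available for SFWS")
    rows <- vector("list", n_anchor)
    for (j in seq_len(n_anchor)) {
      repeat {
        k <- with_spikes[sample.int(length(with_spikes), 1L)]
        i <- sample.int(length(index$peaks[[k]]), 1L)
        tau <- sample.int(W, 1L) - W %/% 2L      # integers in (-W/2, W/2]
        n0 <- index$peaks[[k]][i]
        st <- n0 + tau - W %/% 2L                 # 1-based window start
        if (st >= 1L && st + W - 1L <= index$n_samples[k]) break
      }
      idx <- st:(st + W - 1L)
      inp[j, ] <- pairs[[k]]$lpf_input[idx]
      gt[j, ] <- pairs[[k]]$hpf_gt[idx]
      win_electrode[j] <- k
      win_start[j] <- st
      rows[[j]] <- data.frame(electrode = k, spike = i, tau = tau,
                              peak_pos = n0 - st + 1L)
    }
    anchors <- do.call(rbind, rows)
  }
  for (j in seq.int(n_anchor + 1L, B)) {
    k <- sample.int(K, 1L)
    st <- sample.int(index$n_samples[k] - W + 1L, 1L)
    idx <- st:(st + W - 1L)
    inp[j, ] <- pairs[[k]]$lpf_input[idx]
    gt[j, ] <- pairs[[k]]$hpf_gt[idx]
    win_electrode[j] <- k
    win_start[j] <- st
  }
  list(input = inp, gt = gt,
       windows = data.frame(electrode = win_electrode, start = win_start),
       anchors = anchors)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    s <- max_norm / total
    grads <- lapply(grads, function(g) g * s)
  }
  grads
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train a reconstruction network on normalised signal pairs
#'
#' Minimises the mean squared error between the network output on
#' interpolated low-pass windows and the high-pass ground-truth
#' windows, with Adam at a fixed learning rate, sampling batches with
#' (or without) spike-focused window selection. Fully deterministic
#' under `control$seed` on a single thread.
#'
#' @param net A `"swin1d_net"` with `config$T == control$W`.
#' @param pairs List of `"normalized_pair"` training electrodes.
#' @param control A [train_control()].
#' @param index Optional precomputed [index_spikes()].
#' @return List with the trained `net` and `history`, a data frame of
#'   `step`, `epoch`, `loss` (per optimiser step).
#' @export
train_network <- function(net, pairs, control, index = NULL) {
  stopifnot(inherits(net, "swin1d_net"), inherits(control, "train_control"))
  cfg <- net$config
  if (cfg$T != control$W) stop("control$W must equal the model input length T")
  if (is.null(index)) index <- index_spikes(pairs)
  spe <- control$steps_per_epoch
  if (is.null(spe)) {
    total_windows <- sum(pmax(index$n_samples - control$W + 1L, 0L)) %/% control$W
    spe <- max(1L, min(100L, total_windows %/% control$B))
  }
  spe <- as.integer(spe)
  geoms <- net_geoms(cfg, control$B)
  params <- net$params
  state <- adam_init(params)
  losses <- numeric(control$epochs * spe)
  with_seed(control$seed, {
    step <- 0L
    for (ep in seq_len(control$epochs)) {
      for (it in seq_len(spe)) {
        step <- step + 1L
        batch <- sample_sfws_batch(pairs, index, control)
        X <- matrix(as.vector(t(batch$input)), ncol = 1)
        Y <- matrix(as.vector(t(batch$gt)), ncol = 1)
        fw <- trunk_forward(params, cfg, X, geoms, keep_cache = TRUE)
        err <- fw$out - Y
        loss <- mean(err * err)
        if (!is.finite(loss)) {
          stop(sprintf(
            "non-finite loss at epoch %d step %d (last finite loss: %g)",
            ep, it, if (step > 1L) losses[step - 1L] else NA_real_))
        }
        losses[step] <- loss
        grads <- clip_grads(trunk_backward(params, cfg, fw$cache,
                                           2 * err / length(err)),
                            control$clip)
        upd <- adam_step(params, grads, state, control$lr,
                         beta1 = control$beta1, beta2 = control$beta2)
        params <- upd$params
        state <- upd$state
      }
    }
  })
  net$params <- params
  history <- data.frame(
    step = seq_along(losses),
    epoch = rep(seq_len(control$epochs), each = spe),
    loss = losses
  )
  list(net = net, history = history)
}

#' Reconstruct a full trace with a sliding window
#'
#' Presents consecutive length-`W` windows at hop `stride` to the
#' network and merges overlapping predictions by a centre-weighted
#' (raised-cosine) sample-wise average: a window's prediction counts
#' most near its centre and least at its edges, where the attention
#' context is one-sided and reconstruction is weakest. Weights are
#' renormalised by their accumulated sum, so the merge is exact for
#' identical overlapping predictions at any stride. The last window is
#' right-aligned to the trace end so every sample is covered without
#' zero padding; output length equals input length.
#'
#' @param net A `"swin1d_net"`, or (for testing) a function mapping a
#'   windows matrix to a predictions matrix.
#' @param x Numeric trace (normalised interpolated low-pass input), at
#'   least one window long.
#' @param stride Hop between window starts, in samples.
#' @param W Window length; defaults to the network's `T`.
#' @param chunk Number of windows evaluated per batched forward pass.
#' @return Numeric reconstruction, same length as `x`.
#' @export
reconstruct_sequence <- function(net, x, stride = 64, W = NULL, chunk = 128L) {
  if (is.null(W)) {
    if (!inherits(net, "swin1d_net")) stop("W is required for a stub network")
    W <- net$config$T
  }
  n <- length(x)
  if (n < W) stop("trace shorter than the window length")
  starts <- seq.int(1L, n - W + 1L, by = stride)
  if (starts[length(starts)] != n - W + 1L) starts <- c(starts, n - W + 1L)
  acc <- numeric(n)
  cnt <- numeric(n)
  idx_tpl <- 0:(W - 1L)
  # raised-cosine taper with a floor, so trace ends (covered by a
  # single window edge) keep nonzero weight
  wgt <- 0.05 + 0.95 * sin(pi * (idx_tpl + 0.5) / W)^2
  for (blk in split(starts, ceiling(seq_along(starts) / chunk))) {
    Wm <- matrix(0, length(blk), W)
    for (i in seq_along(blk)) Wm[i, ] <- x[blk[i] + idx_tpl]
    P <- if (is.function(net)) net(Wm) else forward_window(net, Wm)
    for (i in seq_along(blk)) {
      rng <- blk[i] + idx_tpl
      acc[rng] <- acc[rng] + P[i, ] * wgt
      cnt[rng] <- cnt[rng] + wgt
    }
  }
  acc / cnt
}
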