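#' Fit a spike-reconstruction model to preprocessed recordings
#'
#' The main modelling entry point. Takes normalised training pairs
#' (interpolated low-pass input, high-pass ground truth — see
#' [preprocess_recording()]), builds the 1D window-attention network
#' and trains it with mean-squared-error loss, Adam, and spike-focused
#' window selection. Returns a fitted-model object with the usual
#' accessor methods (`print`, `summary`, `coef`, `predict`, `fitted`,
#' `residuals`, `plot`).
#'
#' @param pairs A list of `"normalized_pair"` objects (or a single
#'   pair).
#' @param model A [swin1d_config()]; its `T` must equal `control$W`.
#' @param control A [train_control()].
#' @return An object of class `"spike_sr"`: list with `network`,
#'   `model`, `control`, `history` (per-step loss), `electrodes`
#'   (ids and scales of the training pairs) and `call`.
#' @examples
#' \donttest{
#' sim <- simulate_recording(synth_config(n_channels = 2, duration = 4))
#' pairs <- preprocess_recording(sim$recording, M = 8)
#' fit <- spike_sr(pairs,
#'                 model = swin1d_config(T = 128, C = 8, n_rstb = 1,
#'                                       n_stl = 2, heads = 2),
#'                 control = train_control(epochs = 2, steps_per_epoch = 5))
#' print(fit)
#' rec <- predict(fit, pairs[[1]])
#' }
#' @export
spike_sr <- function(pairs, model = swin1d_config(),
                     control = train_control()) {
  if (inherits(pairs, "normalized_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) > 0L,
            all(vapply(pairs, inherits, logical(1), "normalized_pair")))
  net <- build_spk_model(model, seed = control$seed)
  tr <- train_network(net, pairs, control)
  structure(
    list(
      network = tr$net,
      model = model,
      control = control,
      history = tr$history,
      electrodes = data.frame(
        electrode = seq_along(pairs),
        id = vapply(pairs, function(p) {
          if (is.null(p$electrode_id)) NA_character_ else as.character(p$electrode_id)
        }, character(1)),
        scale = vapply(pairs, function(p) p$scale, numeric(1))
      ),
      pairs = pairs,
      call = match.call()
    ),
    class = "spike_sr"
  )
}

#' @export
print.spike_sr <- function(x, ...) {
  m <- x$model
  cat("Spike-reconstruction model (1D shifted-window attention)\n")
  cat(sprintf("  network: T=%d C=%d, %d x %d layers, %s parameters\n",
              m$T, m$C, m$n_rstb, m$n_stl,
              format(count_params(x$network), big.mark = ",")))
  cat(sprintf("  training: %d electrode(s), %d steps, SFWS %s, final loss %.4g\n",
              nrow(x$electrodes), nrow(x$history),
              if (x$control$sfws) "on" else "off",
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.spike_sr <- function(object, ...) {
  h <- object$history
  per_epoch <- tapply(h$loss, h$epoch, mean)
  out <- list(
    n_parameters = count_params(object$network),
    n_electrodes = nrow(object$electrodes),
    epochs = object$control$epochs,
    steps = nrow(h),
    sfws = object$control$sfws,
    initial_loss = unname(per_epoch[1]),
    final_loss = unname(per_epoch[length(per_epoch)]),
    loss_per_epoch = as.numeric(per_epoch)
  )
  class(out) <- "summary.spike_sr"
  out
}

#' @export
print.summary.spike_sr <- function(x, ...) {
  cat(sprintf(
    "spike_sr fit: %s parameters, %d electrode(s), %d epochs (%d steps), SFWS %s\n",
    format(x$n_parameters, big.mark = ","), x$n_electrodes, x$epochs,
    x$steps, if (x$sfws) "on" else "off"))
  cat(sprintf("  mean epoch loss: %.4g (first) -> %.4g (last)\n",
              x$initial_loss, x$final_loss))
  invisible(x)
}

#' @export
coef.spike_sr <- function(object, ...) {
  object$network$params
}

#' Reconstruct traces with a fitted model
#'
#' @param object A fitted `"spike_sr"`.
#' @param newdata A numeric trace (normalised interpolated low-pass
#'   input), a `"normalized_pair"`, or a list of pairs.
#' @param stride Sliding hop; defaults to the fit's control.
#' @param ... Unused.
#' @return A numeric reconstruction on the normalised scale (multiply
#'   by the pair's `scale` for microvolts), or a list of them.
#' @export
predict.spike_sr <- function(object, newdata, stride = NULL, ...) {
  if (is.null(stride)) stride <- object$control$stride
  one <- function(x) {
    if (inherits(x, "normalized_pair")) x <- x$lpf_input
    reconstruct_sequence(object$network, x, stride = stride)
  }
  if (is.list(newdata) && !inherits(newdata, "normalized_pair")) {
    lapply(newdata, one)
  } else {
    one(newdata)
  }
}

#' @export
fitted.spike_sr <- function(object, ...) {
  predict(object, object$pairs)
}

#' @export
residuals.spike_sr <- function(object, ...) {
  fits <- fitted(object)
  Map(function(p, f) p$hpf_gt - f, object$pairs, fits)
}

#' @export
plot.spike_sr <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$loss, type = "l", log = "y",
                 xlab = "optimiser step", ylab = "MSE loss (log scale)",
                 main = "Training loss", ...)
  per_epoch <- tapply(h$loss, h$epoch, mean)
  steps_mid <- tapply(h$step, h$epoch, stats::median)
  graphics::lines(steps_mid, per_epoch, col = "red", lwd = 2)
  invisible(x)
}

#' Spike-level evaluation of a reconstruction against ground truth
#'
#' Detects spikes in the ground-truth and reconstructed traces at
#' `k_sigma` times the ground-truth background noise, matches the two
#' trains within `tolerance_us`, and reports hit rate, precision, mean
#' matched-spike waveform NRMSE and mean signed time delay.
#'
#' @param gt High-pass ground-truth trace (normalised or microvolts).
#' @param recon Reconstructed trace on the same scale.
#' @param fs Sampling rate, Hz.
#' @param k_sigma Detection threshold multiple (default -6).
#' @param tolerance_us Matching tolerance (default 500).
#' @return List with `hit_rate`, `precision`, `nrmse` (mean over
#'   matched spikes), `mean_delay_us`, `n_gt`, `n_rec`, and the full
#'   `match` object.
#' @export
evaluate_reconstruction <- function(gt, recon, fs, k_sigma = -6,
                                    tolerance_us = 500) {
  sig <- noise_sigma(gt)
  gt_t <- detect_spikes(gt, sig, fs, k_sigma = k_sigma)
  rec_t <- detect_spikes(recon, sig, fs, k_sigma = k_sigma)
  m <- match_trains(gt_t, rec_t, fs, tolerance_us = tolerance_us)
  nr <- if (nrow(m$pairs) > 0L) {
    suppressWarnings(waveform_nrmse(gt, recon, m$pairs[, "gt"], fs)$mean)
  } else NaN
  list(
    hit_rate = m$hit_rate,
    precision = m$precision,
    nrmse = nr,
    mean_delay_us = if (length(m$delays_us)) mean(m$delays_us) else NaN,
    n_gt = length(gt_t),
    n_rec = length(rec_t),
    match = m
  )
}
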