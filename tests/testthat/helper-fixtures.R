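# Shared in-code fixtures: everything is generated at test time.

# A trace of Gaussian noise with spike templates deposited at known
# peaks; returns the trace, the peak indices and the template.
noisy_spike_trace <- function(n = 25000, fs = 25000, peaks = NULL,
                              amplitude = -100, noise_sd = 10, seed = 1) {
  tpl <- make_templates(list(list(amplitude = amplitude, width_ms = 1,
                                  biphasic_ratio = 0.5)), fs)[[1]]
  if (is.null(peaks)) peaks <- as.integer(seq(2000, n - 2000, length.out = 5))
  x <- spikesr:::with_seed(seed, stats::rnorm(n, sd = noise_sd))
  for (p in peaks) {
    idx <- (p - tpl$peak + 1L):(p - tpl$peak + length(tpl$wave))
    x[idx] <- x[idx] + tpl$wave
  }
  list(trace = x, peaks = peaks, template = tpl, fs = fs)
}

# Brute-force optimal one-to-one spike matching by enumeration: returns
# max number of matched pairs within tolerance (samples).
brute_force_matches <- function(gt, rec, tol) {
  best <- 0L
  n <- length(gt)
  m <- length(rec)
  if (n == 0L || m == 0L) return(0L)
  recurse <- function(i, used, count) {
    if (count + (n - i + 1L) <= best) return()
    if (i > n) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)           # leave gt[i] unmatched
    for (j in seq_len(m)) {
      if (!used[j] && abs(rec[j] - gt[i]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L)
  best
}

# A tiny preprocessed two-electrode pair set for training smoke tests.
tiny_pairs <- function(duration = 6, n_channels = 2, seed = 3, M = 8) {
  sim <- simulate_recording(synth_config(n_channels = n_channels,
                                         duration = duration, seed = seed))
  preprocess_recording(sim$recording, M = M)
}
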