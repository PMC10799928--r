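#' Configuration for synthetic extracellular recordings
#'
#' Bundles every parameter of the synthetic-recording generator. The
#' defaults emulate a spontaneous in vitro culture recording on a
#' planar multielectrode array: 25 kHz sampling, one well-isolated unit
#' per electrode firing tonically at a few Hz with occasional bursts,
#' millisecond-scale biphasic spikes of ~100 microvolt negative peak,
#' slow LFP-band oscillations, and ~10 microvolt white background noise.
#'
#' @param n_channels Number of electrodes.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (default 25000).
#' @param units_per_channel Units (putative neurons) per electrode.
#' @param firing_rate Mean firing rate per unit, Hz.
#' @param burst_prob Probability that a Poisson event expands into a
#'   burst.
#' @param burst_size Number of spikes per burst (including the seed
#'   spike).
#' @param burst_isi_ms Range (min, max) of intra-burst inter-spike
#'   intervals, ms.
#' @param refractory_ms Absolute per-unit refractory period, ms.
#' @param noise_sigma Background noise SD, microvolts.
#' @param pink_noise If `TRUE`, shape the noise with a 1/f filter
#'   instead of leaving it white.
#' @param lfp_components List of `c(freq_hz, amplitude_uv)` sinusoidal
#'   LFP components (random phase each).
#' @param template_params Per-unit list of
#'   `list(amplitude, width_ms, biphasic_ratio)` with `amplitude` the
#'   negative peak in microvolts (< 0). `NULL` spreads amplitudes
#'   -80 to -160 microvolts across units.
#' @param correlation Optional symmetric co-firing probability matrix
#'   (`n_channels` square, entries in \[0, 1\]) used by
#'   [simulate_population()].
#' @param cofire_jitter_ms Jitter applied to the second copy of a shared
#'   event, ms (must be < 5).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_channels = 8, duration = 120, fs = 25000,
                         units_per_channel = 1, firing_rate = 5,
                         burst_prob = 0.2, burst_size = 3,
                         burst_isi_ms = c(4, 10), refractory_ms = 2,
                         noise_sigma = 10, pink_noise = FALSE,
                         lfp_components = list(c(2, 50), c(8, 30), c(30, 10)),
                         template_params = NULL,
                         correlation = NULL, cofire_jitter_ms = 1,
                         seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (firing_rate < 0) stop("firing_rate must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (cofire_jitter_ms >= 5) stop("cofire_jitter_ms must be below 5 ms")
  if (is.null(template_params)) {
    u <- max(1L, as.integer(units_per_channel))
    amps <- if (u == 1L) -100 else seq(-80, -160, length.out = u)
    widths <- if (u == 1L) 1 else seq(0.8, 1.2, length.out = u)
    template_params <- lapply(seq_len(u), function(i) {
      list(amplitude = amps[i], width_ms = widths[i], biphasic_ratio = 0.5)
    })
  }
  for (tp in template_params) {
    if (!is.finite(tp$amplitude)) stop("template amplitude must be finite")
    if (tp$width_ms <= 0) stop("template width must be positive")
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(correlation, t(correlation)))) {
      stop("correlation matrix must be symmetric")
    }
    if (any(correlation < 0 | correlation > 1)) {
      stop("correlation entries must lie in [0, 1]")
    }
  }
  structure(
    list(
      n_channels = as.integer(n_channels), duration = duration, fs = fs,
      units_per_channel = as.integer(units_per_channel),
      firing_rate = firing_rate, burst_prob = burst_prob,
      burst_size = as.integer(burst_size), burst_isi_ms = burst_isi_ms,
      refractory_ms = refractory_ms, noise_sigma = noise_sigma,
      pink_noise = isTRUE(pink_noise), lfp_components = lfp_components,
      template_params = template_params, correlation = correlation,
      cofire_jitter_ms = cofire_jitter_ms, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Evaluate a block with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build biphasic spike templates
#'
#' Constructs one waveform per unit: a sharp negative Gaussian lobe
#' (FWHM = `width_ms`) followed by a broader positive rebound of
#' relative amplitude `biphasic_ratio`, on a finite support of roughly
#' 3-4 ms with smoothly tapered, zero tails. The sample index of the
#' negative peak is recorded so spikes can be deposited peak-aligned.
#'
#' @param template_params Per-unit list of
#'   `list(amplitude, width_ms, biphasic_ratio)`; `amplitude` < 0 is the
#'   negative peak in microvolts.
#' @param fs Sampling rate, Hz.
#' @return A list of templates, each `list(wave, peak)` with `wave` the
#'   waveform in microvolts and `peak` the 1-based index of its global
#'   minimum.
#' @export
make_templates <- function(template_params, fs) {
  if (fs <= 0) stop("fs must be positive")
  lapply(template_params, function(tp) {
    if (tp$width_ms <= 0) stop("template width must be positive")
    A <- -abs(tp$amplitude)
    w <- tp$width_ms / 1000
    r <- tp$biphasic_ratio
    sn <- w / 2.355            # FWHM of the negative lobe = width
    sp <- 1.4 * sn
    t0 <- 3.2 * sn             # negative-peak time from support start
    t1 <- t0 + 0.9 * w         # positive-lobe centre
    t_end <- t1 + 3.2 * sp
    tt <- seq(0, t_end, by = 1 / fs)
    wave <- A * exp(-(tt - t0)^2 / (2 * sn^2)) -
      r * A * exp(-(tt - t1)^2 / (2 * sp^2))
    # cosine taper over the outer 10% so the support ends at exactly zero
    m <- length(wave)
    ne <- max(2L, ceiling(0.1 * m))
    ramp <- 0.5 * (1 - cos(pi * (0:(ne - 1)) / (ne - 1)))
    wave[1:ne] <- wave[1:ne] * ramp
    wave[(m - ne + 1L):m] <- wave[(m - ne + 1L):m] * rev(ramp)
    # the rebound lobe partially fills the trough; rescale so the
    # sampled global minimum equals the requested negative peak
    wave <- wave * (abs(A) / abs(min(wave)))
    list(wave = wave, peak = which.min(wave))
  })
}

# One unit's spike train (sample indices) over n samples: Poisson events,
# optional burst expansion, absolute refractory period.
draw_spike_train <- function(n, fs, rate, burst_prob, burst_size,
                             burst_isi_ms) {
  if (rate <= 0) return(integer(0))
  dur <- n / fs
  n_ev <- stats::rpois(1, rate * dur)
  if (n_ev == 0) return(integer(0))
  ev <- sort(stats::runif(n_ev, 0, dur))
  times <- numeric(0)
  for (t in ev) {
    if (burst_prob > 0 && burst_size > 1 && stats::runif(1) < burst_prob) {
      isis <- stats::runif(burst_size - 1, burst_isi_ms[1], burst_isi_ms[2]) / 1000
      times <- c(times, t + c(0, cumsum(isis)))
    } else {
      times <- c(times, t)
    }
  }
  samp <- sort(unique(as.integer(round(times * fs)) + 1L))
  samp[samp >= 1L & samp <= n]
}

enforce_refractory <- function(samples, refr_samples) {
  if (length(samples) < 2L) return(samples)
  keep <- samples[1L]
  last <- samples[1L]
  for (s in samples[-1L]) {
    if (s - last >= refr_samples) {
      keep <- c(keep, s)
      last <- s
    }
  }
  keep
}

# Deposit templates, add LFP + noise; spikes whose support would cross a
# trace edge are dropped (and reported via the returned spike table).
assemble_recording <- function(config, trains) {
  n <- as.integer(round(config$duration * config$fs))
  K <- config$n_channels
  templates <- make_templates(config$template_params, config$fs)
  clean <- matrix(0, nrow = K, ncol = n)
  rows <- vector("list", 0)
  for (ch in seq_len(K)) {
    for (u in seq_along(trains[[ch]])) {
      tpl <- templates[[((u - 1L) %% length(templates)) + 1L]]
      len <- length(tpl$wave)
      peaks <- trains[[ch]][[u]]
      starts <- peaks - tpl$peak + 1L
      ok <- starts >= 1L & (starts + len - 1L) <= n
      if (any(!ok)) {
        message(sprintf("channel %d unit %d: dropped %d edge spike(s)",
                        ch, u, sum(!ok)))
      }
      peaks <- peaks[ok]
      starts <- starts[ok]
      for (i in seq_along(starts)) {
        idx <- starts[i]:(starts[i] + len - 1L)
        clean[ch, idx] <- clean[ch, idx] + tpl$wave
      }
      if (length(peaks) > 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(channel = ch, unit = u, sample = peaks)
      }
    }
  }
  spikes <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(channel = integer(0), unit = integer(0), sample = integer(0))
  }
  tt <- (0:(n - 1)) / config$fs
  lfp <- matrix(0, nrow = K, ncol = n)
  for (ch in seq_len(K)) {
    acc <- numeric(n)
    for (comp in config$lfp_components) {
      acc <- acc + comp[2] * sin(2 * pi * comp[1] * tt + stats::runif(1, 0, 2 * pi))
    }
    lfp[ch, ] <- acc
  }
  noise <- matrix(stats::rnorm(K * n, sd = config$noise_sigma), nrow = K)
  if (config$pink_noise && config$noise_sigma > 0) {
    for (ch in seq_len(K)) {
      X <- stats::fft(noise[ch, ])
      k <- pmin(0:(n - 1), n - (0:(n - 1)))
      shape <- ifelse(k == 0, 0, 1 / sqrt(pmax(k, 1)))
      y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
      noise[ch, ] <- y * (config$noise_sigma / stats::sd(y))
    }
  }
  rec <- structure(
    list(signal = clean + lfp + noise, fs = config$fs,
         channel_ids = seq_len(K), units = "uV",
         meta = list(source = "synthetic", seed = config$seed,
                     duration = config$duration)),
    class = "recording"
  )
  gt <- structure(
    list(spikes = spikes, clean = clean, lfp = lfp, noise = noise,
         templates = templates, fs = config$fs),
    class = "ground_truth"
  )
  list(recording = rec, ground_truth = gt)
}

#' Simulate a multichannel extracellular recording with known spikes
#'
#' Generates `n_channels` independent electrodes. Each unit fires as a
#' Poisson process at `firing_rate`; with probability `burst_prob` an
#' event expands into a burst of `burst_size` spikes at 4-10 ms
#' intervals (tonic firing plus burst behaviour). An absolute 2 ms
#' refractory period is enforced per unit. Spike templates are deposited
#' peak-aligned into a clean trace, to which sinusoidal LFP components
#' (random phase) and Gaussian background noise are added. All
#' randomness is fixed by `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `recording` (class `"recording"`: `signal`
#'   channels-by-samples matrix in microvolts, `fs`, `channel_ids`) and
#'   `ground_truth` (class `"ground_truth"`: `spikes` data frame with
#'   `channel`, `unit`, `sample` (1-based peak indices), plus `clean`,
#'   `lfp`, `noise` component matrices and the `templates`).
#' @examples
#' sim <- simulate_recording(synth_config(n_channels = 1, duration = 2))
#' dim(sim$recording$signal)
#' head(sim$ground_truth$spikes)
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- as.integer(round(config$duration * config$fs))
    refr <- as.integer(round(config$refractory_ms / 1000 * config$fs))
    trains <- lapply(seq_len(config$n_channels), function(ch) {
      lapply(seq_len(config$units_per_channel), function(u) {
        s <- draw_spike_train(n, config$fs, config$firing_rate,
                              config$burst_prob, config$burst_size,
                              config$burst_isi_ms)
        enforce_refractory(s, refr)
      })
    })
    assemble_recording(config, trains)
  })
}

#' Simulate a population with prescribed pairwise co-firing
#'
#' Builds one unit per channel whose spike trains share events according
#' to `config$correlation`: a pair with co-firing probability `p` draws
#' a common Poisson process of rate `p * firing_rate` whose events
#' appear on both electrodes (the second copy jittered by up to
#' `cofire_jitter_ms`), plus independent residual processes so every
#' channel keeps total rate `firing_rate`. The shared fraction of a
#' channel's events therefore approximates its row of the matrix.
#'
#' @param config A [synth_config()] with a symmetric `correlation`
#'   matrix; row sums of off-diagonal entries must not exceed 1.
#' @return As [simulate_recording()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$correlation
  if (is.null(P)) stop("config$correlation is required")
  K <- config$n_channels
  if (nrow(P) != K) stop("correlation matrix must be n_channels square")
  diag(P) <- 0
  if (any(rowSums(P) > 1 + 1e-12)) {
    stop("off-diagonal row sums of the co-firing matrix must be <= 1")
  }
  with_seed(config$seed, {
    n <- as.integer(round(config$duration * config$fs))
    fs <- config$fs
    rate <- config$firing_rate
    dur <- n / fs
    jit <- config$cofire_jitter_ms / 1000
    times <- vector("list", K)
    for (ch in seq_len(K)) times[[ch]] <- numeric(0)
    for (i in seq_len(K - 1L)) {
      for (j in (i + 1L):K) {
        if (P[i, j] <= 0) next
        m <- stats::rpois(1, P[i, j] * rate * dur)
        if (m == 0) next
        shared <- stats::runif(m, 0, dur)
        times[[i]] <- c(times[[i]], shared)
        jj <- if (jit > 0) stats::runif(m, -jit, jit) else 0
        times[[j]] <- c(times[[j]], shared + jj)
      }
    }
    for (ch in seq_len(K)) {
      resid <- (1 - sum(P[ch, ])) * rate
      if (resid > 0) {
        m <- stats::rpois(1, resid * dur)
        times[[ch]] <- c(times[[ch]], stats::runif(m, 0, dur))
      }
    }
    refr <- as.integer(round(config$refractory_ms / 1000 * fs))
    trains <- lapply(times, function(tv) {
      s <- sort(unique(as.integer(round(tv * fs)) + 1L))
      s <- s[s >= 1L & s <= n]
      list(enforce_refractory(s, refr))
    })
    assemble_recording(config, trains)
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$units))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d spike(s) on %d channel(s)\n",
              nrow(x$spikes), nrow(x$clean)))
  invisible(x)
}
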