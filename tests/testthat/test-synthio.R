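test_that("templates have the requested negative peak and finite support", {
  fs <- 25000
  tpls <- make_templates(list(
    list(amplitude = -100, width_ms = 1, biphasic_ratio = 0.5),
    list(amplitude = -80, width_ms = 1, biphasic_ratio = 0.5),
    list(amplitude = -120, width_ms = 1.2, biphasic_ratio = 0.4)
  ), fs)
  t1 <- tpls[[1]]
  expect_equal(min(t1$wave), -100, tolerance = 1e-6)
  expect_identical(which.min(t1$wave), t1$peak)
  expect_equal(t1$wave[1], 0)
  expect_equal(t1$wave[length(t1$wave)], 0)
  # the global minimum is unique
  expect_identical(sum(t1$wave == min(t1$wave)), 1L)
  # support is a few ms
  expect_lt(length(t1$wave) / fs, 0.006)
  # different units differ
  expect_gt(sqrt(sum((tpls[[2]]$wave - t1$wave)^2)), 0)
  expect_error(make_templates(list(list(amplitude = -50, width_ms = 0,
                                        biphasic_ratio = 0.5)), fs),
               "width")
})

test_that("templates survive a resample round trip", {
  fs <- 25000
  tpl <- make_templates(list(list(amplitude = -100, width_ms = 1,
                                  biphasic_ratio = 0.5)), fs)[[1]]
  up <- fourier_resample(tpl$wave, 2)        # to 50 kHz
  back <- up[seq(1, length(up), by = 2)]     # decimate by 2
  expect_lt(max(abs(back - tpl$wave)) / max(abs(tpl$wave)), 1e-6)
})

test_that("simulation is seed-deterministic and honours unit counts", {
  cfg <- synth_config(n_channels = 2, duration = 2, seed = 99)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$recording$signal, s2$recording$signal)
  expect_identical(s1$ground_truth$spikes, s2$ground_truth$spikes)

  # no units: clean trace is exactly zero and no spikes are listed
  cfg0 <- synth_config(n_channels = 1, duration = 1, units_per_channel = 0,
                       seed = 5)
  s0 <- simulate_recording(cfg0)
  expect_equal(nrow(s0$ground_truth$spikes), 0)
  expect_true(all(s0$ground_truth$clean == 0))
})

test_that("spike counts follow the Poisson law and spikes sit at template minima", {
  cfg <- synth_config(n_channels = 1, duration = 60, firing_rate = 5,
                      burst_prob = 0, noise_sigma = 0,
                      lfp_components = list(), seed = 21)
  sim <- simulate_recording(cfg)
  n <- nrow(sim$ground_truth$spikes)
  expect_gt(n, 300 - 3 * sqrt(300))
  expect_lt(n, 300 + 3 * sqrt(300))
  # every isolated spike peak carries the template minimum in the clean trace
  tpl_min <- min(sim$ground_truth$templates[[1]]$wave)
  peaks <- sim$ground_truth$spikes$sample
  isolated <- peaks[c(TRUE, diff(peaks) > 200) & c(diff(peaks) > 200, TRUE)]
  expect_gt(length(isolated), 50)
  expect_true(all(abs(sim$ground_truth$clean[1, isolated] - tpl_min) < 1e-9))
})

test_that("refractory period separates spikes within each unit", {
  cfg <- synth_config(n_channels = 2, duration = 20, firing_rate = 30,
                      burst_prob = 0.5, seed = 3)
  sim <- simulate_recording(cfg)
  sp <- sim$ground_truth$spikes
  for (ch in unique(sp$channel)) {
    s <- sp$sample[sp$channel == ch]
    expect_true(all(diff(s) >= 0.002 * 25000))
  }
})

test_that("strong spikes on weak noise are almost all recoverable", {
  cfg <- synth_config(n_channels = 1, duration = 30, firing_rate = 5,
                      noise_sigma = 10, seed = 77)   # -100 uV on 10 uV noise
  sim <- simulate_recording(cfg)
  bands <- butter_split(sim$recording$signal[1, ], cfg$fs)
  sig <- noise_sigma(bands$hpf)
  det <- detect_spikes(bands$hpf, sig, cfg$fs)
  m <- match_trains(sim$ground_truth$spikes$sample, det, cfg$fs)
  expect_gte(m$hit_rate, 0.95)
})

test_that("component variances add up for non-overlapping spectra", {
  cfg <- synth_config(n_channels = 1, duration = 30, firing_rate = 3,
                      noise_sigma = 8, seed = 13)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  v_tot <- stats::var(sim$recording$signal[1, ])
  v_sum <- stats::var(gt$clean[1, ]) + stats::var(gt$lfp[1, ]) +
    stats::var(gt$noise[1, ])
  expect_lt(abs(v_tot - v_sum) / v_sum, 0.05)
})

test_that("population co-firing matches the prescribed sharing", {
  # p = 1, zero jitter: identical 50 ms bin counts
  P1 <- matrix(c(0, 1, 1, 0), 2, 2)
  cfg1 <- synth_config(n_channels = 2, duration = 30, firing_rate = 4,
                       correlation = P1, cofire_jitter_ms = 0,
                       noise_sigma = 5, seed = 41)
  s1 <- simulate_population(cfg1)
  sp <- s1$ground_truth$spikes
  h1 <- rate_histogram(sp$sample[sp$channel == 1], duration = 30, fs = cfg1$fs)
  h2 <- rate_histogram(sp$sample[sp$channel == 2], duration = 30, fs = cfg1$fs)
  expect_equal(h1, h2)

  # p = 0.5: shared-event fraction within 0.05 of 0.5
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  cfg <- synth_config(n_channels = 2, duration = 300, firing_rate = 4,
                      correlation = P, cofire_jitter_ms = 1,
                      noise_sigma = 5, seed = 42)
  s <- simulate_population(cfg)
  sp <- s$ground_truth$spikes
  tr1 <- sp$sample[sp$channel == 1]
  tr2 <- sp$sample[sp$channel == 2]
  m <- match_trains(tr1, tr2, cfg$fs, tolerance_us = 2500)
  shared_frac <- nrow(m$pairs) / length(tr1)
  expect_lt(abs(shared_frac - 0.5), 0.05)

  expect_error(synth_config(n_channels = 2, correlation = matrix(c(0, 1, 0.2, 0), 2, 2)),
               "symmetric")
})
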