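test_that("spike indexing finds injected peaks per electrode", {
  fs <- 25000
  mk_pair <- function(peaks, seed) {
    tr <- noisy_spike_trace(n = 1e5, peaks = peaks, amplitude = -100,
                            noise_sd = 10, seed = seed)
    structure(list(lpf_input = numeric(1e5), hpf_gt = tr$trace, scale = 1,
                   sigma = noise_sigma(tr$trace), fs = fs,
                   electrode_id = seed),
              class = "normalized_pair")
  }
  pairs <- list(mk_pair(c(20000L, 50000L, 80000L), 1),
                mk_pair(c(30000L, 60000L), 2))
  idx <- index_spikes(pairs)
  expect_identical(idx$K, 2L)
  expect_length(idx$peaks[[1]], 3)
  expect_length(idx$peaks[[2]], 2)
  expect_true(all(abs(idx$peaks[[1]] - c(20000, 50000, 80000)) <= 5))

  # spike-free electrode indexes zero spikes
  quiet <- structure(list(lpf_input = numeric(5e4),
                          hpf_gt = spikesr:::with_seed(9, rnorm(5e4, sd = 3)),
                          scale = 1, sigma = 3, fs = fs, electrode_id = "q"),
                     class = "normalized_pair")
  idxq <- index_spikes(list(quiet))
  expect_length(idxq$peaks[[1]], 0)
})

test_that("SFWS batches anchor half the windows on spike peaks", {
  fs <- 25000
  tr <- noisy_spike_trace(n = 2e5, peaks = as.integer(seq(5000, 195000, by = 5000)),
                          amplitude = -100, noise_sd = 10, seed = 3)
  pair <- structure(list(lpf_input = rnorm(2e5), hpf_gt = tr$trace, scale = 1,
                         sigma = noise_sigma(tr$trace), fs = fs,
                         electrode_id = 1),
                    class = "normalized_pair")
  pairs <- list(pair)
  idx <- index_spikes(pairs)
  ctl <- train_control(B = 16, W = 128, seed = 1)
  set.seed(10)
  for (rep in 1:25) {
    b <- sample_sfws_batch(pairs, idx, ctl)
    expect_identical(dim(b$input), c(16L, 128L))
    expect_identical(dim(b$gt), c(16L, 128L))
    expect_identical(nrow(b$anchors), 8L)
    # every anchored window contains its peak at the recorded position
    expect_true(all(b$anchors$peak_pos >= 1 & b$anchors$peak_pos <= 128))
    expect_true(all(b$anchors$tau > -64 & b$anchors$tau <= 64))
    expect_equal(b$anchors$peak_pos, 64L - b$anchors$tau + 1L)
    for (j in 1:8) {
      n0 <- idx$peaks[[b$anchors$electrode[j]]][b$anchors$spike[j]]
      expect_equal(b$gt[j, b$anchors$peak_pos[j]], pair$hpf_gt[n0])
    }
  }
  # without SFWS no windows are anchored
  ctl_off <- train_control(B = 16, W = 128, sfws = FALSE, seed = 1)
  b <- sample_sfws_batch(pairs, idx, ctl_off)
  expect_null(b$anchors)
  expect_error(train_control(B = 15), "even")
})

test_that("anchored peak positions are uniform over the window", {
  fs <- 25000
  tr <- noisy_spike_trace(n = 1e5, peaks = as.integer(seq(5000, 95000, by = 3000)),
                          amplitude = -100, noise_sd = 10, seed = 5)
  pairs <- list(structure(list(lpf_input = numeric(1e5), hpf_gt = tr$trace,
                               scale = 1, sigma = 1, fs = fs, electrode_id = 1),
                          class = "normalized_pair"))
  idx <- index_spikes(pairs)
  ctl <- train_control(B = 16, W = 128, seed = 1)
  set.seed(77)
  pos <- integer(0)
  for (rep in 1:1250) {
    pos <- c(pos, sample_sfws_batch(pairs, idx, ctl)$anchors$peak_pos)
  }
  counts <- tabulate(pos, nbins = 128)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("training reduces loss, is reproducible, and logs non-negative MSE", {
  pairs <- tiny_pairs(duration = 6, n_channels = 2, seed = 3)
  model <- swin1d_config(T = 128, C = 8, n_rstb = 1, n_stl = 2, heads = 2)
  ctl <- train_control(epochs = 2, steps_per_epoch = 15, lr = 1e-2, seed = 4)
  f1 <- spike_sr(pairs, model = model, control = ctl)
  expect_true(all(f1$history$loss >= 0))
  expect_lt(mean(tail(f1$history$loss, 10)), mean(head(f1$history$loss, 5)))
  # bitwise reproducibility under the same seed
  f2 <- spike_sr(pairs, model = model, control = ctl)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("fitted model exposes the standard accessor methods", {
  pairs <- tiny_pairs(duration = 6, n_channels = 2, seed = 3)
  fit <- spike_sr(pairs,
                  model = swin1d_config(T = 128, C = 8, n_rstb = 1, n_stl = 1,
                                        heads = 2),
                  control = train_control(epochs = 1, steps_per_epoch = 5,
                                          seed = 1))
  expect_s3_class(fit, "spike_sr")
  expect_output(print(fit), "parameters")
  sm <- summary(fit)
  expect_output(print(sm), "epoch loss")
  expect_type(coef(fit), "list")
  pr <- predict(fit, pairs[[1]])
  expect_length(pr, length(pairs[[1]]$lpf_input))
  res <- residuals(fit)
  expect_length(res, 2)
  expect_equal(res[[1]], pairs[[1]]$hpf_gt - fitted(fit)[[1]])
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("sliding-window reconstruction covers and averages correctly", {
  # identity stub: reconstruction must reproduce the input at any stride
  identity_stub <- function(Wm) Wm
  set.seed(6)
  x <- rnorm(1000)
  for (stride in c(1, 17, 64, 128)) {
    y <- reconstruct_sequence(identity_stub, x, stride = stride, W = 128)
    expect_equal(y, x)
  }
  # zero stub gives zeros of full length
  zero_stub <- function(Wm) Wm * 0
  expect_equal(reconstruct_sequence(zero_stub, x, stride = 64, W = 128),
               numeric(1000))
  expect_error(reconstruct_sequence(identity_stub, rnorm(100), W = 128),
               "shorter")
})
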