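# Independent per-layer parameter enumeration, written from the
# architecture definition (not from the builder).
stl_params <- function(C, heads, w, mlp_ratio) {
  H <- round(mlp_ratio * C)
  2 * C +                      # LN1
    3 * C^2 + 3 * C +          # qkv projection
    heads * (2 * w - 1) +      # relative position bias table
    C^2 + C +                  # output projection
    2 * C +                    # LN2
    C * H + H + H * C + C      # MLP
}

trunk_params <- function(C, n_rstb, n_stl, k, heads, w, mlp_ratio) {
  (3 * 1 * C + C) +                              # shallow conv 1 -> C
    n_rstb * (n_stl * stl_params(C, heads, w, mlp_ratio) +
                k * C^2 + C)                     # STLs + block conv
}

spike_net_params <- function(C, n_rstb, n_stl, k = 3, heads, w = 8,
                             mlp_ratio = 2) {
  trunk_params(C, n_rstb, n_stl, k, heads, w, mlp_ratio) +
    k * C * 1 + 1                                # final conv C -> 1
}

swinir_params <- function(C, n_rstb, n_stl, M, k = 3, heads = 6, w = 8,
                          mlp_ratio = 2) {
  trunk_params(C, n_rstb, n_stl, k, heads, w, mlp_ratio) +
    k * C * (C * M) + C * M +                    # sub-pixel upsampler conv
    k * C * 1 + 1                                # final conv
}

edsr_params <- function(C, n_blocks, M, k = 3) {
  (k * C + C) +                                  # head conv 1 -> C
    n_blocks * 2 * (k * C^2 + C) +               # residual blocks
    (k * C^2 + C) +                              # conv after body
    k * C * (C * M) + C * M +                    # upsampler conv
    k * C + 1                                    # final conv C -> 1
}

tcn_params <- function(C, n_blocks, k = 3) {
  (k * 1 * C + C) + (k * C^2 + C) +              # block 1 convs (in = 1)
    (1 * C + C) +                                # block 1 residual 1x1
    (n_blocks - 1) * 2 * (k * C^2 + C) +         # remaining blocks
    C + 1                                        # output head
}

test_that("the default configuration matches the reference architecture", {
  cfg <- swin1d_config()
  expect_equal(cfg$T, 128L)
  expect_equal(cfg$C, 180L)
  expect_equal(cfg$n_rstb, 6L)
  expect_equal(cfg$n_stl, 6L)
  expect_equal(cfg$kernel, 3L)
  expect_error(swin1d_config(T = 100, attn_window = 8), "divisible")
  expect_error(swin1d_config(C = 100, heads = 6), "divisible")
})

test_that("parameter counts match independent enumeration across configs", {
  cases <- list(
    list(C = 16, n_rstb = 2, n_stl = 2, heads = 4),
    list(C = 8, n_rstb = 1, n_stl = 1, heads = 2),
    list(C = 180, n_rstb = 6, n_stl = 6, heads = 6)
  )
  for (cs in cases) {
    net <- build_spk_model(swin1d_config(T = 128, C = cs$C, n_rstb = cs$n_rstb,
                                         n_stl = cs$n_stl, heads = cs$heads),
                           seed = 1)
    expect_identical(count_params(net),
                     as.integer(spike_net_params(cs$C, cs$n_rstb, cs$n_stl,
                                                 heads = cs$heads)))
  }

  for (M in c(1, 8, 16)) {
    net <- build_baseline(baseline_config("swinir", M = M, C = 12,
                                          n_blocks = 2, n_stl = 2, heads = 2),
                          seed = 1)
    expect_identical(count_params(net),
                     as.integer(swinir_params(12, 2, 2, M, heads = 2)))
  }
  for (cs in list(c(C = 10, b = 3, M = 8), c(C = 262, b = 16, M = 8),
                  c(C = 20, b = 2, M = 25))) {
    net <- build_baseline(baseline_config("edsr", M = cs["M"], C = cs["C"],
                                          n_blocks = cs["b"]), seed = 1)
    expect_identical(count_params(net),
                     as.integer(edsr_params(cs["C"], cs["b"], cs["M"])))
  }
  for (cs in list(c(C = 12, b = 2), c(C = 554, b = 6), c(C = 30, b = 4))) {
    net <- build_baseline(baseline_config("tcn", C = cs["C"],
                                          n_blocks = cs["b"]), seed = 1)
    expect_identical(count_params(net),
                     as.integer(tcn_params(cs["C"], cs["b"])))
  }
})

test_that("the trunk preserves length and is deterministic", {
  for (cs in list(c(T = 16, C = 8), c(T = 128, C = 16), c(T = 64, C = 12))) {
    net <- build_spk_model(swin1d_config(T = cs["T"], C = cs["C"], n_rstb = 1,
                                         n_stl = 2, heads = 2), seed = 2)
    x <- spikesr:::with_seed(5, rnorm(cs["T"]))
    y1 <- forward_window(net, x)
    expect_length(y1, cs["T"])
    expect_true(all(is.finite(y1)))
    expect_identical(y1, forward_window(net, x))
  }
  net <- build_spk_model(swin1d_config(T = 16, C = 8, n_rstb = 1, n_stl = 1,
                                       heads = 2), seed = 2)
  expect_error(forward_window(net, rnorm(15)), "length")
})

test_that("zeroing the final convolution zeroes the output", {
  net <- build_spk_model(swin1d_config(T = 32, C = 8, n_rstb = 1, n_stl = 2,
                                       heads = 2), seed = 3)
  net$params$conv_out_w[] <- 0
  net$params$conv_out_b[] <- 0
  expect_equal(forward_window(net, rnorm(32)), rep(0, 32))
})

test_that("the output is the final conv of shallow plus deep features", {
  ns <- asNamespace("spikesr")
  cfg <- swin1d_config(T = 32, C = 8, n_rstb = 2, n_stl = 2, heads = 2)
  net <- build_spk_model(cfg, seed = 9)
  x <- spikesr:::with_seed(4, rnorm(32))
  geoms <- ns$net_geoms(cfg, 1L)
  X <- matrix(x, ncol = 1)
  # independently extract F_SF, run the residual stack for F_DF, then
  # apply the final convolution to their sum
  p <- net$params
  F_sf <- ns$conv1d_fwd(X, p$conv_in_w, p$conv_in_b, geoms$g0)$out
  h <- F_sf
  for (r in 1:2) {
    h_in <- h
    for (s in 1:2) {
      id <- sprintf("r%d_s%d", r, s)
      geom <- if (s %% 2 == 0) geoms$gs else geoms$g0
      a <- ns$attention_fwd(
        ns$layernorm_fwd(h, p[[paste0(id, "_ln1_g")]], p[[paste0(id, "_ln1_b")]])$out,
        list(qkv_w = p[[paste0(id, "_qkv_w")]], qkv_b = p[[paste0(id, "_qkv_b")]],
             bias = p[[paste0(id, "_bias")]], proj_w = p[[paste0(id, "_proj_w")]],
             proj_b = p[[paste0(id, "_proj_b")]]),
        cfg$heads, geom)$out
      h1 <- h + a
      m <- ns$linear_fwd(
        ns$gelu_fwd(ns$linear_fwd(
          ns$layernorm_fwd(h1, p[[paste0(id, "_ln2_g")]], p[[paste0(id, "_ln2_b")]])$out,
          p[[paste0(id, "_mlp1_w")]], p[[paste0(id, "_mlp1_b")]])$out)$out,
        p[[paste0(id, "_mlp2_w")]], p[[paste0(id, "_mlp2_b")]])$out
      h <- h1 + m
    }
    h <- ns$conv1d_fwd(h, p[[sprintf("r%d_conv_w", r)]],
                       p[[sprintf("r%d_conv_b", r)]], geoms$g0)$out + h_in
  }
  F_df <- h
  ref <- ns$conv1d_fwd(F_sf + F_df, p$conv_out_w, p$conv_out_b, geoms$g0)$out
  expect_equal(forward_window(net, x), as.numeric(ref))
})

test_that("window attention matches a dense hand computation", {
  set.seed(42)
  Tn <- 4; C <- 4
  tok <- matrix(rnorm(Tn * C), Tn, C)
  w <- list(qkv_w = matrix(rnorm(C * 3 * C), C, 3 * C), qkv_b = rnorm(3 * C),
            bias = matrix(rnorm(7), 1, 7), proj_w = diag(C), proj_b = rep(0, C))
  out <- window_attention(tok, heads = 1, attn_window = 4, shift = 0,
                          weights = w)
  QKV <- tok %*% w$qkv_w + matrix(w$qkv_b, Tn, 3 * C, byrow = TRUE)
  S <- QKV[, 1:4] %*% t(QKV[, 5:8]) / sqrt(C) +
    outer(1:4, 1:4, function(i, j) w$bias[1, j - i + 4])
  A <- exp(S) / rowSums(exp(S))
  expect_equal(unclass(out), A %*% QKV[, 9:12], ignore_attr = TRUE,
               tolerance = 1e-12)
  # attention rows sum to one
  for (h in attr(out, "attention")) {
    expect_lt(max(abs(apply(h, c(1, 3), sum) - 1)), 1e-6)
  }
})

test_that("shifted attention equals attention on the rolled sequence", {
  set.seed(11)
  Tn <- 16; C <- 6
  tok <- matrix(rnorm(Tn * C), Tn, C)
  w <- list(qkv_w = matrix(rnorm(C * 3 * C), C, 3 * C), qkv_b = rnorm(3 * C),
            bias = matrix(0, 2, 7), proj_w = diag(C), proj_b = rep(0, C))
  o_shift <- window_attention(tok, heads = 2, attn_window = 4, shift = 2,
                              weights = w)
  o_roll <- window_attention(tok[c(3:16, 1:2), ], heads = 2, attn_window = 4,
                             shift = 0, weights = w)[c(15:16, 1:14), ]
  # identical away from the masked seam window
  non_seam <- setdiff(1:16, c(15, 16, 1, 2))
  expect_equal(unclass(o_shift)[non_seam, ], o_roll[non_seam, ],
               tolerance = 1e-12)
})

test_that("comparison networks have the prescribed output shapes", {
  sw <- build_baseline(baseline_config("swinir", M = 8, C = 8, n_blocks = 1,
                                       n_stl = 2, heads = 2), seed = 1)
  y <- forward_baseline(sw, rnorm(128))
  expect_length(y, 1024)

  ed <- build_baseline(baseline_config("edsr", M = 8, C = 8, n_blocks = 2),
                       seed = 1)
  expect_length(forward_baseline(ed, rnorm(128)), 1024)

  tc <- build_baseline(baseline_config("tcn", C = 16, n_blocks = 3), seed = 1)
  expect_length(forward_baseline(tc, rnorm(127)), 1)

  expect_error(baseline_config("swinir"), "M")
  expect_error(baseline_config("edsr"), "M")
})

test_that("network gradients match finite differences", {
  ns <- asNamespace("spikesr")
  cfg <- swin1d_config(T = 16, C = 6, n_rstb = 2, n_stl = 2, heads = 2,
                       attn_window = 4)
  net <- build_spk_model(cfg, seed = 3)
  G <- 2
  geoms <- ns$net_geoms(cfg, G)
  set.seed(7)
  X <- matrix(rnorm(G * 16), ncol = 1)
  Y <- matrix(rnorm(G * 16), ncol = 1)
  lossfn <- function(p) mean((ns$trunk_forward(p, cfg, X, geoms)$out - Y)^2)
  fw <- ns$trunk_forward(net$params, cfg, X, geoms, keep_cache = TRUE)
  grads <- ns$trunk_backward(net$params, cfg, fw$cache,
                             2 * (fw$out - Y) / length(Y))
  set.seed(99)
  for (nm in names(net$params)) {
    i <- sample(length(net$params[[nm]]), 1)
    pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-4
    pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-4
    num <- (lossfn(pp) - lossfn(pm)) / 2e-4
    expect_lt(abs(num - grads[[nm]][i]), 1e-7)
  }
})

test_that("one optimisation step reduces the batch loss", {
  ns <- asNamespace("spikesr")
  cfg <- swin1d_config(T = 16, C = 8, n_rstb = 1, n_stl = 1, heads = 2,
                       attn_window = 4)
  net <- build_spk_model(cfg, seed = 5)
  geoms <- ns$net_geoms(cfg, 4L)
  set.seed(2)
  X <- matrix(rnorm(64), ncol = 1)
  Y <- matrix(rnorm(64), ncol = 1)
  fw <- ns$trunk_forward(net$params, cfg, X, geoms, keep_cache = TRUE)
  l0 <- mean((fw$out - Y)^2)
  g <- ns$trunk_backward(net$params, cfg, fw$cache, 2 * (fw$out - Y) / 64)
  st <- ns$adam_init(net$params)
  upd <- ns$adam_step(net$params, g, st, lr = 1e-4)
  l1 <- mean((ns$trunk_forward(upd$params, cfg, X, geoms)$out - Y)^2)
  expect_lt(l1, l0)
})
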