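#' Configuration of the 1D shifted-window attention reconstruction network
#'
#' The reconstruction trunk is a 1D adaptation of the residual
#' Swin-transformer restoration architecture: a shallow 1D convolution
#' lifts the single-channel input window to `C` feature channels (one
#' token per time sample), a stack of `n_rstb` residual blocks — each
#' `n_stl` window-attention transformer layers followed by a
#' convolution and a residual add — forms the deep feature, the shallow
#' and deep features are summed (global skip), and a final convolution
#' projects back to one channel. There is no upsampling layer: the
#' input is pre-interpolated to the target resolution, so output length
#' equals input length.
#'
#' Defaults follow the reference restoration configuration: input
#' length 128, kernel 3, 180 channels, 6 blocks of 6 layers. Attention
#' uses non-overlapping windows of `attn_window` tokens, with a cyclic
#' shift of half a window on every second layer (masked at the seam),
#' `heads` heads, a learned relative-position bias of size
#' `2 * attn_window - 1` per head, pre-norm LayerNorm, and a GELU MLP
#' of expansion `mlp_ratio`.
#'
#' @param T Input window length in samples (must be divisible by
#'   `attn_window`).
#' @param C Feature channels (must be divisible by `heads`).
#' @param n_rstb Number of residual transformer blocks.
#' @param n_stl Transformer layers per block.
#' @param kernel Convolution kernel length.
#' @param heads Attention heads.
#' @param attn_window Tokens per attention window.
#' @param mlp_ratio Hidden expansion of the MLP.
#' @return An object of class `"swin1d_config"`.
#' @export
swin1d_config <- function(T = 128, C = 180, n_rstb = 6, n_stl = 6,
                          kernel = 3, heads = 6, attn_window = 8,
                          mlp_ratio = 2) {
  T <- as.integer(T); C <- as.integer(C)
  if (any(c(T, C, n_rstb, n_stl, kernel, heads, attn_window) < 1)) {
    stop("all size parameters must be >= 1")
  }
  if (T %% attn_window != 0) stop("T must be divisible by attn_window")
  if (C %% heads != 0) stop("C must be divisible by heads")
  if (attn_window < 2) stop("attn_window must be >= 2")
  structure(
    list(T = T, C = C, n_rstb = as.integer(n_rstb),
         n_stl = as.integer(n_stl), kernel = as.integer(kernel),
         heads = as.integer(heads), attn_window = as.integer(attn_window),
         mlp_ratio = mlp_ratio, shift = as.integer(attn_window) %/% 2L),
    class = "swin1d_config"
  )
}

trunc_normal <- function(n, sd = 0.02) {
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

conv_init <- function(k, cin, cout) {
  bound <- 1 / sqrt(k * cin)
  list(w = array(stats::runif(k * cin * cout, -bound, bound), c(k, cin, cout)),
       b = stats::runif(cout, -bound, bound))
}

init_trunk_params <- function(cfg) {
  C <- cfg$C
  H <- as.integer(round(cfg$mlp_ratio * C))
  p <- list()
  ci <- conv_init(cfg$kernel, 1L, C)
  p$conv_in_w <- ci$w; p$conv_in_b <- ci$b
  for (r in seq_len(cfg$n_rstb)) {
    for (s in seq_len(cfg$n_stl)) {
      id <- sprintf("r%d_s%d", r, s)
      p[[paste0(id, "_ln1_g")]] <- rep(1, C)
      p[[paste0(id, "_ln1_b")]] <- rep(0, C)
      p[[paste0(id, "_qkv_w")]] <- matrix(trunc_normal(C * 3L * C), C, 3L * C)
      p[[paste0(id, "_qkv_b")]] <- rep(0, 3L * C)
      p[[paste0(id, "_bias")]] <- matrix(trunc_normal(cfg$heads * (2L * cfg$attn_window - 1L)),
                                         cfg$heads, 2L * cfg$attn_window - 1L)
      p[[paste0(id, "_proj_w")]] <- matrix(trunc_normal(C * C), C, C)
      p[[paste0(id, "_proj_b")]] <- rep(0, C)
      p[[paste0(id, "_ln2_g")]] <- rep(1, C)
      p[[paste0(id, "_ln2_b")]] <- rep(0, C)
      p[[paste0(id, "_mlp1_w")]] <- matrix(trunc_normal(C * H), C, H)
      p[[paste0(id, "_mlp1_b")]] <- rep(0, H)
      p[[paste0(id, "_mlp2_w")]] <- matrix(trunc_normal(H * C), H, C)
      p[[paste0(id, "_mlp2_b")]] <- rep(0, C)
    }
    cr <- conv_init(cfg$kernel, C, C)
    p[[sprintf("r%d_conv_w", r)]] <- cr$w
    p[[sprintf("r%d_conv_b", r)]] <- cr$b
  }
  p
}

#' Build the spike-reconstruction network
#'
#' Initialises all trainable parameters of the trunk described in
#' [swin1d_config()] plus the final one-channel projection. Attention
#' and MLP weights are truncated-normal (sd 0.02), LayerNorm affine
#' parameters are (1, 0), convolutions use fan-in uniform
#' initialisation. Pass a `seed` for reproducible weights.
#'
#' @param config A [swin1d_config()].
#' @param seed Optional integer seed for the initialisation.
#' @return An object of class `"swin1d_net"`: list with `config` and
#'   the named parameter list `params`.
#' @export
build_spk_model <- function(config = swin1d_config(), seed = NULL) {
  stopifnot(inherits(config, "swin1d_config"))
  make <- function() {
    p <- init_trunk_params(config)
    co <- conv_init(config$kernel, config$C, 1L)
    p$conv_out_w <- co$w; p$conv_out_b <- co$b
    structure(list(config = config, params = p), class = "swin1d_net")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Number of trainable parameters
#'
#' @param net A network built by [build_spk_model()] or
#'   [build_baseline()].
#' @return Integer total count of trainable scalars.
#' @export
count_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.swin1d_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<swin1d_net> T=%d C=%d, %d blocks x %d layers, %d heads, window %d | %s parameters\n",
    cfg$T, cfg$C, cfg$n_rstb, cfg$n_stl, cfg$heads, cfg$attn_window,
    format(count_params(x), big.mark = ",")
  ))
  invisible(x)
}

net_geoms <- function(cfg, G) {
  list(g0 = nn_geom(G, cfg$T, cfg$attn_window, 0L, cfg$kernel),
       gs = nn_geom(G, cfg$T, cfg$attn_window, cfg$shift, cfg$kernel))
}

# Forward pass of the trunk on a chunk of G windows stacked as a
# (G*T) x 1 matrix. Returns the (G*T) x 1 output and, when keep_cache,
# everything the backward pass needs.
trunk_forward <- function(params, cfg, X, geoms, keep_cache = FALSE) {
  p <- params
  cache <- if (keep_cache) list(rstb = vector("list", cfg$n_rstb)) else NULL
  c_in <- conv1d_fwd(X, p$conv_in_w, p$conv_in_b, geoms$g0)
  F_sf <- c_in$out
  if (keep_cache) cache$c_in <- c_in$cache
  x <- F_sf
  for (r in seq_len(cfg$n_rstb)) {
    x_in <- x
    stl_caches <- if (keep_cache) vector("list", cfg$n_stl) else NULL
    for (s in seq_len(cfg$n_stl)) {
      id <- sprintf("r%d_s%d", r, s)
      geom <- if (s %% 2L == 0L) geoms$gs else geoms$g0
      ln1 <- layernorm_fwd(x, p[[paste0(id, "_ln1_g")]], p[[paste0(id, "_ln1_b")]])
      at <- attention_fwd(ln1$out,
                          list(qkv_w = p[[paste0(id, "_qkv_w")]],
                               qkv_b = p[[paste0(id, "_qkv_b")]],
                               bias = p[[paste0(id, "_bias")]],
                               proj_w = p[[paste0(id, "_proj_w")]],
                               proj_b = p[[paste0(id, "_proj_b")]]),
                          cfg$heads, geom)
      x1 <- x + at$out
      ln2 <- layernorm_fwd(x1, p[[paste0(id, "_ln2_g")]], p[[paste0(id, "_ln2_b")]])
      l1 <- linear_fwd(ln2$out, p[[paste0(id, "_mlp1_w")]], p[[paste0(id, "_mlp1_b")]])
      ge <- gelu_fwd(l1$out)
      l2 <- linear_fwd(ge$out, p[[paste0(id, "_mlp2_w")]], p[[paste0(id, "_mlp2_b")]])
      x <- x1 + l2$out
      if (keep_cache) {
        stl_caches[[s]] <- list(ln1 = ln1$cache, at = at$cache,
                                ln2 = ln2$cache, l1 = l1$cache,
                                ge = ge$cache, l2 = l2$cache)
      }
    }
    cr <- conv1d_fwd(x, p[[sprintf("r%d_conv_w", r)]],
                     p[[sprintf("r%d_conv_b", r)]], geoms$g0)
    x <- cr$out + x_in
    if (keep_cache) cache$rstb[[r]] <- list(stl = stl_caches, conv = cr$cache)
  }
  S <- F_sf + x
  c_out <- conv1d_fwd(S, p$conv_out_w, p$conv_out_b, geoms$g0)
  if (keep_cache) cache$c_out <- c_out$cache
  list(out = c_out$out, cache = cache)
}

# Backward pass matching trunk_forward. d_out: (G*T) x 1. Returns a
# named gradient list aligned with the parameter list.
trunk_backward <- function(params, cfg, cache, d_out) {
  g <- list()
  cb <- conv1d_bwd(d_out, cache$c_out)
  g$conv_out_w <- cb$dW; g$conv_out_b <- cb$db
  dS <- cb$dX
  d_F_sf <- dS
  dx <- dS
  for (r in rev(seq_len(cfg$n_rstb))) {
    rc <- cache$rstb[[r]]
    cbr <- conv1d_bwd(dx, rc$conv)
    g[[sprintf("r%d_conv_w", r)]] <- cbr$dW
    g[[sprintf("r%d_conv_b", r)]] <- cbr$db
    d_res <- dx                 # residual branch of the block
    dx <- cbr$dX
    for (s in rev(seq_len(cfg$n_stl))) {
      id <- sprintf("r%d_s%d", r, s)
      sc <- rc$stl[[s]]
      l2b <- linear_bwd(dx, sc$l2)
      g[[paste0(id, "_mlp2_w")]] <- l2b$dW
      g[[paste0(id, "_mlp2_b")]] <- l2b$db
      geb <- gelu_bwd(l2b$dX, sc$ge)
      l1b <- linear_bwd(geb$dX, sc$l1)
      g[[paste0(id, "_mlp1_w")]] <- l1b$dW
      g[[paste0(id, "_mlp1_b")]] <- l1b$db
      ln2b <- layernorm_bwd(l1b$dX, sc$ln2)
      g[[paste0(id, "_ln2_g")]] <- ln2b$dgamma
      g[[paste0(id, "_ln2_b")]] <- ln2b$dbeta
      dx1 <- dx + ln2b$dX
      atb <- attention_bwd(dx1, sc$at)
      g[[paste0(id, "_qkv_w")]] <- atb$dqkv_w
      g[[paste0(id, "_qkv_b")]] <- atb$dqkv_b
      g[[paste0(id, "_bias")]] <- atb$dbias
      g[[paste0(id, "_proj_w")]] <- atb$dproj_w
      g[[paste0(id, "_proj_b")]] <- atb$dproj_b
      ln1b <- layernorm_bwd(atb$dX, sc$ln1)
      g[[paste0(id, "_ln1_g")]] <- ln1b$dgamma
      g[[paste0(id, "_ln1_b")]] <- ln1b$dbeta
      dx <- dx1 + ln1b$dX
    }
    dx <- dx + d_res
  }
  d_F_sf <- d_F_sf + dx
  ci <- conv1d_bwd(d_F_sf, cache$c_in)
  g$conv_in_w <- ci$dW; g$conv_in_b <- ci$db
  g
}

#' Run windows through the reconstruction network
#'
#' Deterministic inference on one or more length-`T` windows. Output
#' length equals input length (the architecture has no resampling
#' layer).
#'
#' @param net A `"swin1d_net"`.
#' @param windows Numeric vector of length `T`, or a matrix with one
#'   window per row.
#' @return Same shape as the input: a vector, or a matrix of
#'   reconstructed windows.
#' @export
forward_window <- function(net, windows) {
  stopifnot(inherits(net, "swin1d_net"))
  cfg <- net$config
  vec <- is.null(dim(windows))
  Wm <- if (vec) matrix(windows, nrow = 1) else as.matrix(windows)
  if (ncol(Wm) != cfg$T) stop(sprintf("windows must have length T = %d", cfg$T))
  G <- nrow(Wm)
  geoms <- net_geoms(cfg, G)
  X <- matrix(as.vector(t(Wm)), ncol = 1)
  out <- trunk_forward(net$params, cfg, X, geoms)$out
  Y <- matrix(out, nrow = G, byrow = TRUE)
  if (vec) as.numeric(Y[1, ]) else Y
}

#' Windowed multi-head self-attention on a token sequence
#'
#' Standalone access to the attention primitive used inside every
#' transformer layer: tokens are partitioned into non-overlapping
#' windows of `attn_window` (after an optional cyclic shift, masked at
#' the wrap-around seam), and scaled dot-product attention with a
#' relative-position bias is computed within each window.
#'
#' @param tokens Numeric T-by-C matrix (T divisible by `attn_window`).
#' @param heads Number of heads (C divisible by `heads`).
#' @param attn_window Window length in tokens.
#' @param shift Cyclic shift (0 or typically `attn_window / 2`).
#' @param weights Optional list with `qkv_w` (C x 3C), `qkv_b`, `bias`
#'   (heads x (2 attn_window - 1)), `proj_w` (C x C), `proj_b`;
#'   randomly initialised when `NULL`.
#' @param seed Optional seed for the random initialisation.
#' @return The attended T-by-C matrix, with attribute `"attention"`: a
#'   list (one per head) of arrays `attn_window x attn_window x
#'   n_windows` of attention weights (rows sum to 1).
#' @export
window_attention <- function(tokens, heads, attn_window, shift = 0,
                             weights = NULL, seed = NULL) {
  tokens <- as.matrix(tokens)
  T <- nrow(tokens); C <- ncol(tokens)
  if (T %% attn_window != 0) stop("token count must be divisible by attn_window")
  if (C %% heads != 0) stop("C must be divisible by heads")
  if (is.null(weights)) {
    make <- function() list(
      qkv_w = matrix(trunc_normal(C * 3 * C), C, 3 * C),
      qkv_b = rep(0, 3 * C),
      bias = matrix(trunc_normal(heads * (2 * attn_window - 1)),
                    heads, 2 * attn_window - 1),
      proj_w = matrix(trunc_normal(C * C), C, C),
      proj_b = rep(0, C))
    weights <- if (is.null(seed)) make() else with_seed(seed, make())
  }
  geom <- nn_geom(1L, T, as.integer(attn_window), as.integer(shift))
  fw <- attention_fwd(tokens, weights, as.integer(heads), geom)
  out <- fw$out
  attn <- lapply(fw$cache$hc, function(h) {
    array(h$A, c(attn_window, attn_window, geom$nb))
  })
  attr(out, "attention") <- attn
  out
}

#' Configuration for a comparison network
#'
#' Three reference families are available, sized to match the
#' reconstruction trunk's parameter budget. `"swinir"` is the same
#' attention trunk but fed
#' the *downsampled* (not pre-interpolated) input and finished with a
#' sub-pixel shuffle upsampler producing `T * M` samples. `"edsr"` is a
#' residual CNN (default 262 channels, 16 residual blocks) with the
#' same upsampler. `"tcn"` is a causal dilated temporal CNN (default
#' 554 channels, 6 stacked blocks) consuming a pre-interpolated window
#' of 127 samples and emitting the single next sample.
#'
#' @param family `"swinir"`, `"edsr"` or `"tcn"`.
#' @param M Upsampling factor (required for swinir/edsr).
#' @param T Input length (defaults: 128 for swinir/edsr, 127 for tcn).
#' @param C Channels (defaults 180 / 262 / 554 by family).
#' @param n_blocks Residual (edsr) or stacked (tcn) blocks.
#' @param n_stl Layers per block (swinir only).
#' @param kernel Kernel length.
#' @param heads,attn_window,mlp_ratio Attention settings (swinir only).
#' @return An object of class `"baseline_config"`.
#' @export
baseline_config <- function(family = c("swinir", "edsr", "tcn"), M = NULL,
                            T = NULL, C = NULL, n_blocks = NULL, n_stl = 6,
                            kernel = 3, heads = 6, attn_window = 8,
                            mlp_ratio = 2) {
  family <- match.arg(family)
  if (family %in% c("swinir", "edsr")) {
    if (is.null(M)) stop(sprintf("family '%s' requires the upsampling factor M", family))
    M <- as.integer(M)
  } else {
    M <- NA_integer_
  }
  defaults <- switch(family,
    swinir = list(T = 128L, C = 180L, n_blocks = 6L),
    edsr = list(T = 128L, C = 262L, n_blocks = 16L),
    tcn = list(T = 127L, C = 554L, n_blocks = 6L)
  )
  structure(
    list(family = family, M = M,
         T = as.integer(if (is.null(T)) defaults$T else T),
         C = as.integer(if (is.null(C)) defaults$C else C),
         n_blocks = as.integer(if (is.null(n_blocks)) defaults$n_blocks else n_blocks),
         n_stl = as.integer(n_stl), kernel = as.integer(kernel),
         heads = as.integer(heads), attn_window = as.integer(attn_window),
         mlp_ratio = mlp_ratio),
    class = "baseline_config"
  )
}

#' Build a comparison network
#'
#' @param config A [baseline_config()].
#' @param seed Optional seed for the initialisation.
#' @return A network object (class `"swinir_net"`, `"edsr_net"` or
#'   `"tcn_net"`) with `config` and `params`; run it with
#'   [forward_baseline()] and size it with [count_params()].
#' @export
build_baseline <- function(config, seed = NULL) {
  stopifnot(inherits(config, "baseline_config"))
  make <- function() {
    switch(config$family,
      swinir = {
        trunk_cfg <- swin1d_config(T = config$T, C = config$C,
                                   n_rstb = config$n_blocks,
                                   n_stl = config$n_stl,
                                   kernel = config$kernel,
                                   heads = config$heads,
                                   attn_window = config$attn_window,
                                   mlp_ratio = config$mlp_ratio)
        p <- init_trunk_params(trunk_cfg)
        up <- conv_init(config$kernel, config$C, config$C * config$M)
        p$conv_up_w <- up$w; p$conv_up_b <- up$b
        co <- conv_init(config$kernel, config$C, 1L)
        p$conv_out_w <- co$w; p$conv_out_b <- co$b
        structure(list(config = config, trunk_cfg = trunk_cfg, params = p),
                  class = "swinir_net")
      },
      edsr = {
        C <- config$C
        p <- list()
        ci <- conv_init(config$kernel, 1L, C)
        p$conv_in_w <- ci$w; p$conv_in_b <- ci$b
        for (r in seq_len(config$n_blocks)) {
          c1 <- conv_init(config$kernel, C, C)
          c2 <- conv_init(config$kernel, C, C)
          p[[sprintf("b%d_conv1_w", r)]] <- c1$w
          p[[sprintf("b%d_conv1_b", r)]] <- c1$b
          p[[sprintf("b%d_conv2_w", r)]] <- c2$w
          p[[sprintf("b%d_conv2_b", r)]] <- c2$b
        }
        cb <- conv_init(config$kernel, C, C)
        p$conv_body_w <- cb$w; p$conv_body_b <- cb$b
        up <- conv_init(config$kernel, C, C * config$M)
        p$conv_up_w <- up$w; p$conv_up_b <- up$b
        co <- conv_init(config$kernel, C, 1L)
        p$conv_out_w <- co$w; p$conv_out_b <- co$b
        structure(list(config = config, params = p), class = "edsr_net")
      },
      tcn = {
        C <- config$C
        p <- list()
        cin <- 1L
        for (r in seq_len(config$n_blocks)) {
          c1 <- conv_init(config$kernel, cin, C)
          c2 <- conv_init(config$kernel, C, C)
          p[[sprintf("b%d_conv1_w", r)]] <- c1$w
          p[[sprintf("b%d_conv1_b", r)]] <- c1$b
          p[[sprintf("b%d_conv2_w", r)]] <- c2$w
          p[[sprintf("b%d_conv2_b", r)]] <- c2$b
          if (cin != C) {
            d <- conv_init(1L, cin, C)
            p[[sprintf("b%d_down_w", r)]] <- d$w
            p[[sprintf("b%d_down_b", r)]] <- d$b
          }
          cin <- C
        }
        co <- conv_init(1L, C, 1L)
        p$head_w <- co$w; p$head_b <- co$b
        structure(list(config = config, params = p), class = "tcn_net")
      }
    )
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

# 1D sub-pixel shuffle: (T x (C*M)) -> ((T*M) x C); sub-position m of
# output step t reads channel block m.
pixel_shuffle_1d <- function(X, M) {
  T <- nrow(X); CM <- ncol(X)
  C <- CM %/% M
  Y <- matrix(0, T * M, C)
  for (m in seq_len(M)) {
    Y[seq.int(m, T * M, by = M), ] <- X[, ((m - 1L) * C + 1L):(m * C), drop = FALSE]
  }
  Y
}

causal_dilated_conv <- function(X, W, b, dilation) {
  k <- dim(W)[1L]; cin <- dim(W)[2L]; cout <- dim(W)[3L]
  n <- nrow(X)
  Y <- matrix(rep(b, each = n), n, cout)
  for (d in seq_len(k)) {
    lag <- (k - d) * dilation
    Wd <- matrix(W[d, , ], cin, cout)
    if (lag == 0L) {
      Y <- Y + X %*% Wd
    } else if (lag < n) {
      Y[(lag + 1L):n, ] <- Y[(lag + 1L):n, , drop = FALSE] +
        X[1:(n - lag), , drop = FALSE] %*% Wd
    }
  }
  Y
}

#' Forward pass of a comparison network
#'
#' @param net A network from [build_baseline()].
#' @param x Numeric input window: length `T` (downsampled window for
#'   swinir/edsr; pre-interpolated window for tcn).
#' @return Numeric vector: length `T * M` for swinir/edsr, length 1 for
#'   tcn.
#' @export
forward_baseline <- function(net, x) {
  UseMethod("forward_baseline")
}

#' @export
forward_baseline.swinir_net <- function(net, x) {
  cfg <- net$config
  if (length(x) != cfg$T) stop(sprintf("input must have length %d", cfg$T))
  tc <- net$trunk_cfg
  geoms <- net_geoms(tc, 1L)
  p <- net$params
  X <- matrix(x, ncol = 1)
  c_in <- conv1d_fwd(X, p$conv_in_w, p$conv_in_b, geoms$g0)
  F_sf <- c_in$out
  xm <- F_sf
  for (r in seq_len(tc$n_rstb)) {
    x_in <- xm
    for (s in seq_len(tc$n_stl)) {
      id <- sprintf("r%d_s%d", r, s)
      geom <- if (s %% 2L == 0L) geoms$gs else geoms$g0
      ln1 <- layernorm_fwd(xm, p[[paste0(id, "_ln1_g")]], p[[paste0(id, "_ln1_b")]])
      at <- attention_fwd(ln1$out,
                          list(qkv_w = p[[paste0(id, "_qkv_w")]],
                               qkv_b = p[[paste0(id, "_qkv_b")]],
                               bias = p[[paste0(id, "_bias")]],
                               proj_w = p[[paste0(id, "_proj_w")]],
                               proj_b = p[[paste0(id, "_proj_b")]]),
                          tc$heads, geom)
      x1 <- xm + at$out
      ln2 <- layernorm_fwd(x1, p[[paste0(id, "_ln2_g")]], p[[paste0(id, "_ln2_b")]])
      l1 <- linear_fwd(ln2$out, p[[paste0(id, "_mlp1_w")]], p[[paste0(id, "_mlp1_b")]])
      ge <- gelu_fwd(l1$out)
      l2 <- linear_fwd(ge$out, p[[paste0(id, "_mlp2_w")]], p[[paste0(id, "_mlp2_b")]])
      xm <- x1 + l2$out
    }
    cr <- conv1d_fwd(xm, p[[sprintf("r%d_conv_w", r)]],
                     p[[sprintf("r%d_conv_b", r)]], geoms$g0)
    xm <- cr$out + x_in
  }
  S <- F_sf + xm
  up <- conv1d_fwd(S, p$conv_up_w, p$conv_up_b, geoms$g0)$out
  Y <- pixel_shuffle_1d(up, cfg$M)
  geom_out <- nn_geom(1L, cfg$T * cfg$M, tc$attn_window, 0L, tc$kernel)
  as.numeric(conv1d_fwd(Y, p$conv_out_w, p$conv_out_b, geom_out)$out)
}

#' @export
forward_baseline.edsr_net <- function(net, x) {
  cfg <- net$config
  if (length(x) != cfg$T) stop(sprintf("input must have length %d", cfg$T))
  p <- net$params
  geom <- nn_geom(1L, cfg$T, 2L, 0L, cfg$kernel)
  X <- matrix(x, ncol = 1)
  h <- conv1d_fwd(X, p$conv_in_w, p$conv_in_b, geom)$out
  body <- h
  for (r in seq_len(cfg$n_blocks)) {
    a <- conv1d_fwd(body, p[[sprintf("b%d_conv1_w", r)]],
                    p[[sprintf("b%d_conv1_b", r)]], geom)$out
    a <- pmax(a, 0)
    a <- conv1d_fwd(a, p[[sprintf("b%d_conv2_w", r)]],
                    p[[sprintf("b%d_conv2_b", r)]], geom)$out
    body <- body + a
  }
  body <- conv1d_fwd(body, p$conv_body_w, p$conv_body_b, geom)$out
  h <- h + body
  up <- conv1d_fwd(h, p$conv_up_w, p$conv_up_b, geom)$out
  Y <- pixel_shuffle_1d(up, cfg$M)
  geom_out <- nn_geom(1L, cfg$T * cfg$M, 2L, 0L, cfg$kernel)
  as.numeric(conv1d_fwd(Y, p$conv_out_w, p$conv_out_b, geom_out)$out)
}

#' @export
forward_baseline.tcn_net <- function(net, x) {
  cfg <- net$config
  if (length(x) != cfg$T) stop(sprintf("input must have length %d", cfg$T))
  p <- net$params
  h <- matrix(x, ncol = 1)
  for (r in seq_len(cfg$n_blocks)) {
    dilation <- 2L^(r - 1L)
    a <- causal_dilated_conv(h, p[[sprintf("b%d_conv1_w", r)]],
                             p[[sprintf("b%d_conv1_b", r)]], dilation)
    a <- pmax(a, 0)
    a <- causal_dilated_conv(a, p[[sprintf("b%d_conv2_w", r)]],
                             p[[sprintf("b%d_conv2_b", r)]], dilation)
    a <- pmax(a, 0)
    res <- if (!is.null(p[[sprintf("b%d_down_w", r)]])) {
      h %*% matrix(p[[sprintf("b%d_down_w", r)]][1L, , ], ncol(h),
                   dim(p[[sprintf("b%d_down_w", r)]])[3L]) +
        rep(p[[sprintf("b%d_down_b", r)]], each = nrow(h))
    } else h
    h <- res + a
  }
  last <- h[nrow(h), , drop = FALSE]
  as.numeric(last %*% matrix(p$head_w[1L, , ], ncol(h), 1L) + p$head_b)
}

#' @export
print.baseline_config <- function(x, ...) {
  cat(sprintf("<baseline_config> %s: T=%d C=%d blocks=%d M=%s\n",
              x$family, x$T, x$C, x$n_blocks,
              if (is.na(x$M)) "-" else x$M))
  invisible(x)
}
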