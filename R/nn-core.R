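# Vectorised 1D neural-network primitives.
#
# Activations for a chunk of G windows of T tokens are stored as a
# single (G*T) x C matrix, rows ordered window-major: row = (g-1)*T + t.
# Every primitive returns list(out, cache) on the forward pass and takes
# (d_out, cache) on the backward pass, so the trunk can be differentiated
# exactly without an autodiff framework. Geometry (index maps for
# padded convolution shifts, cyclic rolls and attention-window blocks)
# is precomputed per (G, T) shape and reused across layers and steps.

nn_geom <- function(G, T, w, shift, kernel = 3L) {
  n <- G * T
  pad <- (kernel - 1L) %/% 2L
  t_idx <- rep(seq_len(T), times = G)
  base <- rep((seq_len(G) - 1L) * T, each = T)
  conv_idx <- lapply((-pad):pad, function(d) {
    tt <- t_idx + d
    idx <- base + tt
    idx[tt < 1L | tt > T] <- n + 1L   # points at the appended zero row
    idx
  })
  roll_fwd <- roll_bwd <- NULL
  mask_vec <- NULL
  if (shift > 0L) {
    tt <- ((t_idx - 1L + shift) %% T) + 1L   # token t takes value from t+shift
    roll_fwd <- base + tt
    tb <- ((t_idx - 1L - shift) %% T) + 1L
    roll_bwd <- base + tb
    # after the roll, the last window of each T-group mixes tokens from
    # both sequence ends; mask cross-segment pairs there
    seg <- c(rep(0L, w - shift), rep(1L, shift))
    mm <- outer(seg, seg, FUN = function(a, b) ifelse(a == b, 0, -1e9))
    mask_vec <- as.vector(mm)   # length w^2, index i + (j-1)*w
  }
  nwin <- T %/% w
  nb <- G * nwin
  ii <- rep(seq_len(w), times = w)
  jj <- rep(seq_len(w), each = w)
  rel <- jj - ii + w           # 1 .. 2w-1
  rel_onehot <- matrix(0, w * w, 2L * w - 1L)
  rel_onehot[cbind(seq_len(w * w), rel)] <- 1
  wbase <- ((seq_len(G * T) - 1L) %/% w) * w   # start row of each token's block
  mask_blocks <- if (shift > 0L) seq.int(nwin, nb, by = nwin) else integer(0)
  list(G = G, T = T, n = n, w = w, nwin = nwin, nb = nb, pad = pad,
       conv_idx = conv_idx, roll_fwd = roll_fwd, roll_bwd = roll_bwd,
       mask_vec = mask_vec, mask_blocks = mask_blocks,
       ii = ii, jj = jj, rel = rel, rel_onehot = rel_onehot,
       wbase = wbase, shift = shift)
}

conv1d_fwd <- function(X, W, b, geom) {
  # W: array (kernel, Cin, Cout); zero "same" padding within each window
  k <- dim(W)[1L]
  cin <- dim(W)[2L]
  cout <- dim(W)[3L]
  Xz <- rbind(X, 0)
  Y <- matrix(rep(b, each = geom$n), geom$n, cout)
  for (d in seq_len(k)) {
    Y <- Y + Xz[geom$conv_idx[[d]], , drop = FALSE] %*%
      matrix(W[d, , ], cin, cout)
  }
  list(out = Y, cache = list(X = X, W = W, geom = geom))
}

conv1d_bwd <- function(dY, cache) {
  X <- cache$X; W <- cache$W; geom <- cache$geom
  k <- dim(W)[1L]; cin <- dim(W)[2L]; cout <- dim(W)[3L]
  Xz <- rbind(X, 0)
  dW <- array(0, dim(W))
  dX <- matrix(0, geom$n, cin)
  dYz <- rbind(dY, 0)
  for (d in seq_len(k)) {
    Xs <- Xz[geom$conv_idx[[d]], , drop = FALSE]
    dW[d, , ] <- crossprod(Xs, dY)
    # reverse shift: output position that read from input offset d reads
    # back; conv_idx for mirrored offset index (k + 1 - d)
    dX <- dX + dYz[geom$conv_idx[[k + 1L - d]], , drop = FALSE] %*%
      t(matrix(W[d, , ], cin, cout))
  }
  list(dX = dX, dW = dW, db = .colSums(dY, nrow(dY), ncol(dY)))
}

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  nr <- nrow(X); nc <- ncol(X)
  mu <- .rowMeans(X, nr, nc)
  xc <- X - mu
  v <- .rowMeans(xc * xc, nr, nc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = Y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_bwd <- function(dY, cache) {
  n <- nrow(dY)
  nc <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- .colSums(dY * xhat, n, nc)
  dbeta <- .colSums(dY, n, nc)
  dxhat <- dY * rep(cache$gamma, each = n)
  dX <- cache$inv * (dxhat - .rowMeans(dxhat, n, nc) -
                       xhat * .rowMeans(dxhat * xhat, n, nc))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)),
       cache = list(X = X, W = W))
}

linear_bwd <- function(dY, cache) {
  list(dX = tcrossprod(dY, cache$W),
       dW = crossprod(cache$X, dY),
       db = .colSums(dY, nrow(dY), ncol(dY)))
}

gelu_fwd <- function(X) {
  list(out = X * stats::pnorm(X), cache = list(X = X))
}

gelu_bwd <- function(dY, cache) {
  X <- cache$X
  list(dX = dY * (stats::pnorm(X) + X * stats::dnorm(X)))
}

# Windowed multi-head self-attention with learned relative position bias
# and optional cyclic shift (masked at the wrap-around seam).
attention_fwd <- function(X, p, heads, geom) {
  n <- geom$n; w <- geom$w; nb <- geom$nb
  C <- ncol(X)
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  Xs <- if (geom$shift > 0L) X[geom$roll_fwd, , drop = FALSE] else X
  QKV <- Xs %*% p$qkv_w + rep(p$qkv_b, each = n)
  O <- matrix(0, n, C)
  hc <- vector("list", heads)
  rows_w <- seq_len(w)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- QKV[, cols, drop = FALSE] * scale
    Kh <- QKV[, C + cols, drop = FALSE]
    Vh <- QKV[, 2L * C + cols, drop = FALSE]
    S <- matrix(0, w * w, nb)
    for (j in rows_w) {
      S[(j - 1L) * w + rows_w, ] <-
        .rowSums(Qh * Kh[geom$wbase + j, , drop = FALSE], n, dh)
    }
    S <- S + p$bias[h, geom$rel]
    if (length(geom$mask_blocks)) {
      S[, geom$mask_blocks] <- S[, geom$mask_blocks] + geom$mask_vec
    }
    # softmax over j (row chunks of length w share i)
    mx <- S[rows_w, , drop = FALSE]
    for (j in 2:w) mx <- pmax(mx, S[(j - 1L) * w + rows_w, , drop = FALSE])
    E <- exp(S - mx[geom$ii, , drop = FALSE])
    dn <- E[rows_w, , drop = FALSE]
    for (j in 2:w) dn <- dn + E[(j - 1L) * w + rows_w, , drop = FALSE]
    A <- E / dn[geom$ii, , drop = FALSE]
    Oh <- matrix(0, n, dh)
    for (j in rows_w) {
      Oh <- Oh + as.vector(A[(j - 1L) * w + rows_w, , drop = FALSE]) *
        Vh[geom$wbase + j, , drop = FALSE]
    }
    O[, cols] <- Oh
    hc[[h]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, A = A)
  }
  P <- O %*% p$proj_w + rep(p$proj_b, each = n)
  out <- if (geom$shift > 0L) P[geom$roll_bwd, , drop = FALSE] else P
  list(out = out,
       cache = list(Xs = Xs, O = O, hc = hc, heads = heads, dh = dh,
                    scale = scale, geom = geom, p = p))
}

attention_bwd <- function(dY, cache) {
  geom <- cache$geom
  n <- geom$n; w <- geom$w; nb <- geom$nb
  p <- cache$p
  heads <- cache$heads; dh <- cache$dh; scale <- cache$scale
  C <- heads * dh
  dP <- if (geom$shift > 0L) dY[geom$roll_fwd, , drop = FALSE] else dY
  dproj_w <- crossprod(cache$O, dP)
  dproj_b <- .colSums(dP, n, C)
  dO <- tcrossprod(dP, p$proj_w)
  dQKV <- matrix(0, n, 3L * C)
  dbias <- matrix(0, heads, 2L * w - 1L)
  rows_w <- seq_len(w)
  block_sum <- function(M) {
    # sum rows of an n x dh matrix within each w-block -> nb x dh
    matrix(.colSums(matrix(M, w, nb * dh), w, nb * dh), nb, dh)
  }
  jrows <- function(j) (seq_len(nb) - 1L) * w + j
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    hcache <- cache$hc[[h]]
    A <- hcache$A
    dOh <- dO[, cols, drop = FALSE]
    # dA[(i,j),b] = sum_k dOh[(b,i),k] * Vh[(b,j),k]
    dA <- matrix(0, w * w, nb)
    dVh <- matrix(0, n, dh)
    for (j in rows_w) {
      dA[(j - 1L) * w + rows_w, ] <-
        .rowSums(dOh * hcache$Vh[geom$wbase + j, , drop = FALSE], n, dh)
      dVh[jrows(j), ] <-
        block_sum(as.vector(A[(j - 1L) * w + rows_w, , drop = FALSE]) * dOh)
    }
    # softmax backward over j
    AdA <- A * dA
    s <- AdA[rows_w, , drop = FALSE]
    for (j in 2:w) s <- s + AdA[(j - 1L) * w + rows_w, , drop = FALSE]
    dS <- A * (dA - s[geom$ii, , drop = FALSE])
    dbias[h, ] <- as.numeric(crossprod(geom$rel_onehot, .rowSums(dS, w * w, nb)))
    dQh <- matrix(0, n, dh)
    dKh <- matrix(0, n, dh)
    for (j in rows_w) {
      dSj <- as.vector(dS[(j - 1L) * w + rows_w, , drop = FALSE])
      dQh <- dQh + dSj * hcache$Kh[geom$wbase + j, , drop = FALSE]
      dKh[jrows(j), ] <- block_sum(dSj * hcache$Qh)
    }
    dQKV[, cols] <- dQh * scale           # Qh carries the 1/sqrt(dh) scale
    dQKV[, C + cols] <- dKh
    dQKV[, 2L * C + cols] <- dVh
  }
  dqkv_w <- crossprod(cache$Xs, dQKV)
  dqkv_b <- .colSums(dQKV, n, 3L * C)
  dXs <- tcrossprod(dQKV, p$qkv_w)
  dX <- if (geom$shift > 0L) dXs[geom$roll_bwd, , drop = FALSE] else dXs
  list(dX = dX, dqkv_w = dqkv_w, dqkv_b = dqkv_b, dbias = dbias,
       dproj_w = dproj_w, dproj_b = dproj_b)
}
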