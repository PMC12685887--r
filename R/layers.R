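# Differentiable layer primitives with hand-written backward passes.
#
# Convention: every forward returns list(out, cache); every backward takes
# (params, cache, dout) and returns list(dx, grads) where `grads` mirrors the
# parameter structure. Caches hold exactly what the backward pass re-reads.

## ---- initialisers -----------------------------------------------------------

# He-normal fan-in initialisation for a conv / linear weight.
init_conv <- function(c_out, c_in, k, init = "he", rng = NULL) {
  n <- c_out * c_in * k * k
  W <- if (init == "zero") matrix(0, c_out, c_in * k * k)
       else matrix(rnorm(n, sd = sqrt(2 / (c_in * k * k))), c_out, c_in * k * k)
  list(W = W, b = numeric(c_out))
}

init_linear <- function(d_out, d_in, init = "he") {
  W <- if (init == "zero") matrix(0, d_out, d_in)
       else matrix(rnorm(d_out * d_in, sd = sqrt(2 / d_in)), d_out, d_in)
  list(W = W, b = numeric(d_out))
}

# 3x3 conv weight implementing the identity on mapped channels (center tap 1);
# unmapped output rows get small-noise He weights scaled by `noise`.
ident_conv3 <- function(c_out, c_in, n_map = min(c_out, c_in), noise = 0.03,
                        rng_noise = TRUE) {
  W <- matrix(if (rng_noise)
    rnorm(c_out * c_in * 9, sd = noise * sqrt(2 / (c_in * 9))) else 0,
    c_out, c_in * 9)
  for (c in seq_len(n_map)) W[c, c + 4 * c_in] <- 1   # center tap (ki=kj=1)
  list(W = W, b = numeric(c_out))
}

# conv + pixel-shuffle weight implementing bilinear x r upsampling per
# channel: output channel j + r*i + r^2*(c-1) takes a 2-tap bilinear stencil
# of input channel c. `gain` scales the interpolation (compensates the global
# skip doubling at identity initialisation).
bilinear_shuffle_conv <- function(channels, r, gain = 1, noise = 0.02) {
  C <- channels
  W <- matrix(rnorm(C * r * r * C * 9, sd = noise * sqrt(2 / (C * 9))),
              C * r * r, C * 9)
  wts <- function(o) {          # bilinear weights over taps dy in -1, 0, 1
    w <- c(0, 0, 0)
    if (o >= 0) { w[2] <- 1 - o; w[3] <- o } else { w[2] <- 1 + o; w[1] <- -o }
    w
  }
  for (c in seq_len(C)) for (i in 0:(r - 1)) for (j in 0:(r - 1)) {
    row <- j + r * i + r * r * (c - 1) + 1
    wy <- wts((i + 0.5) / r - 0.5)
    wx <- wts((j + 0.5) / r - 0.5)
    for (ki in 0:2) for (kj in 0:2) {
      col <- c + C * (ki + 3 * kj)
      W[row, col] <- gain * wy[ki + 1] * wx[kj + 1]
    }
  }
  list(W = W, b = numeric(C * r * r))
}

## ---- conv2d -----------------------------------------------------------------

# params: list(W = (Cout x Cin*k*k), b = Cout). pad: "zero" | "reflect".
# The im2col matrix computed in forward is kept in the cache and reused by
# backward, so each conv builds its column matrix once per step.
conv_fwd <- function(params, x, k = 3L, pad = "zero") {
  k <- as.integer(k)
  r <- cpp_conv2d_fwd(x, params$W, params$b, k, pad == "zero")
  cache <- list(cols = r$cols, dims = dim(x), k = k, pad = pad)
  if (k == 1L) cache$x <- x
  list(out = r$out, cache = cache)
}

conv_bwd <- function(params, cache, dout) {
  if (cache$k == 1L) {
    d <- cache$dims
    doutm <- matrix(dout, nrow = dim(dout)[1])
    xm <- matrix(cache$x, nrow = d[1])
    dW <- tcrossprod(doutm, xm)
    db <- rowSums(doutm)
    dx <- crossprod(params$W, doutm)
    dim(dx) <- d
    return(list(dx = dx, grads = list(W = dW, b = db)))
  }
  g <- cpp_conv2d_bwd(cache$cols, params$W, dout, cache$dims, cache$k,
                      cache$pad == "zero")
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}

## ---- relu -------------------------------------------------------------------

relu_fwd <- function(x) {
  out <- pmax(x, 0)
  dim(out) <- dim(x)
  list(out = out, cache = x > 0)
}

relu_bwd <- function(cache, dout) {
  dx <- dout * cache
  dim(dx) <- dim(dout)
  dx
}

## ---- layer norm over channels ----------------------------------------------

# Normalises each spatial position's channel vector. params: gamma, beta (C).
LN_EPS <- 1e-6

ln_fwd <- function(params, x) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  mu <- colMeans(m)
  xc <- m - rep(mu, each = C)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * rep(inv, each = C)
  out <- xhat * params$gamma + params$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, d = d))
}

ln_bwd <- function(params, cache, dout) {
  d <- cache$d
  C <- d[1]
  dm <- matrix(dout, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dm * xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * params$gamma
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(mean_dxhat, each = C) - xhat * rep(mean_dxhat_xhat, each = C)) *
    rep(cache$inv, each = C)
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- position-wise MLP ------------------------------------------------------

# Two 1x1 linear maps with a ReLU, applied per spatial position.
# params: W1 (Ce x C), b1, W2 (C x Ce), b2.
mlp_fwd <- function(params, x) {
  d <- dim(x)
  C <- d[1]
  m <- matrix(x, nrow = C)
  z1 <- params$W1 %*% m + params$b1
  a <- pmax(z1, 0)
  out <- params$W2 %*% a + params$b2
  dim(out) <- d
  list(out = out, cache = list(m = m, a = a, pos = z1 > 0, d = d))
}

mlp_bwd <- function(params, cache, dout) {
  d <- cache$d
  dm <- matrix(dout, nrow = d[1])
  dW2 <- dm %*% t(cache$a)
  db2 <- rowSums(dm)
  da <- t(params$W2) %*% dm
  dz1 <- da * cache$pos
  dW1 <- dz1 %*% t(cache$m)
  db1 <- rowSums(dz1)
  dx <- t(params$W1) %*% dz1
  dim(dx) <- d
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## ---- pixel shuffle ----------------------------------------------------------

#' Rearrange channel groups into space (sub-pixel upsampling)
#'
#' Maps an `(C*r^2, H, W)` feature map to `(C, r*H, r*W)` using the standard
#' channel-to-space ordering: input channel `c*r^2 + i*r + j` (zero-based)
#' fills output position `(r*h + i, r*w + j)` of output channel `c`.
#'
#' @param x feature map array `(C*r^2, H, W)` or with a trailing batch dim.
#' @param r integer upscaling factor.
#' @return the shuffled feature map.
#' @export
pixel_shuffle <- function(x, r) {
  w4 <- as_fmap4(x)
  x <- w4$x
  d <- dim(x)
  Crr <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  if (Crr %% (r * r) != 0L) stop_input("pixel_shuffle: channels not divisible by r^2")
  C <- Crr %/% (r * r)
  # channel index c*r^2 + i*r + j, zero-based, j fastest in memory
  dim(x) <- c(r, r, C, H, W, B)            # (j, i, c, h, w, b)
  out <- aperm(x, c(3, 2, 4, 1, 5, 6))     # (c, i, h, j, w, b)
  dim(out) <- c(C, r * H, r * W, B)
  drop_batch(out, w4$had_batch)
}

pixel_shuffle_bwd <- function(dout, r) {
  d <- dim(dout)
  C <- d[1]; rH <- d[2]; rW <- d[3]; B <- d[4]
  H <- rH %/% r; W <- rW %/% r
  dim(dout) <- c(C, r, H, r, W, B)         # (c, i, h, j, w, b)
  dx <- aperm(dout, c(4, 2, 1, 3, 5, 6))   # (j, i, c, h, w, b)
  dim(dx) <- c(C * r * r, H, W, B)
  dx
}

## ---- residual block (EDSR style) -------------------------------------------

# y = x + conv2(relu(conv1(x))); constant width, zero padding, k = 3.
resblock_init <- function(channels, init = "he") {
  list(conv1 = init_conv(channels, channels, 3L, init),
       conv2 = init_conv(channels, channels, 3L, init))
}

resblock_fwd <- function(params, x) {
  c1 <- conv_fwd(params$conv1, x)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(params$conv2, r1$out)
  list(out = x + c2$out, cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache))
}

resblock_bwd <- function(params, cache, dout) {
  b2 <- conv_bwd(params$conv2, cache$c2, dout)
  dr <- relu_bwd(cache$r1, b2$dx)
  b1 <- conv_bwd(params$conv1, cache$c1, dr)
  list(dx = dout + b1$dx, grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

# A stack of residual blocks sharing one width.
resstack_init <- function(channels, depth, init = "he") {
  lapply(seq_len(depth), function(i) resblock_init(channels, init))
}

resstack_fwd <- function(params, x) {
  caches <- vector("list", length(params))
  for (i in seq_along(params)) {
    s <- resblock_fwd(params[[i]], x)
    x <- s$out
    caches[[i]] <- s$cache
  }
  list(out = x, cache = caches)
}

resstack_bwd <- function(params, caches, dout) {
  grads <- vector("list", length(params))
  for (i in rev(seq_along(params))) {
    b <- resblock_bwd(params[[i]], caches[[i]], dout)
    dout <- b$dx
    grads[[i]] <- b$grads
  }
  list(dx = dout, grads = grads)
}
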