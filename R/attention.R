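# Hybrid Attention (HA): parallel multi-head self-attention over spatial
# positions and squeeze-and-excitation style channel attention, summed,
# layer-normalised, and passed through a lightweight position-wise MLP:
#
#   F_HA  = MSA(F_in) + CA(F_in)
#   F_out = MLP(Norm(F_HA))          (+ F_in when residual_skip is on)
#
# The two attention paths read the same input (parallel, not sequential) and
# share no weights.

#' Hybrid attention configuration
#'
#' @param channels feature width `C`; must be divisible by `heads`.
#' @param heads number of self-attention heads (default 4).
#' @param ca_reduction channel-attention bottleneck divisor (default 16;
#'   `channels / ca_reduction` is floored at 1).
#' @param mlp_expansion width multiplier of the MLP hidden layer (default 2).
#' @param window side of the square attention window in pixels, or `"full"`
#'   for unwindowed attention over all positions (default 8; windowing bounds
#'   the quadratic cost of self-attention on large maps).
#' @param residual_skip include a skip connection `x + MLP(Norm(...))` around
#'   the unit (default `FALSE`, the literal un-skipped form; the zero-output
#'   MLP initialisation of [hffen_net()] provides training stability without
#'   one).
#' @return an object of class `attention_config`.
#' @export
attention_config <- function(channels, heads = 4L, ca_reduction = 16L,
                             mlp_expansion = 2, window = 8L,
                             residual_skip = FALSE) {
  channels <- as.integer(channels)
  heads <- as.integer(heads)
  if (channels < 1L || heads < 1L) stop_input("channels and heads must be positive")
  if (channels %% heads != 0L)
    stop_input("channels (", channels, ") must be divisible by heads (", heads, ")")
  ca_hidden <- max(1L, channels %/% as.integer(ca_reduction))
  mlp_hidden <- max(1L, as.integer(round(channels * mlp_expansion)))
  structure(list(channels = channels, heads = heads,
                 ca_reduction = as.integer(ca_reduction),
                 ca_hidden = ca_hidden,
                 mlp_expansion = mlp_expansion, mlp_hidden = mlp_hidden,
                 window = window, residual_skip = isTRUE(residual_skip)),
            class = "attention_config")
}

ha_init <- function(channels, acfg, init = "he") {
  stopifnot(acfg$channels == channels)
  list(
    msa = list(q = init_linear(channels, channels, init),
               k = init_linear(channels, channels, init),
               v = init_linear(channels, channels, init),
               o = init_linear(channels, channels, init)),
    ca = list(f1 = init_linear(acfg$ca_hidden, channels, init),
              f2 = init_linear(channels, acfg$ca_hidden, init)),
    ln = list(gamma = rep(if (init == "zero") 0 else 1, channels),
              beta = numeric(channels)),
    mlp = list(W1 = init_linear(acfg$mlp_hidden, channels, init)$W,
               b1 = numeric(acfg$mlp_hidden),
               W2 = init_linear(channels, acfg$mlp_hidden, init)$W,
               b2 = numeric(channels))
  )
}

## ---- window partition -------------------------------------------------------

# Rearranges (C, H, W, B) into token blocks (T, G, C): T = tokens per window,
# G = windows * batch. Maps smaller than the window (or "full") use a single
# window covering the zero-padded map.
win_partition <- function(x, window) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  if (identical(window, "full")) {
    wh <- H; ww <- W
  } else {
    wh <- ww <- as.integer(window)
  }
  Hp <- ceiling(H / wh) * wh
  Wp <- ceiling(W / ww) * ww
  if (Hp != H || Wp != W) {
    xp <- array(0, c(C, Hp, Wp, B))
    xp[, seq_len(H), seq_len(W), ] <- x
    x <- xp
  }
  nH <- Hp %/% wh; nW <- Wp %/% ww
  dim(x) <- c(C, wh, nH, ww, nW, B)
  tok <- aperm(x, c(2, 4, 1, 3, 5, 6))        # (wh, ww, C, nH, nW, B)
  Tn <- wh * ww
  G <- nH * nW * B
  dim(tok) <- c(Tn, C, G)
  list(tok = tok, geom = list(C = C, H = H, W = W, B = B, wh = wh, ww = ww,
                              nH = nH, nW = nW, Hp = Hp, Wp = Wp))
}

win_merge <- function(tok, geom) {
  g <- geom
  dim(tok) <- c(g$wh, g$ww, g$C, g$nH, g$nW, g$B)
  x <- aperm(tok, c(3, 1, 4, 2, 5, 6))        # (C, wh, nH, ww, nW, B)
  dim(x) <- c(g$C, g$Hp, g$Wp, g$B)
  if (g$Hp != g$H || g$Wp != g$W) x <- x[, seq_len(g$H), seq_len(g$W), , drop = FALSE]
  x
}

# Adjoint of win_partition (zero-pad the gradient back, then merge is exact).
win_partition_adj <- function(dtok, geom) win_merge(dtok, geom)

win_merge_adj <- function(dx, geom) {
  g <- geom
  if (g$Hp != g$H || g$Wp != g$W) {
    dp <- array(0, c(g$C, g$Hp, g$Wp, g$B))
    dp[, seq_len(g$H), seq_len(g$W), ] <- dx
    dx <- dp
  }
  dim(dx) <- c(g$C, g$wh, g$nH, g$ww, g$nW, g$B)
  tok <- aperm(dx, c(2, 4, 1, 3, 5, 6))
  dim(tok) <- c(g$wh * g$ww, g$C, g$nH * g$nW * g$B)
  tok
}

## ---- multi-head self-attention ---------------------------------------------

# Projections run as one big gemm over all tokens; the per-(window, head)
# score/softmax/value loop runs in C++ (cpp_attn_fwd/bwd).
msa_fwd <- function(params, x, acfg) {
  wp <- win_partition(x, acfg$window)
  tok <- wp$tok
  Tn <- dim(tok)[1]; C <- dim(tok)[2]; G <- dim(tok)[3]
  h <- acfg$heads; dh <- C %/% h
  X <- matrix(aperm(tok, c(1, 3, 2)), nrow = Tn * G)     # (T*G, C)
  Q <- X %*% t(params$q$W) + rep(params$q$b, each = Tn * G)
  K <- X %*% t(params$k$W) + rep(params$k$b, each = Tn * G)
  V <- X %*% t(params$v$W) + rep(params$v$b, each = Tn * G)
  # split heads: channel index = d + dh*(head-1); slices are (T, dh, G*h)
  to_slices <- function(M) {
    dim(M) <- c(Tn, G, dh, h)
    M <- aperm(M, c(1, 3, 2, 4))
    dim(M) <- c(Tn, dh, G * h)
    M
  }
  Qs <- to_slices(Q); Ks <- to_slices(K); Vs <- to_slices(V)
  at <- cpp_attn_fwd(Qs, Ks, Vs)
  O <- at$O
  dim(O) <- c(Tn, dh, G, h)
  O <- aperm(O, c(1, 3, 2, 4))
  Om <- matrix(O, nrow = Tn * G)                          # (T*G, C) head-concat
  Y <- Om %*% t(params$o$W) + rep(params$o$b, each = Tn * G)
  ytok <- aperm(array(Y, c(Tn, G, C)), c(1, 3, 2))
  out <- win_merge(ytok, wp$geom)
  list(out = out,
       cache = list(X = X, Qs = Qs, Ks = Ks, Vs = Vs, A = at$A, Om = Om,
                    geom = wp$geom, Tn = Tn, G = G, h = h, dh = dh))
}

msa_bwd <- function(params, cache, dout, acfg) {
  g0 <- cache$geom
  Tn <- cache$Tn; G <- cache$G; h <- cache$h; dh <- cache$dh
  C <- g0$C
  dtok <- win_merge_adj(dout, g0)                         # (T, C, G)
  dY <- matrix(aperm(dtok, c(1, 3, 2)), nrow = Tn * G)    # (T*G, C)
  dWo <- t(dY) %*% cache$Om
  dbo <- colSums(dY)
  dO <- dY %*% params$o$W
  dim(dO) <- c(Tn, G, dh, h)
  dO <- aperm(dO, c(1, 3, 2, 4))
  dim(dO) <- c(Tn, dh, G * h)
  bk <- cpp_attn_bwd(cache$Qs, cache$Ks, cache$Vs, cache$A, dO)
  from_slices <- function(M) {
    dim(M) <- c(Tn, dh, G, h)
    M <- aperm(M, c(1, 3, 2, 4))
    matrix(M, nrow = Tn * G)
  }
  dQm <- from_slices(bk$dQ)
  dKm <- from_slices(bk$dK)
  dVm <- from_slices(bk$dV)
  X <- cache$X
  grads <- list(q = list(W = t(dQm) %*% X, b = colSums(dQm)),
                k = list(W = t(dKm) %*% X, b = colSums(dKm)),
                v = list(W = t(dVm) %*% X, b = colSums(dVm)),
                o = list(W = dWo, b = dbo))
  dX <- dQm %*% params$q$W + dKm %*% params$k$W + dVm %*% params$v$W
  dtok2 <- aperm(array(dX, c(Tn, G, C)), c(1, 3, 2))
  dx <- win_partition_adj(dtok2, g0)
  list(dx = dx, grads = grads)
}

## ---- channel attention ------------------------------------------------------

# broadcast a (C, B) per-channel quantity over the spatial grid
bcast_cb <- function(g, d) {
  HW <- d[2] * d[3]
  out <- g[, rep(seq_len(d[4]), each = HW), drop = FALSE]
  dim(out) <- d
  out
}

# sum a (C, HW*B)-viewed array over the spatial grid -> (C, B)
pool_cb <- function(x, C, HW, B, scale = 1) {
  sel <- diag(B)[rep(seq_len(B), each = HW), , drop = FALSE]
  (matrix(x, nrow = C) %*% sel) * scale
}

ca_fwd <- function(params, x) {
  d <- dim(x)
  C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  pooled <- pool_cb(x, C, HW, B, 1 / HW)       # (C, B) global average pool
  z1 <- params$f1$W %*% pooled + params$f1$b
  a <- pmax(z1, 0)
  z2 <- params$f2$W %*% a + params$f2$b
  gate <- 1 / (1 + exp(-z2))                   # (C, B), strictly in (0, 1)
  gx <- bcast_cb(gate, d)
  list(out = x * gx, cache = list(x = x, pooled = pooled, a = a,
                                  pos = z1 > 0, gate = gate, d = d))
}

ca_bwd <- function(params, cache, dout) {
  d <- cache$d
  C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  gate <- cache$gate
  dx <- dout * bcast_cb(gate, d)
  dgate <- pool_cb(dout * cache$x, C, HW, B)
  dz2 <- dgate * gate * (1 - gate)
  dW2 <- dz2 %*% t(cache$a)
  db2 <- rowSums(dz2)
  da <- t(params$f2$W) %*% dz2
  dz1 <- da * cache$pos
  dW1 <- dz1 %*% t(cache$pooled)
  db1 <- rowSums(dz1)
  dpool <- t(params$f1$W) %*% dz1              # (C, B)
  list(dx = dx + bcast_cb(dpool / HW, d),
       grads = list(f1 = list(W = dW1, b = db1), f2 = list(W = dW2, b = db2)))
}

## ---- hybrid attention unit --------------------------------------------------

ha_fwd <- function(params, x, acfg) {
  ms <- msa_fwd(params$msa, x, acfg)
  ca <- ca_fwd(params$ca, x)
  s <- ms$out + ca$out
  ln <- ln_fwd(params$ln, s)
  ml <- mlp_fwd(params$mlp, ln$out)
  out <- if (acfg$residual_skip) x + ml$out else ml$out
  list(out = out, cache = list(msa = ms$cache, ca = ca$cache,
                               ln = ln$cache, mlp = ml$cache))
}

ha_bwd <- function(params, cache, dout, acfg) {
  ml <- mlp_bwd(params$mlp, cache$mlp, dout)
  ln <- ln_bwd(params$ln, cache$ln, ml$dx)
  ms <- msa_bwd(params$msa, cache$msa, ln$dx, acfg)
  ca <- ca_bwd(params$ca, cache$ca, ln$dx)
  dx <- ms$dx + ca$dx
  if (acfg$residual_skip) dx <- dx + dout
  list(dx = dx, grads = list(msa = ms$grads, ca = ca$grads,
                             ln = ln$grads, mlp = ml$grads))
}

## ---- exported user-facing wrappers ------------------------------------------

wrap_unary <- function(x, f) {
  check_fmap(x)
  w4 <- as_fmap4(x)
  drop_batch(f(w4$x), w4$had_batch)
}

#' Multi-head self-attention over spatial positions
#'
#' Flattens the positions of each (optionally windowed) region into tokens of
#' dimension `C` and applies standard scaled dot-product attention with
#' `heads` heads. Attention weights per query are non-negative and sum to 1.
#' No positional encoding is used.
#'
#' @param x feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param cfg an [attention_config()] with matching `channels`.
#' @param params optional parameter list (from `ha_init()$msa`); freshly
#'   initialised if missing.
#' @return feature map of identical shape.
#' @export
multi_head_self_attention <- function(x, cfg = attention_config(dim(x)[1]),
                                      params = NULL) {
  if (dim(x)[1] != cfg$channels)
    stop_input("input channels != cfg$channels")
  if (is.null(params)) params <- ha_init(cfg$channels, cfg)$msa
  wrap_unary(x, function(x4) msa_fwd(params, x4, cfg)$out)
}

#' Channel attention (squeeze-and-excitation gate)
#'
#' Globally average-pools each channel, passes the descriptor through a
#' two-layer bottleneck (`C -> C/r -> C`) and a sigmoid, and rescales each
#' channel by its gate in (0, 1).
#'
#' @inheritParams multi_head_self_attention
#' @return feature map of identical shape.
#' @export
channel_attention <- function(x, cfg = attention_config(dim(x)[1]),
                              params = NULL) {
  if (dim(x)[1] != cfg$channels) stop_input("input channels != cfg$channels")
  if (is.null(params)) params <- ha_init(cfg$channels, cfg)$ca
  wrap_unary(x, function(x4) ca_fwd(params, x4)$out)
}

#' Hybrid attention unit
#'
#' `MLP(Norm(MSA(x) + CA(x)))`, optionally with a residual skip around the
#' unit. The two attention paths read the same input in parallel.
#'
#' @inheritParams multi_head_self_attention
#' @param params optional full HA parameter list (from `ha_init()`).
#' @return feature map of identical shape.
#' @export
hybrid_attention <- function(x, cfg = attention_config(dim(x)[1]),
                             params = NULL) {
  if (dim(x)[1] != cfg$channels) stop_input("input channels != cfg$channels")
  if (is.null(params)) params <- ha_init(cfg$channels, cfg)
  wrap_unary(x, function(x4) ha_fwd(params, x4, cfg)$out)
}
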