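# Hybrid attention: parallel MSA + CA, normalised, through an MLP.

test_that("attention_config validates divisibility and bottleneck", {
  expect_error(attention_config(10L, heads = 4L), "divisible")
  cfg <- attention_config(8L, heads = 2L, ca_reduction = 16L)
  expect_gte(cfg$ca_hidden, 1L)
})

test_that("identical tokens yield identical MSA outputs", {
  cfg <- attention_config(6L, heads = 2L, window = "full")
  x <- array(rep(rnorm(6), 5 * 4), c(6L, 5L, 4L))   # every position identical
  out <- withr::with_seed(1, multi_head_self_attention(x, cfg))
  ref <- out[, 1, 1]
  for (i in 1:5) for (j in 1:4) expect_equal(out[, i, j], ref, tolerance = 1e-12)
})

test_that("MSA preserves shape with windowing and padding", {
  cfg <- attention_config(16L, heads = 4L, window = 8L)
  x <- rand_fmap(16L, 8L, 8L, seed = 1)
  expect_identical(dim(withr::with_seed(1, multi_head_self_attention(x, cfg))),
                   dim(x))
  # non-divisible spatial extent exercises the padding path
  x2 <- rand_fmap(16L, 11L, 5L, seed = 2)
  expect_identical(dim(withr::with_seed(1, multi_head_self_attention(x2, cfg))),
                   dim(x2))
})

test_that("attention weights match a hand-computed 2-token softmax", {
  # 2 channels, 1 head, two tokens; hand-set projections
  cfg <- attention_config(2L, heads = 1L, window = "full")
  Wq <- matrix(c(1, 0, 0, 1), 2, 2)      # identity
  Wk <- matrix(c(0.5, -0.2, 0.3, 1), 2, 2, byrow = TRUE)
  Wv <- matrix(c(2, 0, 0, -1), 2, 2, byrow = TRUE)
  params <- list(q = list(W = Wq, b = c(0, 0)), k = list(W = Wk, b = c(0, 0)),
                 v = list(W = Wv, b = c(0, 0)),
                 o = list(W = diag(2), b = c(0, 0)))
  x <- array(c(1, 2, -1, 0.5), c(2L, 1L, 2L))   # tokens t1=(1,2), t2=(-1,0.5)
  st <- hffen:::msa_fwd(params, array(x, c(2, 1, 2, 1)), cfg)
  # oracle: straight from the definition
  X <- rbind(c(1, 2), c(-1, 0.5))
  Q <- X %*% t(Wq); K <- X %*% t(Wk); V <- X %*% t(Wv)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- A %*% V
  expect_equal(matrix(st$cache$A[, , 1], 2, 2), A, tolerance = 1e-12)
  expect_equal(st$out[, 1, 1, 1], O[1, ], tolerance = 1e-12)
  expect_equal(st$out[, 1, 2, 1], O[2, ], tolerance = 1e-12)
  # weights per query are a probability distribution
  expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
})

test_that("attention rows always sum to one", {
  cfg <- attention_config(8L, heads = 2L, window = 4L)
  params <- withr::with_seed(3, hffen:::ha_init(8L, cfg))
  x <- rand_fmap(8L, 7L, 9L, 1L, seed = 4)
  st <- hffen:::msa_fwd(params$msa, x, cfg)
  sums <- apply(st$cache$A, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("channel gates are symmetric, bounded, and 0.5 at zero weights", {
  cfg <- attention_config(6L, heads = 2L, ca_reduction = 2L)
  # channel-symmetric weights + identical channels -> equal gates
  one <- matrix(rnorm(8 * 8), 8, 8)
  x <- array(rep(one, 6), c(8L, 8L, 6L))
  x <- aperm(x, c(3, 1, 2))
  params <- withr::with_seed(5, hffen:::ha_init(6L, cfg))
  # make every channel's pathway identical: equal rows in both layers
  params$ca$f1$W <- matrix(rep(params$ca$f1$W[1, ], each = 3), 3, 6)
  params$ca$f2$W <- matrix(rep(params$ca$f2$W[1, ], each = 6), 6, 3)
  params$ca$f1$b[] <- 0.1
  params$ca$f2$b[] <- -0.2
  st <- hffen:::ca_fwd(params$ca, array(x, c(6, 8, 8, 1)))
  gates <- st$cache$gate
  expect_equal(max(gates) - min(gates), 0, tolerance = 1e-12)
  expect_true(all(gates > 0 & gates < 1))
  # gates bounded for arbitrary (asymmetric) weights too
  st2 <- hffen:::ca_fwd(withr::with_seed(5, hffen:::ha_init(6L, cfg))$ca,
                        rand_fmap(6L, 8L, 8L, 1L, seed = 55, sd = 10))
  expect_true(all(st2$cache$gate > 0 & st2$cache$gate < 1))
  # zero bottleneck weights -> every gate exactly 0.5, output x/2
  pz <- list(f1 = list(W = matrix(0, 3, 6), b = rep(0, 3)),
             f2 = list(W = matrix(0, 6, 3), b = rep(0, 6)))
  y <- rand_fmap(6L, 5L, 5L, 1L, seed = 6)
  stz <- hffen:::ca_fwd(pz, y)
  expect_equal(stz$cache$gate, matrix(0.5, 6, 1), tolerance = 1e-15)
  expect_equal(stz$out, y / 2, tolerance = 1e-15)
})

test_that("hybrid attention is MLP(Norm(MSA + CA)) over a shared input", {
  cfg <- attention_config(8L, heads = 2L, ca_reduction = 2L, window = 4L)
  params <- withr::with_seed(7, hffen:::ha_init(8L, cfg))
  x <- rand_fmap(8L, 12L, 12L, 1L, seed = 8)
  out <- hffen:::ha_fwd(params, x, cfg)$out
  # recompute both parallel paths independently and chain the tail
  s <- hffen:::msa_fwd(params$msa, x, cfg)$out + hffen:::ca_fwd(params$ca, x)$out
  want <- hffen:::mlp_fwd(params$mlp, hffen:::ln_fwd(params$ln, s)$out)$out
  expect_equal(out, want, tolerance = 1e-10)
  expect_identical(dim(out), dim(x))
  # with the skip toggle the same unit adds its input
  cfg2 <- attention_config(8L, heads = 2L, ca_reduction = 2L, window = 4L,
                           residual_skip = TRUE)
  out2 <- hffen:::ha_fwd(params, x, cfg2)$out
  expect_equal(out2, want + x, tolerance = 1e-10)
})

test_that("batch items do not interact", {
  cfg <- attention_config(8L, heads = 2L, window = 4L)
  params <- withr::with_seed(9, hffen:::ha_init(8L, cfg))
  x1 <- rand_fmap(8L, 8L, 8L, 1L, seed = 10)
  xb <- array(c(x1, x1), c(8L, 8L, 8L, 2L))
  out <- hffen:::ha_fwd(params, xb, cfg)$out
  expect_equal(out[, , , 1], out[, , , 2], tolerance = 1e-12)
})

test_that("full attention is equivariant to circular token shifts", {
  cfg <- attention_config(6L, heads = 3L, window = "full")
  params <- withr::with_seed(11, hffen:::ha_init(6L, cfg))
  x <- rand_fmap(6L, 5L, 5L, 1L, seed = 12)
  out <- hffen:::msa_fwd(params$msa, x, cfg)$out
  # shift rows circularly by 2
  sh <- function(a) a[, c(4:5, 1:3), , , drop = FALSE]
  out_sh <- hffen:::msa_fwd(params$msa, sh(x), cfg)$out
  expect_equal(out_sh, sh(out), tolerance = 1e-10)
})

test_that("shapes and finiteness hold across a config sweep", {
  for (C in c(16L, 32L)) for (h in c(1L, 2L, 4L)) {
    cfg <- attention_config(C, heads = h, window = 4L)
    params <- withr::with_seed(C + h, hffen:::ha_init(C, cfg))
    x <- rand_fmap(C, 6L, 10L, 1L, seed = C * h)
    out <- hffen:::ha_fwd(params, x, cfg)$out
    expect_identical(dim(out), dim(x))
    expect_true(all(is.finite(out)))
  }
})
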