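# End-to-end HFFEN assembly: shallow conv, cascaded modules, reconstruction.

test_that("config invariants: scale set, module count, ablation coupling", {
  expect_error(hffen_config(5L), "scale")
  expect_error(hffen_config(2L, n_modules = 0L), "n_modules")
  expect_error(hffen_config(2L, hiem_depth = 0L), "hiem_depth")
  cfg <- hffen_config(2L, use_hiem = FALSE, use_ha = FALSE)
  expect_false(cfg$use_hf)   # nothing left in the branch
})

test_that("shallow extraction is a shape-preserving 3x3 conv, linear in x", {
  cfg <- tiny_cfg(channels = 16L)
  p <- withr::with_seed(1, hffen:::init_conv(16L, 3L, 3L))
  x <- rand_fmap(3L, 48L, 48L, seed = 1, sd = 0.3)
  f0 <- shallow_extract(x, p, cfg)
  expect_identical(dim(f0), c(16L, 48L, 48L))
  expect_error(shallow_extract(rand_fmap(4L, 8L, 8L)), "3-channel")
  # zero input with zero-bias weights -> zero output
  expect_true(all(shallow_extract(array(0, c(3L, 8L, 8L)), p, cfg) == 0))
  # linearity for bias-free weights: f(2x) = 2 f(x)
  expect_equal(shallow_extract(2 * x, p, cfg), 2 * f0, tolerance = 1e-12)
})

test_that("module fusion is the sum of two branches reading one input", {
  cfg <- tiny_cfg(channels = 8L)
  bb <- hffen:::get_backbone(cfg$backbone)
  params <- withr::with_seed(2, list(
    sr = bb$init(8L, cfg$backbone_blocks, "he"),
    hf = hffen:::hffe_init(8L, cfg)))
  x <- rand_fmap(8L, 24L, 24L, seed = 3)
  fused <- hf_fe_sr_module(x, cfg, params)
  expect_identical(dim(fused), dim(x))
  # branch-wise recomputation oracle
  f_sr <- residual_refine(x, params$sr)
  f_hf <- hf_fe_branch(x, params$hf, cfg)
  expect_equal(fused, f_sr + f_hf, tolerance = 1e-10)
  # with the HF branch output forced to zero, F_n equals the backbone output
  pz <- params
  pz$hf <- hffen:::hffe_init(8L, cfg, init = "zero")
  expect_equal(hf_fe_sr_module(x, cfg, pz), f_sr, tolerance = 1e-12)
})

test_that("pixel shuffle matches the brute-force index oracle", {
  # channel c holds constant value c: 2x2 sub-blocks tile by channel order
  x <- array(rep(0:3, 2 * 2), c(4L, 2L, 2L))
  for (c in 1:4) x[c, , ] <- c - 1
  got <- pixel_shuffle(x, 2L)
  expect_equal(got, pixel_shuffle_oracle(x, 2L))
  expect_equal(got[1, 1:2, 1:2], matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE))
  # random content, r = 2 and 3
  for (r in 2:3) {
    y <- rand_fmap(2L * r * r, 3L, 4L, seed = r)
    expect_equal(pixel_shuffle(y, r), pixel_shuffle_oracle(y, r))
    # element count conserved
    expect_identical(length(pixel_shuffle(y, r)), length(y))
  }
})

test_that("reconstruction upsamples to exactly scale x input size", {
  cfg <- hffen_config(2L, channels = 64L)
  fd <- rand_fmap(64L, 48L, 48L, seed = 4, sd = 0.1)
  f0 <- rand_fmap(64L, 48L, 48L, seed = 5, sd = 0.1)
  p <- withr::with_seed(6, list(
    up = list(hffen:::init_conv(256L, 64L, 3L)),
    final = hffen:::init_conv(3L, 64L, 3L)))
  out <- reconstruct(fd, f0, cfg, p)
  expect_identical(dim(out), c(3L, 96L, 96L))
  expect_error(reconstruct(fd, f0[, 1:10, , drop = FALSE], cfg, p),
               "identical shapes")
})

test_that("forward meets the exact-scale contract over a size sweep", {
  for (s in c(2L, 3L, 4L)) {
    cfg <- tiny_cfg(scale = s, channels = 8L)
    net <- hffen_net(cfg, seed = s)
    for (H in c(17L, 32L, 48L)) for (W in c(17L, 32L)) {
      img <- withr::with_seed(H + W, array(runif(H * W * 3, 0, 255),
                                           c(H, W, 3L)))
      sr <- sr_apply(net, img)
      expect_identical(dim(sr), c(s * H, s * W, 3L))
      expect_true(all(sr >= 0 & sr <= 255))
    }
  }
})

test_that("odd sizes pass through the attention padding unharmed", {
  cfg <- tiny_cfg(scale = 3L, channels = 8L)
  net <- hffen_net(cfg, seed = 1)
  img <- withr::with_seed(1, array(runif(41 * 37 * 3, 0, 255), c(41L, 37L, 3L)))
  expect_identical(dim(sr_apply(net, img)), c(123L, 111L, 3L))
})

test_that("inference is deterministic", {
  cfg <- tiny_cfg(channels = 8L)
  net <- hffen_net(cfg, seed = 2)
  img <- withr::with_seed(3, array(runif(20 * 20 * 3, 0, 255), c(20L, 20L, 3L)))
  expect_identical(sr_apply(net, img), sr_apply(net, img))
})

test_that("disabling the HF-FE branch equals the bare backbone cascade", {
  cfg <- tiny_cfg(channels = 8L, use_hf = FALSE)
  net <- hffen_net(cfg, seed = 7)
  for (i in 1:10) {
    x <- rand_fmap(3L, 12L, 12L, 1L, seed = i, sd = 0.3)
    a <- hffen:::net_forward(net$params, net$cfg, x)$out
    b <- hffen:::backbone_cascade_forward(net, x)
    expect_equal(a, b, tolerance = 1e-14)
  }
})

test_that("the global skip keeps the shallow path alive", {
  cfg <- tiny_cfg(channels = 8L)
  net <- hffen_net(cfg, seed = 8)
  # zero every module and the aggregation conv; keep head and upsampler
  net$params$modules <- hffen:::tree_zeros_like(net$params$modules)
  net$params$agg$W[] <- 0; net$params$agg$b[] <- 0
  x <- rand_fmap(3L, 16L, 16L, 1L, seed = 9, sd = 0.3)
  out <- hffen:::net_forward(net$params, net$cfg, x)$out
  # expected: upsampler applied to F0 alone (agg contributes zero)
  f0 <- hffen:::conv_fwd(net$params$head, x)$out
  g <- f0
  for (s in seq_along(net$params$up))
    g <- pixel_shuffle(hffen:::conv_fwd(net$params$up[[s]], g)$out,
                       hffen:::upsample_factors(cfg)[s])
  want <- hffen:::conv_fwd(net$params$final, g)$out
  expect_equal(out, want, tolerance = 1e-12)
})

test_that("gradients reach the first module and the last MLP", {
  cfg <- tiny_cfg(channels = 8L)
  net <- hffen_net(cfg, seed = 10)
  img <- generate_leaf(scene_spec(size = 64L, seed = 1))
  hr <- aperm(img, c(3, 1, 2)) / 255
  lr <- aperm(bicubic_downsample(img, 2L), c(3, 1, 2)) / 255
  dim(hr) <- c(dim(hr), 1L); dim(lr) <- c(dim(lr), 1L)
  fw <- hffen:::net_forward(net$params, net$cfg, lr, want_cache = TRUE)
  grads <- hffen:::net_backward(net$params, net$cfg, fw$cache,
                                hffen:::l1_loss_grad(fw$out, hr))
  g_first <- sqrt(hffen:::tree_sumsq(grads$modules[[1]]))
  g_mlp <- sqrt(hffen:::tree_sumsq(
    grads$modules[[cfg$n_modules]]$hf$ha$mlp))
  expect_gt(g_first, 0)
  expect_gt(g_mlp, 0)
})

test_that("sr init starts the network as a near-bilinear upsampler", {
  cfg <- hffen_config(2L, channels = 16L, n_modules = 2L,
                      backbone_blocks = 2L)
  net <- hffen_net(cfg, seed = 11, init = "sr")
  img <- generate_leaf(scene_spec(size = 96L, seed = 3))
  sr <- sr_apply(net, bicubic_downsample(img, 2L))
  ys <- rgb_to_y(sr); yh <- rgb_to_y(img)
  expect_gt(psnr(ys, yh, 255), 25)   # far above a random map (~8 dB)
})

test_that("custom backbones must honour the interface", {
  expect_error(register_backbone("bogus", list(init = identity)),
               "must provide")
  # a registered shape-preserving backbone slots in
  register_backbone("double3", list(
    init = function(channels, blocks, init = "he") list(s = array(2, 1)),
    forward = function(params, x) list(out = x * params$s[1], cache = NULL),
    backward = function(params, cache, dout)
      list(dx = dout * params$s[1], grads = list(s = array(0, 1))),
    complexity = function(channels, blocks, H, W) list(params = 1, madds = 0)))
  cfg <- tiny_cfg(channels = 8L, backbone = "double3", use_hf = FALSE)
  net <- hffen_net(cfg, seed = 12)
  x <- rand_fmap(3L, 8L, 8L, 1L, seed = 13)
  expect_identical(dim(hffen:::net_forward(net$params, cfg, x)$out),
                   c(3L, 16L, 16L, 1L))
})
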