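# Optimisation protocol: L1, Adam, LR halving, clipping, resumability.

test_that("l1 loss matches its definition", {
  a <- rand_fmap(3L, 8L, 8L, 2L, seed = 1)
  expect_identical(l1_loss(a, a), 0)
  expect_equal(l1_loss(a + 0.1, a), 0.1, tolerance = 1e-12)
  b <- rand_fmap(3L, 8L, 8L, 2L, seed = 2)
  expect_equal(l1_loss(a, b), mean(abs(a - b)), tolerance = 1e-14)
  expect_error(l1_loss(a, b[, 1:4, , ]), "shape")
})

test_that("the learning rate follows the closed-form halving schedule", {
  cfg <- train_config(2L, "paper", seed = 1)
  expect_equal(lr_at(0L, cfg), 1e-4)
  expect_equal(lr_at(99999L, cfg), 1e-4)
  expect_equal(lr_at(100000L, cfg), 5e-5)
  expect_equal(lr_at(350000L, cfg), 1.25e-5)
})

test_that("gradient clipping bounds the global norm, preserving direction", {
  g <- list(a = matrix(c(3, 4), 1), b = array(0, c(2, 2)))
  cl <- clip_gradients(g, 5)                      # norm exactly 5: untouched
  expect_false(cl$scaled)
  expect_identical(cl$grads, g)
  small <- list(a = matrix(c(1.2, 1.6), 1))       # norm 2 < 5
  expect_false(clip_gradients(small, 5)$scaled)
  big <- hffen:::tree_map(function(x) x * 10, g)  # norm 50
  cl2 <- clip_gradients(big, 5)
  expect_true(cl2$scaled)
  expect_equal(sqrt(hffen:::tree_sumsq(cl2$grads)), 5, tolerance = 1e-12)
  expect_equal(cl2$grads$a, big$a * 0.1, tolerance = 1e-12)
  zero <- list(a = matrix(0, 2, 2))
  expect_identical(clip_gradients(zero, 5)$grads, zero)
  expect_error(clip_gradients(list(a = matrix(NaN, 1, 1)), 5), "non-finite")
})

make_toy_run <- function(total_iters, seed = 1, init = "sr", resume = NULL,
                         ckpt = NULL, every = 0L) {
  imgs <- synth_images(8, base_seed = 80, scene_spec(size = 64L))
  man <- split_dataset(names(imgs), seed = 3)
  cfg <- tiny_cfg(channels = 8L)
  net <- hffen_net(cfg, seed = seed, init = init)
  tcfg <- train_config(2L, "mini", seed = seed, total_iters = total_iters,
                       batch_size = 2L, patch_size = 32L)
  train_hffen(net, imgs, man, tcfg, checkpoint_path = ckpt,
              checkpoint_every = every, resume = resume)
}

test_that("a smoke run logs schedule-consistent, clip-bounded iterations", {
  fit <- make_toy_run(12L, init = "he")
  tr <- fit$trace
  expect_identical(nrow(tr), 12L)
  tcfg <- train_config(2L, "mini", seed = 1)
  expect_equal(tr$lr, vapply(tr$iter - 1L, lr_at, 0, cfg = tcfg))
  expect_true(all(tr$grad_norm_post <= tcfg$clip_norm + 1e-9))
  expect_true(all(is.finite(tr$loss)))
})

test_that("training is seeded-deterministic and resumable bit-for-bit", {
  full <- make_toy_run(10L)
  again <- make_toy_run(10L)
  expect_identical(full$net$params, again$net$params)
  expect_identical(full$trace, again$trace)
  # run 5, checkpoint, resume to 10: identical weights and trace
  td <- withr::local_tempfile(fileext = ".rds")
  make_toy_run(5L, ckpt = td)
  ck <- load_checkpoint(td)
  expect_identical(ck$iter, 5L)
  resumed <- make_toy_run(10L, resume = ck)
  expect_identical(resumed$net$params, full$net$params)
  expect_identical(resumed$trace, full$trace)
})

test_that("checkpoints are self-describing and validated", {
  td <- withr::local_tempfile(fileext = ".rds")
  make_toy_run(3L, ckpt = td)
  ck <- load_checkpoint(td)
  expect_s3_class(ck$net, "hffen_net")
  expect_identical(ck$seed, 1L)
  # corrupting a field is named in the diagnostic
  bad <- readRDS(td)
  bad$adam_state <- NULL
  saveRDS(bad, td)
  expect_error(load_checkpoint(td), "adam_state")
})

test_that("a mismatched-scale pair aborts immediately", {
  cfg <- tiny_cfg(channels = 8L, scale = 2L)
  net <- hffen_net(cfg, seed = 1)
  tcfg <- train_config(2L, "mini", seed = 1)
  batch_x3 <- list(lr = rand_fmap(3L, 16L, 16L, 1L, seed = 1),
                   hr = rand_fmap(3L, 48L, 48L, 1L, seed = 2))
  st <- hffen:::adam_init(net$params)
  expect_error(hffen:::train_step(net, batch_x3, st, 1e-4, tcfg),
               "scale mismatch")
  # and one model never trains for another scale
  tcfg3 <- train_config(3L, "mini", seed = 1)
  imgs <- synth_images(6, base_seed = 90, scene_spec(size = 64L))
  man <- split_dataset(names(imgs), seed = 1)
  expect_error(train_hffen(net, imgs, man, tcfg3), "model scale")
})

test_that("a non-finite loss aborts with the last good state retained", {
  imgs <- synth_images(6, base_seed = 95, scene_spec(size = 64L))
  man <- split_dataset(names(imgs), seed = 1)
  cfg <- tiny_cfg(channels = 8L)
  net <- hffen_net(cfg, seed = 1)
  net$params$head$W[1, 1] <- 1e300          # forces an overflow forward
  tcfg <- train_config(2L, "mini", seed = 1, total_iters = 5L,
                       batch_size = 2L, patch_size = 32L)
  expect_warning(fit <- train_hffen(net, imgs, man, tcfg), "non-finite")
  expect_true(fit$aborted)
  expect_s3_class(fit$net, "hffen_net")
})
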