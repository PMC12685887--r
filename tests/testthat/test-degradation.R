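# Data protocol: seeded split, patch extraction, dihedral augmentation,
# bicubic degradation.

test_that("seeded 80/20 split partitions deterministically", {
  ids <- sprintf("img%03d", 1:100)
  m1 <- split_dataset(ids, seed = 42)
  m2 <- split_dataset(ids, seed = 42)
  expect_identical(m1$train_ids, m2$train_ids)
  expect_identical(m1$test_ids, m2$test_ids)
  expect_length(m1$train_ids, 80L)
  expect_length(m1$test_ids, 20L)
  # partition property across sizes
  for (n in c(5L, 13L, 57L)) {
    m <- split_dataset(seq_len(n), seed = n)
    expect_length(intersect(m$train_ids, m$test_ids), 0L)
    expect_setequal(c(m$train_ids, m$test_ids), seq_len(n))
  }
  expect_error(split_dataset(1:4, seed = 1), "at least 5")
  # a different seed reshuffles
  expect_false(identical(split_dataset(ids, 1)$train_ids,
                         split_dataset(ids, 2)$train_ids))
})

test_that("manifests round-trip through JSON", {
  m <- split_dataset(sprintf("leaf_%02d", 1:20), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_identical(m2$train_ids, m$train_ids)
  expect_identical(m2$test_ids, m$test_ids)
  expect_identical(m2$seed, m$seed)
})

test_that("patch extraction crops uniformly and records provenance", {
  img <- withr::with_seed(1, array(runif(500 * 400 * 3, 0, 255),
                                   c(500L, 400L, 3L)))
  withr::with_seed(2, {
    for (i in 1:20) {
      p <- extract_patch(img, 192L, id = "a")
      prov <- attr(p, "provenance")
      expect_identical(dim(p), c(192L, 192L, 3L))
      expect_true(prov$y0 >= 0 && prov$y0 <= 308)
      expect_true(prov$x0 >= 0 && prov$x0 <= 208)
      # crop content equals the source sub-array at the recorded offsets
      expect_identical(p[1, 1, ], img[prov$y0 + 1, prov$x0 + 1, ])
      expect_identical(unclass(p)[, , ],
                       img[prov$y0 + seq_len(192), prov$x0 + seq_len(192), ],
                       ignore_attr = TRUE)
    }
  })
  # exact-size image: single valid position
  small <- img[1:192, 1:192, , drop = FALSE]
  p <- withr::with_seed(3, extract_patch(small, 192L))
  expect_identical(attr(p, "provenance")[c("y0", "x0")], list(y0 = 0L, x0 = 0L))
  expect_warning(extract_patch(img[1:100, , , drop = FALSE], 192L), "skipped")
})

test_that("dihedral augmentation realises the full group of order 8", {
  patch <- withr::with_seed(4, array(runif(8 * 8 * 3), c(8L, 8L, 3L)))
  expect_identical(augment(patch, 0L), patch, ignore_attr = TRUE)
  # horizontal flip is an involution
  expect_equal(augment(augment(patch, 4L), 4L), patch, ignore_attr = TRUE)
  # four rotations compose to the identity
  r <- patch
  for (i in 1:4) r <- augment(r, 1L)
  expect_equal(r, patch, ignore_attr = TRUE)
  # the 8 images of an asymmetric patch are pairwise distinct
  outs <- lapply(0:7, function(op) augment(patch, op))
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(isTRUE(all.equal(outs[[i]], outs[[j]])))
  expect_error(augment(patch, 8L), "0..7")
  expect_error(augment(array(0, c(4L, 5L, 3L)), 1L), "square")
})

test_that("bicubic downsampling meets the protocol contracts", {
  img <- withr::with_seed(5, array(runif(192 * 192 * 3, 40, 200),
                                   c(192L, 192L, 3L)))
  expect_identical(dim(bicubic_downsample(img, 3L)), c(64L, 64L, 3L))
  # constants are reproduced exactly
  flat <- array(123, c(48L, 48L, 3L))
  expect_equal(bicubic_downsample(flat, 2L), array(123, c(24L, 24L, 3L)),
               tolerance = 1e-12)
  # mean intensity preserved for a smooth image
  smooth <- generate_leaf(scene_spec(size = 96L, seed = 6, venation_density = 0,
                                     lesion_count = 0L,
                                     serration_amplitude = 0,
                                     background_noise_sd = 0))
  lr <- bicubic_downsample(smooth, 2L)
  expect_lt(abs(mean(lr) - mean(smooth)), 0.5)
  # non-divisible dims are cropped, with a message
  odd <- img[1:191, 1:190, , drop = FALSE]
  expect_message(out <- bicubic_downsample(odd, 2L), "divisibility")
  expect_identical(dim(out), c(95L, 95L, 3L))
})

test_that("bicubic commutes with quarter-turn rotations", {
  img <- generate_leaf(scene_spec(size = 96L, seed = 7))
  rot <- augment(img, 1L)
  a <- bicubic_downsample(rot, 2L)
  b <- augment(bicubic_downsample(img, 2L), 1L)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("patch pairs keep the exact scale relation and direction", {
  hr <- withr::with_seed(8, extract_patch(
    generate_leaf(scene_spec(size = 96L, seed = 8)), 48L, id = "leaf_x"))
  pp <- patch_pair(hr, 3L)
  expect_s3_class(pp, "patch_pair")
  expect_identical(dim(pp$hr)[1:2], 3L * dim(pp$lr)[1:2])
  expect_identical(pp$provenance$id, "leaf_x")
  # the LR member is the bicubic image of the HR member
  expect_equal(pp$lr, bicubic_downsample(hr, 3L), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the batch schedule is deterministic and leakage-free", {
  man <- split_dataset(sprintf("leaf_%04d", 1:50), seed = 9)
  s1 <- hffen:::build_schedule(man$train_ids, 20L, 4L, seed = 10)
  s2 <- hffen:::build_schedule(man$train_ids, 20L, 4L, seed = 10)
  expect_identical(s1, s2)
  expect_true(all(s1$id %in% man$train_ids))
  expect_silent(audit_no_leakage(man, s1$id))
  expect_error(audit_no_leakage(man, c(s1$id, man$test_ids[1])), "leakage")
})
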