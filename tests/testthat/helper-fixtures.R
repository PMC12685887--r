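# Shared fixtures and independent oracles used across the suite.

# deterministic random feature map
rand_fmap <- function(C, H, W, B = NULL, seed = 1, sd = 1) {
  n <- C * H * W * max(1, B %||% 1)
  withr::with_seed(seed, {
    x <- array(rnorm(n, sd = sd), c(C, H, W, if (is.null(B)) NULL else B))
  })
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny network config used wherever the architecture itself is under test
tiny_cfg <- function(scale = 2L, channels = 8L, ...) {
  hffen_config(scale, channels = channels, n_modules = 1L,
               backbone_blocks = 1L, hiem_depth = 1L, heads = 2L,
               ca_reduction = 4L, window = 4L, ...)
}

# brute-force direct 2-D convolution oracle (independent of the C++ path):
# plain loops, explicit padding.
conv2d_oracle <- function(x, kern, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  H <- nrow(x); W <- ncol(x); k <- nrow(kern); p <- (k - 1) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - p; jj <- j + kj - 1 - p
      if (padding == "zero") {
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        acc <- acc + kern[ki, kj] * x[ii, jj]
      } else {
        acc <- acc + kern[ki, kj] * x[refl(ii, H), refl(jj, W)]
      }
    }
    out[i, j] <- acc
  }
  out
}

# brute-force pixel-shuffle oracle: enumerate the channel-to-space index map
pixel_shuffle_oracle <- function(x, r) {
  d <- dim(x)
  C <- d[1] %/% (r * r); H <- d[2]; W <- d[3]
  out <- array(0, c(C, r * H, r * W))
  for (c in 0:(C - 1)) for (i in 0:(r - 1)) for (j in 0:(r - 1))
    for (h in 0:(H - 1)) for (w in 0:(W - 1))
      out[c + 1, r * h + i + 1, r * w + j + 1] <-
        x[c * r * r + i * r + j + 1, h + 1, w + 1]
  out
}

# a small venation-textured grayscale patch and a Gaussian-blurred copy
textured_patch <- function(S = 24, seed = 5) {
  img <- generate_leaf(scene_spec(size = 96L, seed = seed))
  g <- apply(img, c(1, 2), mean)
  g[seq_len(S) + 30, seq_len(S) + 30]
}

gauss_blur <- function(x, sigma = 2) {
  r <- 3L
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m) m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ]
  xr <- pad(x)
  xr <- apply(xr, 2, function(col) stats::filter(col, k, sides = 2))
  xr <- xr[r + seq_len(nrow(x)), ]
  xc <- t(pad(t(xr)))
  xc <- t(apply(xc, 1, function(row) stats::filter(row, k, sides = 2)))
  xc[, r + seq_len(ncol(x))]
}

# SSIM reference via scikit-image (independent implementation), one python
# call for a whole batch of matrix pairs
skimage_ssim <- function(pairs) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  for (i in seq_along(pairs)) {
    utils::write.csv(pairs[[i]]$a, file.path(td, sprintf("a%03d.csv", i)),
                     row.names = FALSE)
    utils::write.csv(pairs[[i]]$b, file.path(td, sprintf("b%03d.csv", i)),
                     row.names = FALSE)
  }
  py <- file.path(td, "ssim_ref.py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    "d = sys.argv[1]",
    "for fa in sorted(glob.glob(d + '/a*.csv')):",
    "    fb = fa.replace('/a', '/b')",
    "    a = np.loadtxt(fa, delimiter=',', skiprows=1)",
    "    b = np.loadtxt(fb, delimiter=',', skiprows=1)",
    "    print('%.12f' % ssim(a, b, data_range=255, gaussian_weights=True,",
    "          sigma=1.5, use_sample_covariance=False))"), py)
  out <- system2("python", c(py, td), stdout = TRUE)
  as.numeric(out)
}
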