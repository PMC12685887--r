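# Data protocol: seeded 80/20 split, random HR patch extraction, dihedral
# augmentation, and bicubic LR synthesis at x2/x3/x4. LR images are always
# computed from HR (never the reverse), and LR patches are synthesized
# strictly from the training split.

#' Seeded 80/20 train/test split
#'
#' Shuffles the ids with a fixed seed and assigns the first `floor(0.8 n)` to
#' training, the remainder to testing. Regeneration with the same seed yields
#' identical lists.
#'
#' @param ids character or integer vector of image ids (>= 5).
#' @param seed integer seed.
#' @param fractions train/test fractions; fixed at `c(0.8, 0.2)`.
#' @return an object of class `split_manifest`: `train_ids`, `test_ids`,
#'   `seed`, `fractions`.
#' @export
split_dataset <- function(ids, seed, fractions = c(0.8, 0.2)) {
  n <- length(ids)
  if (n < 5L)
    stop_input("split_dataset: need at least 5 ids (a 20% slice would be empty)")
  if (anyDuplicated(ids)) stop_input("split_dataset: ids must be unique")
  shuffled <- withr::with_seed(seed, sample(ids))
  n_train <- floor(fractions[1] * n)
  structure(list(train_ids = shuffled[seq_len(n_train)],
                 test_ids = shuffled[-seq_len(n_train)],
                 seed = as.integer(seed), fractions = fractions),
            class = "split_manifest")
}

#' Write / read a split manifest
#'
#' @param manifest a `split_manifest`.
#' @param path JSON file path.
#' @return the manifest (invisibly for write).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = m$train_ids, test_ids = m$test_ids,
                 seed = as.integer(m$seed), fractions = as.numeric(m$fractions)),
            class = "split_manifest")
}

#' Random HR patch extraction
#'
#' Uniformly positioned square crop; the crop offset is recorded in the
#' result's `provenance` attribute. Draws from the current RNG stream.
#'
#' @param hr_image `(H, W, 3)` image array.
#' @param size patch side in pixels.
#' @param id source image id recorded in provenance.
#' @return the `size x size` crop, or `NULL` (with a warning) when the image
#'   is undersized.
#' @export
extract_patch <- function(hr_image, size, id = NA) {
  d <- dim(hr_image)
  if (d[1] < size || d[2] < size) {
    warning(sprintf("image %s (%dx%d) smaller than patch size %d: skipped",
                    id, d[1], d[2], size))
    return(NULL)
  }
  y0 <- sample.int(d[1] - size + 1L, 1L) - 1L
  x0 <- sample.int(d[2] - size + 1L, 1L) - 1L
  patch <- hr_image[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
  attr(patch, "provenance") <- list(id = id, y0 = y0, x0 = x0)
  patch
}

#' Dihedral augmentation
#'
#' Applies the `op_id`-th element of the dihedral group of order 8 to a
#' square patch: `op_id` 0..3 are rotations by 0/90/180/270 degrees
#' (counter-clockwise), 4..7 are a horizontal flip followed by the same
#' rotations.
#'
#' @param patch square `(S, S, C)` image array.
#' @param op_id integer in 0..7.
#' @return the transformed patch.
#' @export
augment <- function(patch, op_id) {
  d <- dim(patch)
  if (length(d) != 3L || d[1] != d[2])
    stop_input("augment: patch must be square (S, S, C)")
  if (length(op_id) != 1L || !op_id %in% 0:7)
    stop_input("augment: op_id must be a single integer in 0..7")
  rot90 <- function(a) {            # 90 degrees counter-clockwise
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  fliph <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  out <- patch
  if (op_id >= 4L) out <- fliph(out)
  for (i in seq_len(op_id %% 4L)) out <- rot90(out)
  prov <- attr(patch, "provenance")
  if (!is.null(prov)) { prov$aug <- as.integer(op_id); attr(out, "provenance") <- prov }
  out
}

## ---- bicubic resampling -----------------------------------------------------

# Catmull-Rom style cubic kernel, a = -0.5 (the convention of standard SR
# data-preparation pipelines).
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Row-resampling matrix n_out x n_in. For downscaling the kernel is widened
# by the scale factor (antialias); edge samples are replicated.
resize_matrix <- function(n_in, n_out, antialias = TRUE) {
  s <- n_in / n_out
  ks <- if (antialias && s > 1) s else 1
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * s - 0.5            # source coordinate, zero-based
    lo <- ceiling(u - 2 * ks)
    hi <- floor(u + 2 * ks)
    k <- lo:hi
    w <- cubic_kernel((u - k) / ks)
    w <- w / sum(w)
    kc <- pmin(pmax(k, 0), n_in - 1)    # replicate edges
    for (j in seq_along(k)) A[i, kc[j] + 1L] <- A[i, kc[j] + 1L] + w[j]
  }
  A
}

#' Bicubic resampling of an RGB image
#'
#' Separable cubic-kernel (a = -0.5) resampling with edge replication;
#' downscaling widens the kernel by the scale factor (antialias).
#'
#' @param img `(H, W, C)` image array, values 0..255.
#' @param out_h,out_w target size.
#' @param clamp clamp the result back to 0..255 (default TRUE).
#' @return `(out_h, out_w, C)` array.
#' @export
bicubic_resize <- function(img, out_h, out_w, clamp = TRUE) {
  d <- dim(img)
  A <- resize_matrix(d[1], out_h)
  Bm <- resize_matrix(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% img[, , c] %*% t(Bm)
  if (clamp) { out[out < 0] <- 0; out[out > 255] <- 255 }
  out
}

#' Bicubic degradation (HR -> LR)
#'
#' Standard bicubic downsampling by an integer scale factor; the sole
#' degradation model of the protocol. Non-divisible dimensions are cropped to
#' the largest divisible size first (with a message).
#'
#' @param hr `(H, W, 3)` HR image, values 0..255.
#' @param scale integer factor (2, 3 or 4).
#' @return `(H/scale, W/scale, 3)` LR image.
#' @export
bicubic_downsample <- function(hr, scale) {
  d <- dim(hr)
  h <- (d[1] %/% scale) * scale
  w <- (d[2] %/% scale) * scale
  if (h != d[1] || w != d[2]) {
    message(sprintf("cropping %dx%d to %dx%d for divisibility by %d",
                    d[1], d[2], h, w, scale))
    hr <- hr[seq_len(h), seq_len(w), , drop = FALSE]
  }
  bicubic_resize(hr, h %/% scale, w %/% scale)
}

#' Build an aligned LR/HR patch pair
#'
#' @param hr HR patch (`(s*p, s*p, 3)`).
#' @param scale integer scale factor.
#' @return list of class `patch_pair`: `hr`, `lr`, `scale`, `provenance`.
#' @export
patch_pair <- function(hr, scale) {
  lr <- bicubic_downsample(hr, scale)
  structure(list(hr = hr, lr = lr, scale = as.integer(scale),
                 provenance = attr(hr, "provenance")),
            class = "patch_pair")
}

## ---- deterministic batch schedule ------------------------------------------

# Pre-computes, from one seed, the full (image id, crop offsets, augmentation)
# stream for a training run. Resuming a run regenerates the identical stream,
# and the same schedule can be replayed across ablation variants so all
# variants see the data in the same order.
build_schedule <- function(train_ids, n_iters, batch_size, seed) {
  # drawn one iteration at a time so that a longer run's schedule is a
  # strict prefix extension of a shorter one (required for bit-for-bit
  # resumption from a checkpoint taken mid-run)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_iters), function(t)
      data.frame(iter = t,
                 id = sample(train_ids, batch_size, replace = TRUE),
                 u_y = runif(batch_size), u_x = runif(batch_size),
                 aug = sample(0:7, batch_size, replace = TRUE),
                 stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Materialise one scheduled batch as (3, h, w, B) LR / (3, H, W, B) HR arrays.
schedule_batch <- function(schedule, iter, images, patch_size, scale) {
  rows <- schedule[schedule$iter == iter, , drop = FALSE]
  B <- nrow(rows)
  p <- patch_size
  hr <- array(0, c(3L, p, p, B))
  lr <- array(0, c(3L, p %/% scale, p %/% scale, B))
  for (b in seq_len(B)) {
    img <- images[[rows$id[b]]]
    d <- dim(img)
    y0 <- floor(rows$u_y[b] * (d[1] - p + 1))
    x0 <- floor(rows$u_x[b] * (d[2] - p + 1))
    hp <- img[y0 + seq_len(p), x0 + seq_len(p), , drop = FALSE]
    hp <- augment(hp, rows$aug[b])
    lp <- bicubic_downsample(hp, scale)
    hr[, , , b] <- aperm(hp, c(3, 1, 2)) / 255
    lr[, , , b] <- aperm(lp, c(3, 1, 2)) / 255
  }
  list(lr = lr, hr = hr, ids = rows$id)
}

#' Audit a patch stream for test-set leakage
#'
#' @param manifest a `split_manifest`.
#' @param provenance_ids ids of every patch used in training.
#' @return `TRUE` invisibly; errors when any id lies in the test split.
#' @export
audit_no_leakage <- function(manifest, provenance_ids) {
  leaked <- intersect(unique(provenance_ids), manifest$test_ids)
  if (length(leaked) > 0)
    stop_input("test-set leakage: ids ", paste(leaked, collapse = ", "),
               " appear in the training patch stream")
  invisible(TRUE)
}
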