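# Workflow wrappers: dataset preparation (split + materialised LR/HR trees)
# and the controlled ablation harness comparing the HF-FE variants under
# identical seeds, weights-init and data order.

#' Prepare a dataset directory
#'
#' Splits the images 80/20 with the given seed, writes the manifest, and
#' materialises LR folder trees `X2/ X3/ X4/` (plus `HR/`) for the requested
#' scales. LR images are synthesised from HR only.
#'
#' @param input_dir directory of HR images (PNG), or `NULL` with `n_synth`
#'   to use the synthetic leaf generator.
#' @param out_dir output directory.
#' @param seed split (and synthesis) seed.
#' @param scales integer vector of scale factors.
#' @param n_synth number of synthetic images when `input_dir` is `NULL`.
#' @param spec_template [scene_spec()] template for synthesis.
#' @return the `split_manifest`, invisibly.
#' @export
prepare_dataset <- function(input_dir = NULL, out_dir, seed = 1L,
                            scales = c(2L, 3L, 4L), n_synth = 200L,
                            spec_template = scene_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(input_dir)) {
    images <- synth_images(n_synth, base_seed = seed, spec_template)
  } else {
    files <- list.files(input_dir, pattern = "\\.png$", full.names = TRUE)
    if (length(files) == 0) stop_input("no PNG images found in ", input_dir)
    images <- lapply(files, function(f) png::readPNG(f) * 255)
    names(images) <- sub("\\.png$", "", basename(files))
  }
  manifest <- split_dataset(names(images), seed)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  hr_dir <- file.path(out_dir, "HR")
  dir.create(hr_dir, showWarnings = FALSE)
  for (id in names(images))
    png::writePNG(images[[id]] / 255, file.path(hr_dir, paste0(id, ".png")))
  for (s in scales) {
    sd <- file.path(out_dir, paste0("X", s))
    dir.create(sd, showWarnings = FALSE)
    for (id in names(images)) {
      lr <- bicubic_downsample(images[[id]], s)
      png::writePNG(lr / 255, file.path(sd, paste0(id, ".png")))
    }
  }
  invisible(manifest)
}

#' Load an image directory as a named list
#'
#' @param dir directory of PNG images.
#' @return named list of `(H, W, 3)` arrays with values 0..255.
#' @export
load_images <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f) * 255
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3]
    img
  })
  names(imgs) <- sub("\\.png$", "", basename(files))
  imgs
}

ablation_variants <- list(
  baseline = list(use_hf = FALSE, use_hiem = FALSE, use_ha = FALSE),
  hiem = list(use_hf = TRUE, use_hiem = TRUE, use_ha = FALSE),
  ha = list(use_hf = TRUE, use_hiem = FALSE, use_ha = TRUE),
  hiem_ha = list(use_hf = TRUE, use_hiem = TRUE, use_ha = TRUE))

#' Controlled ablation of the HF-FE components
#'
#' Trains the requested variants (`baseline`, `+HIEM`, `+HA`, `+HIEM+HA`)
#' under identical settings — same weight-initialisation seed, same
#' precomputed batch schedule, same test split — and reports mean Y-channel
#' PSNR/SSIM on the held-out split per variant along with parameter and
#' analytic FLOPs counts. A diverging variant is marked failed; the table is
#' still emitted. A plain-bicubic row is included as the reference point.
#'
#' @param images named list of HR images.
#' @param manifest a `split_manifest` over `names(images)`.
#' @param scale integer scale factor.
#' @param profile architecture/training profile (see [hffen_profile()]).
#' @param seeds integer vector; each seed drives one full train/eval
#'   repetition of every variant. Results are averaged over seeds.
#' @param variants subset of `c("baseline", "hiem", "ha", "hiem_ha")`.
#' @param flops_input input size for the analytic FLOPs column.
#' @param quiet suppress progress output.
#' @return list: `table` (one aggregated row per variant), `runs` (per-seed
#'   rows), `bicubic` (baseline metric report).
#' @export
run_ablation <- function(images, manifest, scale = 2L, profile = "mini",
                         seeds = 1L,
                         variants = c("baseline", "hiem_ha"),
                         flops_input = c(192L, 192L), quiet = TRUE) {
  variants <- match.arg(variants, names(ablation_variants), several.ok = TRUE)
  bic <- evaluate_sr("bicubic", images, manifest$test_ids, scale)
  runs <- list()
  for (seed in seeds) {
    tcfg <- train_config(scale, profile, seed = seed)
    schedule <- build_schedule(manifest$train_ids, tcfg$total_iters,
                               tcfg$batch_size, tcfg$seed)
    for (v in variants) {
      flags <- ablation_variants[[v]]
      cfg <- do.call(hffen_profile,
                     c(list(scale = scale, profile = profile), flags))
      net <- hffen_net(cfg, seed = seed, init = "sr")
      if (!quiet) message("training variant ", v, " (seed ", seed, ")")
      fit <- train_hffen(net, images, manifest, tcfg, schedule = schedule,
                         quiet = quiet)
      cx <- count_complexity(fit$net, flops_input)
      rep <- if (fit$aborted) NULL
             else evaluate_sr(fit$net, images, manifest$test_ids, scale)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = v, seed = seed,
        psnr_db = if (is.null(rep)) NA_real_ else rep$mean_psnr_db,
        ssim = if (is.null(rep)) NA_real_ else rep$mean_ssim,
        parameters = cx$parameters, flops_madds = cx$flops_madds,
        failed = fit$aborted)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$variant), function(d)
    data.frame(variant = d$variant[1],
               psnr_db = mean(d$psnr_db), ssim = mean(d$ssim),
               parameters = d$parameters[1], flops_madds = d$flops_madds[1],
               n_failed = sum(d$failed))))
  agg <- agg[order(match(agg$variant, names(ablation_variants))), ]
  rownames(agg) <- NULL
  list(table = agg, runs = runs, bicubic = bic)
}
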