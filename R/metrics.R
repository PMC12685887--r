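# Evaluation protocol: PSNR and SSIM on the Y (luma) channel, averaged over
# the held-out test split, plus the analytic parameter/FLOPs accounting.
# All comparisons in one run share the same conventions (Y standard, border
# crop), which are embedded in every report.

#' RGB to luma (Y) conversion
#'
#' @param img `(H, W, 3)` array with values 0..255.
#' @param convention `"bt601"` (ITU-R BT.601 studio range, Y in 16..235 — the
#'   convention of standard SR benchmark scripts; default) or `"full"`
#'   (full-range, coefficients 0.299/0.587/0.114 summing to 1).
#' @return `(H, W)` matrix of luma values.
#' @export
rgb_to_y <- function(img, convention = c("bt601", "full")) {
  convention <- match.arg(convention)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop_input("rgb_to_y expects an (H, W, 3) RGB image")
  if (convention == "bt601")
    16 + (65.481 * img[, , 1] + 128.553 * img[, , 2] + 24.966 * img[, , 3]) / 255
  else
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical inputs return `Inf` (a
#' documented sentinel; aggregation skips sentinels with a logged count).
#'
#' @param a,b real arrays of identical shape.
#' @param peak dynamic range (255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = 255) {
  if (!identical(dim(a), dim(b))) stop_input("psnr: shape mismatch")
  if (peak <= 0) stop_input("psnr: peak must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable Gaussian filter with symmetric (edge-including) padding
gauss_filter2 <- function(x, sigma = 1.5, radius = 5L) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  padi <- c(radius:1, 1:n, n:(n - radius + 1))
  xp <- x[padi, , drop = FALSE]
  xr <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  xr <- xr[(radius + 1):(radius + n), , drop = FALSE]
  padj <- c(radius:1, 1:m, m:(m - radius + 1))
  xp2 <- xr[, padj, drop = FALSE]
  xc <- t(apply(xp2, 1, function(row) stats::filter(row, k, sides = 2)))
  xc[, (radius + 1):(radius + m), drop = FALSE]
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sd 1.5), constants
#' `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`, Gaussian-weighted (not
#' sample) covariances, and a border strip of the filter radius excluded
#' from the average.
#'
#' @param a,b real matrices of identical shape, at least 11x11.
#' @param peak dynamic range.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, peak = 255) {
  if (!identical(dim(a), dim(b))) stop_input("ssim: shape mismatch")
  radius <- 5L
  if (nrow(a) < 2 * radius + 1 || ncol(a) < 2 * radius + 1)
    stop_input("ssim: image smaller than the 11x11 window")
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  ux <- gauss_filter2(a); uy <- gauss_filter2(b)
  uxx <- gauss_filter2(a * a); uyy <- gauss_filter2(b * b)
  uxy <- gauss_filter2(a * b)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  core <- S[(radius + 1):(nrow(S) - radius), (radius + 1):(ncol(S) - radius)]
  mean(core)
}

## ---- complexity accounting --------------------------------------------------

# Analytic multiply-add count for one forward pass, layer by layer, traversing
# the architecture symbolically (no forward pass is executed). Convs count
# k^2*Cin*Cout*Hout*Wout; linear layers din*dout*tokens; attention the
# standard QKV + score + weighted-sum terms on the window-padded grid.
complexity_table <- function(cfg, input_size) {
  H <- input_size[1]; W <- input_size[2]
  C <- cfg$channels
  HW <- H * W
  rows <- list()
  add <- function(layer, params, madds)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, params = params,
                                             madds = madds)
  conv_cost <- function(cin, cout, k, hw) list(p = k * k * cin * cout + cout,
                                               m = k * k * cin * cout * hw)
  hd <- conv_cost(3, C, 3, HW)
  add("head", hd$p, hd$m)
  bb <- get_backbone(cfg$backbone)
  if (is.null(bb$complexity))
    stop_input("uncounted layer: backbone '", cfg$backbone,
               "' provides no complexity() entry")
  acfg <- cfg$ha
  w <- acfg$window
  if (identical(w, "full")) { Hp <- H; Wp <- W; Tn <- H * W }
  else {
    Hp <- ceiling(H / w) * w; Wp <- ceiling(W / w) * w; Tn <- w * w
  }
  Np <- Hp * Wp
  for (n in seq_len(cfg$n_modules)) {
    bc <- bb$complexity(C, cfg$backbone_blocks, H, W)
    add(sprintf("module%d.sr", n), bc$params, bc$madds)
    if (cfg$use_hf) {
      if (cfg$use_hiem) {
        add(sprintf("module%d.hf.laplacian", n), 0, 9 * C * HW)
        rc <- conv_cost(C, C, 3, HW)
        add(sprintf("module%d.hf.res", n), cfg$hiem$depth * 2 * rc$p,
            cfg$hiem$depth * 2 * rc$m)
      }
      if (cfg$use_ha) {
        msa_p <- 4 * (C * C + C)
        msa_m <- 4 * C * C * Np + 2 * Tn * C * Np
        add(sprintf("module%d.hf.msa", n), msa_p, msa_m)
        ch <- acfg$ca_hidden
        add(sprintf("module%d.hf.ca", n), C * ch + ch + ch * C + C,
            2 * C * ch + C * HW)
        add(sprintf("module%d.hf.ln", n), 2 * C, 2 * C * HW)
        mh <- acfg$mlp_hidden
        add(sprintf("module%d.hf.mlp", n), C * mh + mh + mh * C + C,
            2 * C * mh * HW)
      }
    }
  }
  ag <- conv_cost(C, C, 3, HW)
  add("agg", ag$p, ag$m)
  for (r in upsample_factors(cfg)) {
    up <- conv_cost(C, C * r * r, 3, HW)
    add(sprintf("up.x%d", r), up$p, up$m)
    HW <- HW * r * r
  }
  fin <- conv_cost(C, 3, 3, HW)
  add("final", fin$p, fin$m)
  do.call(rbind, rows)
}

#' Analytic parameter and FLOPs count
#'
#' Parameters are counted exactly from the constructed network; multiply-adds
#' are computed analytically from the architecture for a stated input size
#' (never measured). A backbone without a complexity entry triggers an
#' explicit "uncounted layer" error, never a silent omission.
#'
#' @param net an `hffen_net`, or an `hffen_config` (parameters then counted
#'   analytically from the config).
#' @param input_size `c(H, W)` of the LR input (default `c(192, 192)`).
#' @return an object of class `complexity_report`: `parameters`,
#'   `flops_madds`, `input_size`, and a per-layer `breakdown`.
#' @export
count_complexity <- function(net, input_size = c(192L, 192L)) {
  cfg <- if (inherits(net, "hffen_net")) net$cfg else net
  stopifnot(inherits(cfg, "hffen_config"))
  tab <- complexity_table(cfg, input_size)
  n_par <- sum(tab$params)
  if (inherits(net, "hffen_net")) {
    exact <- tree_n_params(net$params)
    if (exact != n_par)
      stop_input("uncounted layer: analytic parameter count (", n_par,
                 ") disagrees with the constructed network (", exact, ")")
    n_par <- exact
  }
  structure(list(parameters = n_par, flops_madds = sum(tab$madds),
                 input_size = as.integer(input_size), breakdown = tab),
            class = "complexity_report")
}

#' HF-FE branch overhead
#'
#' Compares the full network against the identical architecture with the
#' HF-FE branch disabled, both counted analytically at the same input size.
#'
#' @param cfg a [hffen_config()] with `use_hf = TRUE`.
#' @param input_size `c(H, W)` of the LR input.
#' @return list with `full`, `baseline` (complexity reports) and the relative
#'   `flops_overhead` and `params_overhead`.
#' @export
hf_fe_overhead <- function(cfg, input_size = c(192L, 192L)) {
  stopifnot(inherits(cfg, "hffen_config"), cfg$use_hf)
  base_cfg <- cfg
  base_cfg$use_hf <- FALSE
  full <- count_complexity(cfg, input_size)
  base <- count_complexity(base_cfg, input_size)
  list(full = full, baseline = base,
       flops_overhead = (full$flops_madds - base$flops_madds) / base$flops_madds,
       params_overhead = (full$parameters - base$parameters) / base$parameters)
}

## ---- split evaluation -------------------------------------------------------

#' Evaluate a super-resolver on a test split
#'
#' For every test image: bicubic-degrade the HR ground truth, super-resolve
#' the LR image, convert both SR and HR to Y, crop a `border` strip, and
#' compute PSNR/SSIM; then aggregate means. Infinite PSNR sentinels (perfect
#' reconstructions) are skipped in the mean with a logged count.
#'
#' @param net an `hffen_net`, the string `"bicubic"` (plain bicubic
#'   upsampling baseline), or a function `f(lr_img) -> sr_img`.
#' @param images named list of `(H, W, 3)` HR arrays (values 0..255).
#' @param ids ids to evaluate (e.g. `manifest$test_ids`).
#' @param scale integer scale factor.
#' @param border pixels cropped from each side before metrics (default
#'   `scale`, standard SR practice).
#' @param convention Y conversion, see [rgb_to_y()].
#' @return an object of class `metric_report`.
#' @export
evaluate_sr <- function(net, images, ids, scale, border = scale,
                        convention = "bt601") {
  if (length(ids) == 0) stop_input("evaluate_sr: empty test set")
  srf <- if (inherits(net, "hffen_net")) {
    if (net$cfg$scale != scale)
      stop_input("network was trained for scale x", net$cfg$scale,
                 ", evaluation requested x", scale)
    function(lr) sr_apply(net, lr)
  } else if (identical(net, "bicubic")) {
    function(lr) bicubic_resize(lr, nrow(lr) * scale, ncol(lr) * scale)
  } else if (is.function(net)) net
  else stop_input("evaluate_sr: unsupported net")
  res <- lapply(ids, function(id) {
    hr <- images[[id]]
    if (is.null(hr)) stop_input("evaluate_sr: missing image ", id)
    lr <- bicubic_downsample(hr, scale)
    sr <- srf(lr)
    yh <- rgb_to_y(hr, convention)
    ys <- rgb_to_y(sr, convention)
    if (border > 0) {
      keep_r <- (border + 1):(nrow(yh) - border)
      keep_c <- (border + 1):(ncol(yh) - border)
      yh <- yh[keep_r, keep_c]; ys <- ys[keep_r, keep_c]
    }
    data.frame(id = id, psnr_db = psnr(ys, yh, 255), ssim = ssim(ys, yh, 255))
  })
  per_image <- do.call(rbind, res)
  finite <- is.finite(per_image$psnr_db)
  structure(list(per_image = per_image,
                 mean_psnr_db = mean(per_image$psnr_db[finite]),
                 mean_ssim = mean(per_image$ssim),
                 n_infinite_psnr = sum(!finite),
                 scale = as.integer(scale), n_images = nrow(per_image),
                 conventions = list(y = convention, border = border,
                                    ssim_window = 11L, ssim_sigma = 1.5)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("x%d SR evaluation over %d images (Y %s, border %d)\n",
              x$scale, x$n_images, x$conventions$y, x$conventions$border))
  cat(sprintf("  mean PSNR %.3f dB, mean SSIM %.4f", x$mean_psnr_db, x$mean_ssim))
  if (x$n_infinite_psnr > 0)
    cat(sprintf("  (%d infinite PSNR sentinels skipped)", x$n_infinite_psnr))
  cat("\n")
  invisible(x)
}
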