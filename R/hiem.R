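# HIEM: the fixed-Laplacian high-frequency pathway.
#
# The high-frequency branch of each module is HA(R(L * x)): a fixed (never
# trained) Laplacian stencil applied depthwise, a stack of residual blocks,
# then the hybrid attention unit. The stencil's zero DC response is what makes
# the branch a high-pass pathway: constant regions contribute nothing, thin
# venation lines, lesion rims and serrated boundaries contribute strongly.

LAP4 <- matrix(c(0, 1, 0,
                 1, -4, 1,
                 0, 1, 0), 3, 3, byrow = TRUE)
LAP8 <- matrix(c(1, 1, 1,
                 1, -8, 1,
                 1, 1, 1), 3, 3, byrow = TRUE)

#' Specification of the fixed Laplacian stage
#'
#' @param kernel `"lap4"` (4-neighbour stencil, the canonical discrete
#'   Laplacian, default) or `"lap8"` (8-neighbour variant), or a user 3x3
#'   matrix whose entries sum to zero.
#' @param padding `"reflect"` (default; avoids dark halo artifacts an
#'   edge-detecting filter produces with zero padding) or `"zero"`.
#' @return an object of class `laplacian_spec`.
#' @export
laplacian_spec <- function(kernel = "lap4", padding = "reflect") {
  K <- if (is.matrix(kernel)) kernel
       else switch(kernel, lap4 = LAP4, lap8 = LAP8,
                   stop_input("unknown Laplacian kernel: ", kernel))
  if (!all(dim(K) == c(3L, 3L))) stop_input("Laplacian kernel must be 3x3")
  if (abs(sum(K)) > 1e-12) stop_input("Laplacian kernel entries must sum to 0")
  if (!padding %in% c("reflect", "zero")) stop_input("padding must be reflect|zero")
  structure(list(kernel = K, padding = padding, per_channel = TRUE,
                 learnable = FALSE),
            class = "laplacian_spec")
}

#' Fixed depthwise Laplacian filtering
#'
#' Convolves every channel independently with the fixed 3x3 Laplacian
#' stencil. The kernel is a constant of the architecture: it carries no
#' parameters and is never touched by the optimizer.
#'
#' @param x feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param spec a [laplacian_spec()].
#' @return a feature map of identical shape.
#' @export
laplacian_filter <- function(x, spec = laplacian_spec()) {
  check_fmap(x, "laplacian_filter input")
  stopifnot(inherits(spec, "laplacian_spec"))
  w4 <- as_fmap4(x)
  out <- cpp_dwconv2d_fwd(w4$x, spec$kernel, spec$padding == "zero")
  drop_batch(out, w4$had_batch)
}

laplacian_bwd <- function(dout, spec) {
  # adjoint wrt the input; the stencil is symmetric but the adjoint loop
  # handles any zero-sum 3x3 stencil and the padding correctly
  cpp_dwconv2d_bwd(dout, spec$kernel, spec$padding == "zero")
}

#' Residual refinement stack
#'
#' Applies `depth` EDSR-style residual blocks (conv3x3 - ReLU - conv3x3 with
#' an additive skip, constant width) to a feature map. With all residual
#' weights zero this is the identity; the identity branch is expressed by
#' disabling it, never by `depth = 0`.
#'
#' @param x feature map.
#' @param params parameters from `resstack_init(channels, depth)`; if missing,
#'   zero-initialised blocks (identity) of the stated depth are used.
#' @param depth number of residual blocks (>= 1); inferred from `params`.
#' @return feature map of identical shape.
#' @export
residual_refine <- function(x, params = NULL, depth = 4L) {
  check_fmap(x, "residual_refine input")
  if (!is.null(params)) depth <- length(params)
  if (depth < 1L)
    stop_input("residual_refine: depth must be >= 1 (disable the branch to express the identity)")
  C <- dim(x)[1]
  if (is.null(params)) params <- resstack_init(C, depth, init = "zero")
  w4 <- as_fmap4(x)
  drop_batch(resstack_fwd(params, w4$x)$out, w4$had_batch)
}

# ---- full HF-FE branch (internal trainable form) ----------------------------

hffe_init <- function(channels, cfg, init = "he") {
  p <- list()
  if (cfg$use_hiem)
    p$res <- resstack_init(channels, cfg$hiem$depth, init)
  if (cfg$use_ha)
    p$ha <- ha_init(channels, cfg$ha, init)
  p
}

# Branch forward honouring the ablation flags:
#   full       : HA(R(L x))
#   hiem only  : R(L x)
#   ha only    : HA(x)
hffe_fwd <- function(params, x, cfg) {
  cache <- list()
  z <- x
  if (cfg$use_hiem) {
    lap <- cpp_dwconv2d_fwd(z, cfg$lap_spec$kernel, cfg$lap_spec$padding == "zero")
    rs <- resstack_fwd(params$res, lap)
    cache$res <- rs$cache
    z <- rs$out
  }
  if (cfg$use_ha) {
    ha <- ha_fwd(params$ha, z, cfg$ha)
    cache$ha <- ha$cache
    z <- ha$out
  }
  list(out = z, cache = cache)
}

hffe_bwd <- function(params, cache, dout, cfg) {
  grads <- list()
  if (cfg$use_ha) {
    b <- ha_bwd(params$ha, cache$ha, dout, cfg$ha)
    grads$ha <- b$grads
    dout <- b$dx
  }
  if (cfg$use_hiem) {
    b <- resstack_bwd(params$res, cache$res, dout)
    grads$res <- b$grads
    dout <- laplacian_bwd(b$dx, cfg$lap_spec)
  }
  list(dx = dout, grads = grads[names(params)])   # align with parameter order
}

#' High-frequency feature enhancement branch
#'
#' The composite operator `HA(R(L * x))`: fixed Laplacian extraction,
#' residual refinement, hybrid attention — in exactly that order.
#'
#' @param x feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param params branch parameters (from the network constructor); zero
#'   residual weights and a default-initialised HA if missing.
#' @param cfg a [hffen_config()]; its `hiem`/`ha` sub-configs and ablation
#'   flags are honoured.
#' @return feature map of identical shape.
#' @export
hf_fe_branch <- function(x, params = NULL, cfg = NULL) {
  check_fmap(x, "hf_fe_branch input")
  C <- dim(x)[1]
  if (is.null(cfg)) cfg <- hffen_config(scale = 2L, channels = C)
  if (C != cfg$channels)
    stop_input("hf_fe_branch: input has ", C, " channels but config expects ",
               cfg$channels)
  if (is.null(params)) params <- hffe_init(C, cfg, init = "zero")
  w4 <- as_fmap4(x)
  drop_batch(hffe_fwd(params, w4$x, cfg)$out, w4$had_batch)
}
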