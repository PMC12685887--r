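# SR-branch (backbone) registry.
#
# The HF-FE branch is plug-and-play: it attaches to any shape-preserving
# trainable branch. A backbone implementation is a list with members
#   init(channels, blocks, init)            -> parameter tree
#   forward(params, x)                      -> list(out, cache)
#   backward(params, cache, dout)           -> list(dx, grads)
#   complexity(channels, blocks, H, W)      -> list(params, madds)
# operating on (C, H, W, B) arrays and preserving the shape (no internal
# up/downsampling). The shipped reference backbone is an EDSR-style stack of
# residual blocks.

.backbones <- new.env(parent = emptyenv())

#' Register an SR-branch (backbone) implementation
#'
#' @param name identifier used in [hffen_config()].
#' @param impl list with `init`, `forward`, `backward`, `complexity` members
#'   (see the package vignette for the contract).
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, impl) {
  stopifnot(is.character(name), length(name) == 1L)
  need <- c("init", "forward", "backward", "complexity")
  if (!all(need %in% names(impl)))
    stop_input("backbone implementation must provide: ", paste(need, collapse = ", "))
  assign(name, impl, envir = .backbones)
  invisible(name)
}

get_backbone <- function(name) {
  if (!exists(name, envir = .backbones))
    stop_input("unknown backbone: ", name)
  get(name, envir = .backbones)
}

# reference backbone: stack of EDSR-style residual blocks
.resstack_backbone <- list(
  init = function(channels, blocks, init = "he") resstack_init(channels, blocks, init),
  forward = function(params, x) resstack_fwd(params, x),
  backward = function(params, cache, dout) resstack_bwd(params, cache, dout),
  complexity = function(channels, blocks, H, W) {
    per_conv <- 9 * channels * channels
    list(params = blocks * 2 * (per_conv + channels),
         madds = blocks * 2 * per_conv * H * W)
  }
)
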