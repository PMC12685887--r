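#' @useDynLib hffen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Validate a feature map array
#'
#' Feature maps are numeric arrays with dim `(C, H, W)` or `(C, H, W, B)`,
#' channel-major so that one spatial position is contiguous in memory.
#'
#' @param x numeric array.
#' @param where label used in diagnostics.
#' @return `x`, invisibly.
#' @keywords internal
check_fmap <- function(x, where = "feature map") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop_input(where, ": expected an array with dim (C, H, W) or (C, H, W, B)")
  if (!all(is.finite(x)))
    stop_input(where, ": non-finite values in input")
  invisible(x)
}

# Promote (C,H,W) to (C,H,W,1); returns list(x, had_batch)
as_fmap4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    list(x = x, had_batch = FALSE)
  } else list(x = x, had_batch = TRUE)
}

drop_batch <- function(x, had_batch) {
  if (!had_batch) {
    d <- dim(x)
    dim(x) <- d[1:3]
  }
  x
}

# Recursive parameter-tree utilities. A tree is a nested named list whose
# leaves are numeric arrays/matrices/vectors.
tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    stopifnot(is.list(y), length(x) == length(y))
    out <- mapply(function(a, b) tree_map2(f, a, b), x, y, SIMPLIFY = FALSE)
    names(out) <- names(x)
    out
  } else f(x, y)
}

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), recursive = FALSE, use.names = FALSE)
  else list(x)
}

tree_sumsq <- function(x) sum(vapply(tree_leaves(x), function(l) sum(l * l), 0.0))

tree_n_params <- function(x) sum(vapply(tree_leaves(x), length, 0L))

tree_zeros_like <- function(x) tree_map(function(l) { l[] <- 0; l }, x)

tree_finite <- function(x) all(vapply(tree_leaves(x), function(l) all(is.finite(l)), TRUE))
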