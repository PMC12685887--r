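# Optimisation protocol: L1 loss, Adam (beta1 0.9, beta2 0.999), learning
# rate halved on a fixed iteration schedule, global gradient-norm clipping,
# one model per scale, seeded and fully resumable. One "iteration" is one
# optimisation step on one randomly sampled batch of patch pairs.

#' Training configuration
#'
#' The `paper` profile is the full protocol (lr0 1e-4 halved every 100,000
#' iterations, 400,000 iterations, 192px HR patches); `desk` and `mini` are
#' CPU-sized profiles for desk runs (see the methods vignette for the
#' sizing rationale).
#'
#' @param scale integer scale factor the model is trained for.
#' @param profile `"paper"`, `"desk"` or `"mini"`.
#' @param seed integer seed driving the batch schedule.
#' @param ... overrides of individual fields (`lr0`, `halve_every`,
#'   `total_iters`, `batch_size`, `patch_size`, `clip_norm`, `betas`,
#'   `log_every`).
#' @return an object of class `train_config`.
#' @export
train_config <- function(scale, profile = c("paper", "desk", "mini"),
                         seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    paper = list(lr0 = 1e-4, halve_every = 100000L, total_iters = 400000L,
                 batch_size = 16L, patch_size = 192L),
    desk = list(lr0 = 1e-3, halve_every = 500L, total_iters = 2000L,
                batch_size = 8L, patch_size = 64L),
    mini = list(lr0 = 1e-3, halve_every = 150L, total_iters = 400L,
                batch_size = 4L, patch_size = 48L))
  cfg <- utils::modifyList(
    c(base, list(betas = c(0.9, 0.999), clip_norm = 5.0, eps = 1e-8,
                 log_every = 50L, scale = as.integer(scale),
                 seed = as.integer(seed), profile = profile)),
    list(...))
  class(cfg) <- "train_config"
  cfg
}

#' Network architecture profile matching a training profile
#'
#' @param scale integer scale factor.
#' @param profile `"paper"` (reference architecture), `"desk"` or `"mini"`.
#' @param ... overrides passed to [hffen_config()].
#' @return an [hffen_config()].
#' @export
hffen_profile <- function(scale, profile = c("paper", "desk", "mini"), ...) {
  profile <- match.arg(profile)
  args <- switch(profile,
    paper = list(),
    desk = list(channels = 32L, n_modules = 2L, backbone_blocks = 4L),
    mini = list(channels = 16L, n_modules = 2L, backbone_blocks = 2L))
  do.call(hffen_config, utils::modifyList(c(list(scale = scale), args),
                                          list(...)))
}

#' L1 (mean absolute error) loss
#'
#' @param pred,target arrays of identical shape, normalised intensity units.
#' @return scalar mean absolute difference.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop_input("l1_loss: shape mismatch")
  mean(abs(pred - target))
}

l1_loss_grad <- function(pred, target) {
  g <- sign(pred - target) / length(pred)
  dim(g) <- dim(pred)
  g
}

#' Learning rate at an iteration
#'
#' Closed form of the step-halving schedule:
#' `lr0 * 0.5 ^ floor(t / halve_every)`.
#'
#' @param t iteration index (>= 0).
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(t, cfg) {
  stopifnot(t >= 0)
  cfg$lr0 * 0.5^(t %/% cfg$halve_every)
}

#' Global gradient-norm clipping
#'
#' Rescales the whole gradient tree so its global L2 norm does not exceed
#' `max_norm`; direction is preserved when scaling occurs.
#'
#' @param grads gradient tree (nested list of arrays).
#' @param max_norm maximum global norm.
#' @return list: `grads` (possibly rescaled), `norm` (pre-clip), `scaled`.
#' @export
clip_gradients <- function(grads, max_norm) {
  if (!tree_finite(grads))
    stop_input("non-finite gradients: aborting iteration")
  nrm <- sqrt(tree_sumsq(grads))
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    grads <- tree_map(function(g) g * sc, grads)
    list(grads = grads, norm = nrm, scaled = TRUE)
  } else list(grads = grads, norm = nrm, scaled = FALSE)
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

## ---- one optimisation step --------------------------------------------------

# Forward + backward + clip + Adam on one (lr, hr) batch. Validates the
# pair's scale against the model's: a mismatched pair aborts immediately.
train_step <- function(net, batch, adam_state, lr_t, tcfg) {
  dl <- dim(batch$lr); dh <- dim(batch$hr)
  s <- net$cfg$scale
  if (!identical(dh[2:3], dl[2:3] * s))
    stop_input("scale mismatch: batch is x", dh[2] / dl[2],
               " but the model is x", s)
  fw <- net_forward(net$params, net$cfg, batch$lr, want_cache = TRUE)
  loss <- l1_loss(fw$out, batch$hr)
  if (!is.finite(loss)) return(list(loss = loss, diverged = TRUE))
  grads <- net_backward(net$params, net$cfg, fw$cache,
                        l1_loss_grad(fw$out, batch$hr))
  cl <- clip_gradients(grads, tcfg$clip_norm)
  post_norm <- min(cl$norm, tcfg$clip_norm)
  st <- adam_step(net$params, cl$grads, adam_state, lr_t, tcfg$betas, tcfg$eps)
  list(net = structure(list(params = st$params, cfg = net$cfg),
                       class = "hffen_net"),
       adam_state = st$state, loss = loss,
       grad_norm_pre = cl$norm, grad_norm_post = post_norm,
       diverged = FALSE)
}

## ---- checkpointing ----------------------------------------------------------

#' Save / load a training checkpoint
#'
#' A checkpoint stores weights, the full network and training configs, the
#' Adam state, the iteration counter and the seed: everything needed to
#' resume bit-for-bit.
#'
#' @param path file path (`.rds`).
#' @param net an `hffen_net`.
#' @param tcfg a [train_config()].
#' @param iter iteration the checkpoint was taken at.
#' @param adam_state optimizer state.
#' @param trace loss trace data frame so far.
#' @return the path (write) or the checkpoint list (load).
#' @export
save_checkpoint <- function(path, net, tcfg, iter, adam_state, trace = NULL) {
  saveRDS(list(params = net$params, cfg = net$cfg, tcfg = tcfg,
               iter = as.integer(iter), adam_state = adam_state,
               seed = tcfg$seed, trace = trace), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  need <- c("params", "cfg", "tcfg", "iter", "adam_state", "seed")
  miss <- setdiff(need, names(ck))
  if (length(miss) > 0)
    stop_input("corrupt checkpoint: missing field(s) ", paste(miss, collapse = ", "))
  ck$net <- structure(list(params = ck$params, cfg = ck$cfg), class = "hffen_net")
  ck
}

## ---- training loop ----------------------------------------------------------

#' Train an HFFEN model
#'
#' Runs `total_iters` optimisation steps on patch pairs sampled from the
#' training split with a fully precomputed (seed-derived) batch schedule, so
#' the same run is reproducible and resumable bit-for-bit: resuming from a
#' checkpoint at iteration k and running to n reproduces the weights of an
#' uninterrupted n-iteration run. A NaN loss aborts with the last good state
#' retained. One model per scale, never mixed.
#'
#' @param net an `hffen_net` whose config scale equals `tcfg$scale`.
#' @param images named list of HR images (values 0..255).
#' @param manifest a `split_manifest`; patches are drawn from its
#'   `train_ids` only.
#' @param tcfg a [train_config()].
#' @param checkpoint_path optional `.rds` path written every
#'   `checkpoint_every` iterations (default: only at the end when a path is
#'   given).
#' @param checkpoint_every iterations between checkpoints (0 = end only).
#' @param resume optional checkpoint (from [load_checkpoint()]) to resume.
#' @param schedule optional precomputed batch schedule (shared across
#'   ablation variants); built from `tcfg$seed` if missing.
#' @param quiet suppress progress messages.
#' @return list: `net` (trained), `trace` (data frame iter/lr/loss/
#'   grad_norm), `adam_state`, `schedule_ids` (patch provenance for leakage
#'   audits), `aborted`.
#' @export
train_hffen <- function(net, images, manifest, tcfg,
                        checkpoint_path = NULL, checkpoint_every = 0L,
                        resume = NULL, schedule = NULL, quiet = TRUE) {
  stopifnot(inherits(net, "hffen_net"), inherits(tcfg, "train_config"))
  if (net$cfg$scale != tcfg$scale)
    stop_input("model scale x", net$cfg$scale, " != training scale x", tcfg$scale)
  p <- tcfg$patch_size
  if (p %% tcfg$scale != 0L)
    stop_input("patch_size must be divisible by the scale")
  if (is.null(schedule))
    schedule <- build_schedule(manifest$train_ids, tcfg$total_iters,
                               tcfg$batch_size, tcfg$seed)
  audit_no_leakage(manifest, schedule$id)
  start <- 0L
  adam_state <- adam_init(net$params)
  trace <- NULL
  if (!is.null(resume)) {
    net <- resume$net
    adam_state <- resume$adam_state
    start <- resume$iter
    trace <- resume$trace
  }
  traces <- list(trace)
  aborted <- FALSE
  for (t in seq.int(start + 1L, length.out = tcfg$total_iters - start)) {
    batch <- schedule_batch(schedule, t, images, p, tcfg$scale)
    lr_t <- lr_at(t - 1L, tcfg)
    st <- train_step(net, batch, adam_state, lr_t, tcfg)
    if (st$diverged) {
      warning("non-finite loss at iteration ", t,
              ": aborting with last good state retained")
      aborted <- TRUE
      break
    }
    net <- st$net
    adam_state <- st$adam_state
    traces[[length(traces) + 1L]] <-
      data.frame(iter = t, lr = lr_t, loss = st$loss,
                 grad_norm_pre = st$grad_norm_pre,
                 grad_norm_post = st$grad_norm_post)
    if (!quiet && t %% tcfg$log_every == 0L)
      message(sprintf("iter %6d  lr %.2e  loss %.5f", t, lr_t, st$loss))
    if (!is.null(checkpoint_path) && checkpoint_every > 0L &&
        t %% checkpoint_every == 0L)
      save_checkpoint(checkpoint_path, net, tcfg, t, adam_state,
                      do.call(rbind, traces))
  }
  trace <- do.call(rbind, traces)
  rownames(trace) <- NULL
  if (!is.null(checkpoint_path))
    save_checkpoint(checkpoint_path, net, tcfg,
                    if (aborted) max(trace$iter) else tcfg$total_iters,
                    adam_state, trace)
  list(net = net, trace = trace, adam_state = adam_state,
       schedule_ids = schedule$id, aborted = aborted)
}
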