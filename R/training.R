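# Training procedure: Nesterov-momentum SGD with a cosine-annealed learning
# rate, minibatching over 2D slices, periodic checkpointing, and metric
# evaluation on a held-out split.

#' Cosine annealing schedule configuration
#'
#' @param eta_max initial (maximum) learning rate; default 0.0015.
#' @param eta_min minimum learning rate; default 0.
#' @param T_i iterations per annealing cycle; default 5400.
#' @param restart logical; `TRUE` restarts the cycle (warm restarts) when
#'   `t` exceeds `T_i`, `FALSE` clamps the rate at `eta_min`.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(eta_max = 0.0015, eta_min = 0, T_i = 5400L,
                            restart = TRUE) {
  stopifnot(eta_min <= eta_max, T_i >= 1)
  structure(list(eta_max = eta_max, eta_min = eta_min, T_i = as.integer(T_i),
                 restart = isTRUE(restart)), class = "schedule_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * t_cur / T_i))` with
#' `t_cur = t mod T_i` under warm restarts, or `min(t, T_i)` in clamped
#' mode.  The rate equals `eta_max` at every cycle start and `eta_min` at
#' cycle ends, and is continuous and non-increasing within a cycle.
#'
#' @param t iteration counter (>= 0); vectorised.
#' @param cfg a [schedule_config()].
#' @return learning rate(s).
#' @export
cosine_lr <- function(t, cfg = schedule_config()) {
  stopifnot(all(t >= 0))
  tc <- if (cfg$restart) t %% cfg$T_i else pmin(t, cfg$T_i)
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
    (1 + cos(pi * tc / cfg$T_i))
}

#' Training configuration
#'
#' Defaults follow the published experiment: batch size 4, 9000 optimizer
#' iterations with a checkpoint every 900, Nesterov momentum 0.9, no weight
#' decay, the 0.7/0.3 cross-entropy + Dice mixture loss, and deep
#' supervision over the fused and side outputs.
#'
#' @param batch_size slices per optimizer step.
#' @param total_iters total optimizer steps.
#' @param checkpoint_every checkpoint cadence in steps.
#' @param momentum momentum coefficient.
#' @param nesterov logical; Nesterov momentum.
#' @param weight_decay L2 coefficient.
#' @param loss `"mixture"`, `"ce"`, `"dice"` or `"bce"`.
#' @param deep_supervision logical; apply the loss to all seven outputs
#'   (fused + 6 sides) rather than the fused map alone.
#' @param w mixture [loss_weights()].
#' @param seed RNG seed for shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, total_iters = 9000L,
                         checkpoint_every = 900L, momentum = 0.9,
                         nesterov = TRUE, weight_decay = 0,
                         loss = c("mixture", "ce", "dice", "bce"),
                         deep_supervision = TRUE, w = loss_weights(),
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, total_iters >= 1, checkpoint_every >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 total_iters = as.integer(total_iters),
                 checkpoint_every = as.integer(checkpoint_every),
                 momentum = momentum, nesterov = isTRUE(nesterov),
                 weight_decay = weight_decay, loss = loss,
                 deep_supervision = isTRUE(deep_supervision), w = w,
                 seed = as.integer(seed)), class = "train_config")
}

# replicate (H,W,B) grayscale slices to the model's input channels
.to_input <- function(images, idx, input_channels) {
  d <- dim(images)
  x <- array(0, c(d[1], d[2], input_channels, length(idx)))
  for (k in seq_along(idx))
    for (c in seq_len(input_channels))
      x[, , c, k] <- images[, , idx[k]]
  x
}

# autograd loss over the seven (or one) outputs
.ag_supervised <- function(out, target, tcfg) {
  maps <- c(list(out$fused), if (tcfg$deep_supervision) out$sides)
  terms <- list()
  weights <- numeric(0)
  for (m in maps) {
    p <- ag_softmax_c(m)
    if (tcfg$loss == "mixture") {
      terms <- c(terms, list(ag_ce_probs(p, target), ag_dice_probs(p, target)))
      weights <- c(weights, tcfg$w$w_ce, tcfg$w$w_dice)
    } else {
      terms <- c(terms, list(switch(tcfg$loss,
        ce = ag_ce_probs(p, target),
        dice = ag_dice_probs(p, target),
        bce = ag_bce_probs(p, target))))
      weights <- c(weights, 1)
    }
  }
  ag_wsum(terms, weights)
}

#' Train a network with cosine-annealed Nesterov SGD
#'
#' Runs `total_iters` optimizer steps over shuffled minibatches, applying
#' the configured loss to the forward outputs, with the learning rate from
#' [cosine_lr()] at each step.  A checkpoint (weights + batch-norm moments)
#' is recorded every `checkpoint_every` steps.  Aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param model a `seunet_model` from [seunet_build()].
#' @param images (H, W, N) array of grayscale slices in [0, 1].
#' @param masks (H, W, N) integer array of 0/1 lesion masks.
#' @param tcfg a [train_config()].
#' @param scfg a [schedule_config()].
#' @param checkpoint_dir optional directory; when given, checkpoints are
#'   written there as RDS files and only their paths kept in memory.
#' @param verbose print progress every 25 iterations.
#' @return the trained model, with `log` (data frame of iteration, lr,
#'   loss) and `checkpoints` entries added.
#' @export
seunet_train <- function(model, images, masks, tcfg = train_config(),
                         scfg = schedule_config(), checkpoint_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(model, "seunet_model"))
  if (is.matrix(images)) dim(images) <- c(dim(images), 1L)
  if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
  n <- dim(images)[3]
  if (n < 1) stop("empty training set")
  .with_seed(tcfg$seed, {
    W <- model$weights
    bn_env <- .bn_env_from_list(model$bn)
    vel <- lapply(W, function(a) a * 0)  # zero buffers with a's exact shape
    pool <- integer(0)
    log_iter <- integer(tcfg$total_iters)
    log_lr <- numeric(tcfg$total_iters)
    log_loss <- numeric(tcfg$total_iters)
    checkpoints <- list()
    for (t in seq_len(tcfg$total_iters) - 1L) {
      lr <- cosine_lr(t, scfg)
      if (length(pool) < tcfg$batch_size)
        pool <- c(pool, sample(n))
      idx <- pool[seq_len(tcfg$batch_size)]
      pool <- pool[-seq_len(tcfg$batch_size)]
      x <- .to_input(images, idx, model$config$input_channels)
      target <- masks[, , idx, drop = FALSE]
      ctx <- .make_ctx(W, bn_env, TRUE)
      out <- .fw_net(ctx, ag_const(x), model$config)
      loss <- .ag_supervised(out, target, tcfg)
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss ", loss$value,
             " at iteration ", t, " (lr = ", signif(lr, 4), ")")
      ag_backward(loss)
      for (nm in ls(ctx$pnodes)) {
        g <- ctx$pnodes[[nm]]$grad
        if (is.null(g)) next
        if (tcfg$weight_decay > 0) g <- g + tcfg$weight_decay * W[[nm]]
        v <- tcfg$momentum * vel[[nm]] + g
        vel[[nm]] <- v
        step <- if (tcfg$nesterov) g + tcfg$momentum * v else v
        W[[nm]] <- W[[nm]] - lr * step
      }
      log_iter[t + 1L] <- t
      log_lr[t + 1L] <- lr
      log_loss[t + 1L] <- loss$value
      if (verbose && (t + 1L) %% 25L == 0L)
        message(sprintf("iter %d  lr %.5f  loss %.4f", t + 1L, lr, loss$value))
      if ((t + 1L) %% tcfg$checkpoint_every == 0L) {
        ck <- list(iter = t + 1L, weights = W, bn = .bn_as_list(bn_env, model$bn))
        if (!is.null(checkpoint_dir)) {
          dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
          path <- file.path(checkpoint_dir, sprintf("ckpt_%06d.rds", t + 1L))
          saveRDS(ck, path)
          ck <- list(iter = t + 1L, path = path)
        }
        checkpoints[[length(checkpoints) + 1L]] <- ck
      }
    }
    model$weights <- W
    model$bn <- .bn_as_list(bn_env, model$bn)
    model$log <- data.frame(iter = log_iter, lr = log_lr, loss = log_loss)
    model$checkpoints <- checkpoints
    model$train_config <- tcfg
    model$schedule_config <- scfg
    model
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bn_as_list <- function(bn_env, template) {
  out <- template
  for (k in names(template)) out[[k]] <- bn_env[[k]]
  out
}

#' Per-pixel class prediction
#'
#' Runs the network in evaluation mode (batch norm on running moments) and
#' takes the per-pixel argmax over the fused output's class channels; ties
#' resolve toward class 0 (background).
#'
#' @param model a (trained) `seunet_model`.
#' @param images (H, W, N) array of grayscale slices in [0, 1].
#' @param batch_size forward batch size.
#' @return (H, W, N) integer array of class labels.
#' @export
seunet_predict <- function(model, images, batch_size = 4L) {
  if (is.matrix(images)) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  out <- array(0L, d)
  for (start in seq(1L, d[3], by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, d[3])
    x <- .to_input(images, idx, model$config$input_channels)
    fused <- seunet_forward(model, x)$fused
    C <- dim(fused)[3]
    pm <- matrix(aperm(fused, c(3, 1, 2, 4)), C)
    cls <- max.col(t(pm), ties.method = "first") - 1L
    out[, , idx] <- array(cls, c(d[1], d[2], length(idx)))
  }
  out
}

#' Evaluate a model on a labelled split
#'
#' Predicts every slice, accumulates confusion tallies globally over the
#' split, and reports the four metrics in percent.
#'
#' @param model a (trained) `seunet_model`.
#' @param images (H, W, N) array of grayscale slices in [0, 1].
#' @param masks (H, W, N) integer 0/1 lesion masks.
#' @param percent report percentages (the published convention).
#' @return a [metric_report()].
#' @export
seunet_evaluate <- function(model, images, masks, percent = TRUE) {
  if (is.matrix(images)) dim(images) <- c(dim(images), 1L)
  if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
  if (dim(images)[3] < 1) stop("empty evaluation split")
  pred <- seunet_predict(model, images)
  metric_report(accumulate(pred, masks,
                           num_classes = model$config$num_classes),
                percent = percent)
}

#' Segment image files to mask PNGs
#'
#' Reads 8-bit grayscale PNGs, segments them with the model, and writes one
#' binary mask PNG (values 0/255) per input, same size as the input.
#'
#' @param model a trained `seunet_model`.
#' @param image_paths character vector of PNG paths.
#' @param out_dir output directory (created if needed).
#' @return character vector of written mask paths, invisibly.
#' @export
predict_to_png <- function(model, image_paths, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(length(image_paths))
  for (i in seq_along(image_paths)) {
    m <- png::readPNG(image_paths[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    cls <- seunet_predict(model, array(m, c(dim(m), 1L)))[, , 1]
    outs[i] <- file.path(out_dir,
                         sub("\\.png$", "_mask.png", basename(image_paths[i])))
    .write_png8(255L * (cls > 0), outs[i])
  }
  invisible(outs)
}
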