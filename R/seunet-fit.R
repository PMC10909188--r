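# Classic modelling-idiom front end: one fitting function returning a
# classed object with print / summary / predict / plot methods, wrapping
# seunet_build() + seunet_train().

#' Fit a nested-U segmentation network to labelled slices
#'
#' Builds a network from `config`, trains it on the slice/mask pairs with
#' cosine-annealed Nesterov SGD, and returns a fitted model.
#'
#' @param x (H, W, N) array of grayscale slices in [0, 1]; H and W must be
#'   divisible by 32.
#' @param y (H, W, N) integer array of 0/1 lesion masks.
#' @param config a [model_config()]; defaults to the CPU-scale
#'   [smoke_config()] (use [default_config()] for the full-size network).
#' @param train a [train_config()].
#' @param schedule a [schedule_config()].
#' @param init_seed seed for weight initialisation.
#' @param ... passed to [seunet_train()] (e.g. `checkpoint_dir`, `verbose`).
#' @return an object of class `c("seunet", "seunet_model")`.
#' @export
#' @examples
#' \donttest{
#' spec <- phantom_spec(seed = 7)
#' vol <- make_phantom_volume(spec)
#' w <- window_spec()
#' imgs <- vapply(seq_len(8), function(z)
#'   slice_to_png(vol$image[, , z + 7], w) / 255, matrix(0, 96, 96))
#' msk <- (vol$labels[, , 8:15] > 0) * 1L
#' fit <- seunet(imgs, msk,
#'               train = train_config(batch_size = 2, total_iters = 5,
#'                                    checkpoint_every = 5))
#' print(fit)
#' }
seunet <- function(x, y, config = smoke_config(),
                   train = train_config(), schedule = schedule_config(),
                   init_seed = 1L, ...) {
  model <- seunet_build(config, seed = init_seed)
  model <- seunet_train(model, x, y, tcfg = train, scfg = schedule, ...)
  class(model) <- c("seunet", class(model))
  model
}

#' @export
print.seunet <- function(x, ...) {
  cfg <- x$config
  cat("Nested-U segmentation network (", cfg$variant, ")\n", sep = "")
  rep <- count_parameters(cfg)
  cat(sprintf("  stages: %d encoder + %d decoder; params %s (trainable %s)\n",
              length(cfg$encoder_stages), length(cfg$decoder_stages),
              format(rep$total_params, big.mark = ","),
              format(rep$total_trainable, big.mark = ",")))
  if (!is.null(x$log)) {
    n <- nrow(x$log)
    cat(sprintf("  trained %d iterations; loss %.4f -> %.4f; %d checkpoints\n",
                n, x$log$loss[1], x$log$loss[n], length(x$checkpoints)))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.seunet <- function(object, ...) {
  print(object)
  print(count_parameters(object$config))
  invisible(object)
}

#' @export
predict.seunet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class") return(seunet_predict(object, newdata))
  if (is.matrix(newdata)) dim(newdata) <- c(dim(newdata), 1L)
  d <- dim(newdata)
  probs <- array(0, c(d[1], d[2], object$config$num_classes, d[3]))
  for (k in seq_len(d[3])) {
    xk <- .to_input(newdata, k, object$config$input_channels)
    probs[, , , k] <- softmax_classes(seunet_forward(object, xk)$fused)
  }
  probs
}

#' @export
plot.seunet <- function(x, ...) {
  if (is.null(x$log)) stop("model has no training log")
  graphics::plot(x$log$iter, x$log$loss, type = "l", xlab = "iteration",
                 ylab = "training loss", main = "Training loss", ...)
  invisible(x)
}

#' @export
coef.seunet <- function(object, ...) object$weights
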