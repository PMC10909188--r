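# Assembly of residual U-blocks into the two-level nested U architecture:
# six encoder stages with 2x pooling between them, five decoder stages fed
# by the upsampled deeper feature concatenated with the encoder skip, one
# side output per decoder stage plus one from the deepest encoder stage,
# and a 1x1 fusion convolution over the six upsampled side maps.

#' Model configuration
#'
#' @param variant `"seu2net"` (SE units on the eight non-dilated stages) or
#'   `"u2net"` (no SE anywhere).
#' @param input_channels channels of the input map (grayscale slices are
#'   replicated to 3 channels at load time).
#' @param num_classes output classes of every side/fused map (softmax head).
#' @param encoder_stages,decoder_stages lists of 6 and 5 [stage_spec()]s
#'   (decoder deepest-first); `NULL` for the full-size defaults.
#' @param se_cfg [se_config()] applied to SE-bearing stages of the defaults.
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("seu2net", "u2net"),
                         input_channels = 3L, num_classes = 2L,
                         encoder_stages = NULL, decoder_stages = NULL,
                         se_cfg = se_config()) {
  variant <- match.arg(variant)
  if (is.null(encoder_stages) || is.null(decoder_stages)) {
    st <- .default_stages(variant, se_cfg)
    encoder_stages <- st$encoder
    decoder_stages <- st$decoder
  }
  stopifnot(length(encoder_stages) == 6L, length(decoder_stages) == 5L)
  if (variant == "seu2net") {
    nse <- sum(vapply(c(encoder_stages, decoder_stages),
                      function(s) s$se, logical(1)))
    ndl <- sum(vapply(c(encoder_stages, decoder_stages),
                      function(s) s$dilated && s$se, logical(1)))
    if (nse != 8L || ndl != 0L)
      stop("seu2net requires SE on exactly the eight non-dilated stages")
  }
  structure(list(variant = variant,
                 input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 encoder_stages = encoder_stages,
                 decoder_stages = decoder_stages),
            class = "model_config")
}

.default_stages <- function(variant, se_cfg) {
  se <- variant == "seu2net"
  cfg <- if (se) se_cfg else NULL
  enc <- list(
    stage_spec("enc1", 7, 3, 32, 64, se = se, se_cfg = cfg),
    stage_spec("enc2", 6, 64, 32, 128, se = se, se_cfg = cfg),
    stage_spec("enc3", 5, 128, 64, 256, se = se, se_cfg = cfg),
    stage_spec("enc4", 4, 256, 128, 512, se = se, se_cfg = cfg),
    stage_spec("enc5", 4, 512, 256, 512, dilated = TRUE),
    stage_spec("enc6", 4, 512, 256, 512, dilated = TRUE))
  dec <- list(
    stage_spec("dec5", 4, 1024, 256, 512, dilated = TRUE),
    stage_spec("dec4", 4, 1024, 128, 256, se = se, se_cfg = cfg),
    stage_spec("dec3", 5, 512, 64, 128, se = se, se_cfg = cfg),
    stage_spec("dec2", 6, 256, 32, 64, se = se, se_cfg = cfg),
    stage_spec("dec1", 7, 128, 16, 64, se = se, se_cfg = cfg))
  list(encoder = enc, decoder = dec)
}

#' Default full-size configuration of a variant
#'
#' The published full nested-U stage table: encoder RSU-7(3,32,64),
#' RSU-6(64,32,128), RSU-5(128,64,256), RSU-4(256,128,512) and two
#' RSU-4F(512,256,512); decoder RSU-4F(1024,256,512), RSU-4(1024,128,256),
#' RSU-5(512,64,128), RSU-6(256,32,64), RSU-7(128,16,64).  The `seu2net`
#' variant places SE units on the eight non-dilated stages.
#'
#' @inheritParams model_config
#' @return a [model_config()].
#' @export
default_config <- function(variant = c("seu2net", "u2net"),
                           se_cfg = se_config()) {
  model_config(match.arg(variant), se_cfg = se_cfg)
}

#' Reduced configuration for CPU-scale smoke training
#'
#' Same 11-stage topology and SE placement as the full model but with
#' narrow channels (8 residual, 4 internal) and per-channel SE with a
#' bottleneck of 2, small enough to train for a few hundred iterations on
#' one CPU core.
#'
#' @param variant as in [model_config()].
#' @return a [model_config()].
#' @export
smoke_config <- function(variant = c("seu2net", "u2net")) {
  variant <- match.arg(variant)
  se <- variant == "seu2net"
  cfg <- if (se) se_config("per_channel", bottleneck = 2L) else NULL
  enc <- list(
    stage_spec("enc1", 7, 3, 4, 8, se = se, se_cfg = cfg),
    stage_spec("enc2", 6, 8, 4, 8, se = se, se_cfg = cfg),
    stage_spec("enc3", 5, 8, 4, 8, se = se, se_cfg = cfg),
    stage_spec("enc4", 4, 8, 4, 8, se = se, se_cfg = cfg),
    stage_spec("enc5", 4, 8, 4, 8, dilated = TRUE),
    stage_spec("enc6", 4, 8, 4, 8, dilated = TRUE))
  dec <- list(
    stage_spec("dec5", 4, 16, 4, 8, dilated = TRUE),
    stage_spec("dec4", 4, 16, 4, 8, se = se, se_cfg = cfg),
    stage_spec("dec3", 5, 16, 4, 8, se = se, se_cfg = cfg),
    stage_spec("dec2", 6, 16, 4, 8, se = se, se_cfg = cfg),
    stage_spec("dec1", 7, 16, 4, 8, se = se, se_cfg = cfg))
  model_config(variant, encoder_stages = enc, decoder_stages = dec)
}

.all_stages <- function(config) c(config$encoder_stages, config$decoder_stages)

.side_in_channels <- function(config) {
  dec_out <- vapply(config$decoder_stages, function(s) s$out_ch, integer(1))
  # side1..side5 from shallowest..deepest decoder stage, side6 from enc6
  c(rev(dec_out), config$encoder_stages[[6]]$out_ch)
}

#' Build a network from a configuration
#'
#' Initialises every stage, side convolution and the fusion convolution
#' (He-normal kernels, identity batch norm), returning an untrained model.
#'
#' @param config a [model_config()].
#' @param seed optional integer; when given, initialisation is drawn from a
#'   private RNG stream and the caller's RNG state is left untouched.
#' @return an object of class `seunet_model`: list with `config`, `weights`
#'   (flat named list), `bn` (running moments per conv unit).
#' @export
seunet_build <- function(config, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  W <- list()
  bn <- list()
  for (s in .all_stages(config)) {
    ini <- init_stage_weights(s)
    W <- c(W, ini$weights)
    bn <- c(bn, ini$bn)
  }
  ncls <- config$num_classes
  side_in <- .side_in_channels(config)
  for (i in seq_along(side_in)) {
    cin <- side_in[i]
    W[[paste0("side", i, ".w")]] <-
      array(stats::rnorm(9 * cin * ncls, sd = sqrt(2 / (9 * cin))),
            c(3, 3, cin, ncls))
    W[[paste0("side", i, ".b")]] <- numeric(ncls)
  }
  W[["fuse.w"]] <- array(stats::rnorm(6 * ncls * ncls, sd = sqrt(2 / (6 * ncls))),
                         c(1, 1, 6 * ncls, ncls))
  W[["fuse.b"]] <- numeric(ncls)
  structure(list(config = config, weights = W, bn = bn),
            class = "seunet_model")
}

# autograd forward of the whole network; returns list(fused=, sides=list of 6)
.fw_net <- function(ctx, x, config) {
  d <- dim(x$value)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial size must be divisible by 32, got ", d[1], "x", d[2])
  if (d[3] != config$input_channels)
    stop("input has ", d[3], " channels, model expects ",
         config$input_channels)
  enc <- vector("list", 6L)
  cur <- x
  for (i in 1:6) {
    if (i > 1L) cur <- ag_maxpool2(cur)
    cur <- .fw_stage(ctx, cur, config$encoder_stages[[i]])
    enc[[i]] <- cur
  }
  dcur <- enc[[6]]
  dec <- vector("list", 5L)
  for (j in 1:5) {
    skip <- enc[[6L - j]]
    sz <- dim(skip$value)
    dcur <- .fw_stage(ctx, ag_concat_c(ag_upsample(dcur, sz[1], sz[2]), skip),
                      config$decoder_stages[[j]])
    dec[[j]] <- dcur
  }
  side_src <- c(rev(dec), enc[6])
  sides <- vector("list", 6L)
  for (i in 1:6) {
    s <- ag_conv2d(side_src[[i]], .pnode(ctx, paste0("side", i, ".w")),
                   .pnode(ctx, paste0("side", i, ".b")), pad = 1L, dil = 1L)
    sides[[i]] <- ag_upsample(s, d[1], d[2])
  }
  cat6 <- sides[[1]]
  for (i in 2:6) cat6 <- ag_concat_c(cat6, sides[[i]])
  fused <- ag_conv2d(cat6, .pnode(ctx, "fuse.w"), .pnode(ctx, "fuse.b"),
                     pad = 0L, dil = 1L)
  list(fused = fused, sides = sides)
}

#' Forward pass with side outputs and saliency fusion
#'
#' @param model a `seunet_model` from [seunet_build()].
#' @param x input map: (H, W, C, N) array (or (H, W, C)); H and W must be
#'   divisible by 32.
#' @param training logical; `TRUE` uses batch statistics in the batch-norm
#'   units (and updates the model's running moments as a side effect of
#'   training; this function always leaves the model unchanged).
#' @return list with `fused` (H, W, num_classes, N) logits and `sides`, a
#'   list of six side-output logit maps of the same shape.
#' @export
seunet_forward <- function(model, x, training = FALSE) {
  x <- .as_feature_map(x)
  ctx <- .make_ctx(model$weights, .bn_env_from_list(model$bn), training)
  out <- .fw_net(ctx, ag_const(x), model$config)
  list(fused = out$fused$value,
       sides = lapply(out$sides, function(s) s$value))
}

# ---- complexity audit -------------------------------------------------------

.se_param_count <- function(cfg, channels) {
  cin <- if (cfg$mode == "shared_group") cfg$group_size else channels
  n <- 2L * cin * cfg$bottleneck
  if (cfg$bias) n <- n + cfg$bottleneck + cin
  n
}

# per-stage counts by shape enumeration (no allocation)
.stage_param_count <- function(spec) {
  tr <- 0L
  buf <- 0L
  for (u in .stage_units(spec)) {
    tr <- tr + 9L * u$cin * u$cout + 3L * u$cout  # w, b, gamma, beta
    buf <- buf + 2L * u$cout                      # running mean, var
  }
  if (spec$se) tr <- tr + .se_param_count(spec$se_cfg, spec$out_ch)
  c(trainable = tr, buffers = buf)
}

#' Structural complexity audit
#'
#' Enumerates parameter counts per stage and for the side/fusion head.
#' The headline `total_params` follows the accounting convention of the
#' published complexity table, which includes the batch-norm running
#' moments alongside the trainable weights; `total_trainable` excludes
#' them.  `total_mult_adds` is an informational multiply-accumulate count
#' at 512x512 input (one MAC per convolution weight application).
#'
#' @param x a `model_config` or a built `seunet_model`.
#' @return an object of class `complexity_report`.
#' @export
count_parameters <- function(x) {
  config <- if (inherits(x, "seunet_model")) x$config else x
  stopifnot(inherits(config, "model_config"))
  stages <- .all_stages(config)
  per_stage <- integer(0)
  tr <- 0
  buf <- 0
  for (s in stages) {
    n <- .stage_param_count(s)
    per_stage[[s$name]] <- n[["trainable"]] + n[["buffers"]]
    tr <- tr + n[["trainable"]]
    buf <- buf + n[["buffers"]]
  }
  ncls <- config$num_classes
  side_in <- .side_in_channels(config)
  head_n <- sum(9L * side_in * ncls + ncls) + 6L * ncls * ncls + ncls
  rep <- structure(list(
    variant = config$variant,
    per_stage_params = per_stage,
    side_and_fusion_params = head_n,
    total_params = sum(per_stage) + head_n,
    total_trainable = tr + head_n,
    total_buffers = buf,
    total_mult_adds = .count_mult_adds(config)),
    class = "complexity_report")
  if (inherits(x, "seunet_model")) {
    direct <- sum(vapply(x$weights, length, numeric(1))) +
      sum(vapply(x$bn, function(s) length(s$mean) + length(s$var), numeric(1)))
    if (direct != rep$total_params)
      stop("internal audit mismatch: enumerated ", rep$total_params,
           " vs traversed ", direct)
  }
  rep
}

# informational MAC count at 512x512 (one multiply-accumulate per conv
# weight application, batch norm and resampling not counted)
.count_mult_adds <- function(config, hw = 512L) {
  total <- 0
  res <- hw
  stage_macs <- function(spec, res) {
    m <- 0
    lev <- 0L
    for (u in .stage_units(spec)) {
      if (!spec$dilated) {
        lev <- switch(substr(u$name, 1, 3),
                      "in" = 0L, "enc" = min(as.integer(substr(u$name, 4, 4)) - 1L,
                                             spec$height - 2L),
                      "dec" = as.integer(substr(u$name, 4, 4)) - 1L)
        if (is.na(lev)) lev <- 0L
      } else lev <- 0L
      r <- res / 2^lev
      m <- m + 9 * u$cin * u$cout * r * r
    }
    m
  }
  for (i in seq_along(config$encoder_stages)) {
    total <- total + stage_macs(config$encoder_stages[[i]], res)
    if (i < 6L && !config$encoder_stages[[i + 1]]$dilated) res <- res / 2
    else if (i < 6L) res <- res / 2
  }
  # decoder resolutions mirror encoder skips: enc5..enc1
  dres <- hw / c(16L, 8L, 4L, 2L, 1L)
  for (j in seq_along(config$decoder_stages))
    total <- total + stage_macs(config$decoder_stages[[j]], dres[j])
  ncls <- config$num_classes
  side_in <- .side_in_channels(config)
  side_res <- c(hw, hw / 2L, hw / 4L, hw / 8L, hw / 16L, hw / 32L)
  total <- total + sum(9 * side_in * ncls * side_res^2)
  total + 6 * ncls * ncls * hw * hw
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Network complexity audit (", x$variant, ")\n", sep = "")
  df <- data.frame(stage = names(x$per_stage_params),
                   params = unname(x$per_stage_params))
  print(df, row.names = FALSE)
  cat(sprintf("side + fusion: %s\n", format(x$side_and_fusion_params, big.mark = ",")))
  cat(sprintf("total params (incl. BN moments): %s\n",
              format(x$total_params, big.mark = ",")))
  cat(sprintf("trainable only: %s\n", format(x$total_trainable, big.mark = ",")))
  cat(sprintf("mult-adds at 512x512 (informational): %.2f G\n",
              x$total_mult_adds / 1e9))
  invisible(x)
}
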