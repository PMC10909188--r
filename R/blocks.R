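# Building blocks of the nested-U architecture: the Conv+BN+ReLU unit, the
# squeeze-and-excitation (SE) recalibration unit, and the residual U-blocks
# RSU-L (L = 4..7), their dilated "F" variant, and the SE-augmented RSU in
# which the residual branch is recalibrated before the final addition.
#
# Feature maps are (H, W, C, N) arrays.  Weights live in flat named lists
# ("<unit>.w", "<unit>.b", "<unit>.gamma", "<unit>.beta", SE: "<unit>.w1"
# ...), batch-norm running moments in a parallel environment keyed by unit
# name.  The same forward code serves both the public array-in/array-out
# operations (evaluation mode) and the autograd training path.

#' Squeeze-and-excitation configuration
#'
#' Describes the shape of the two affine maps inside an SE unit.  In
#' `shared_group` mode one `(group_size -> bottleneck -> group_size)` pair of
#' maps is applied to every consecutive group of `group_size` channels with
#' shared weights, giving a parameter overhead that is constant across
#' stages of different width; `per_channel` is the conventional SE layout
#' with a `(C -> bottleneck -> C)` pair sized to the block.
#'
#' @param mode `"shared_group"` or `"per_channel"`.
#' @param group_size channels per shared group (`shared_group` mode).
#' @param bottleneck width of the squeezed hidden layer.
#' @param bias logical; include bias terms in both affine maps.
#' @return an object of class `se_config`.
#' @export
se_config <- function(mode = c("shared_group", "per_channel"),
                      group_size = 16L, bottleneck = 4L, bias = TRUE) {
  mode <- match.arg(mode)
  stopifnot(bottleneck >= 1)
  structure(list(mode = mode, group_size = as.integer(group_size),
                 bottleneck = as.integer(bottleneck), bias = isTRUE(bias)),
            class = "se_config")
}

#' Stage specification for one residual U-block
#'
#' @param name label used as the weight-name prefix.
#' @param height number of encoder levels L (4..7).
#' @param in_ch,mid_ch,out_ch input, internal and output channel counts.
#' @param dilated logical; the "F" variant in which pooling/upsampling are
#'   replaced by dilated convolutions (requires `height == 4`).
#' @param se logical; recalibrate the residual branch with an SE unit.
#' @param se_cfg an [se_config()] (required when `se` is `TRUE`).
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(name, height, in_ch, mid_ch, out_ch,
                       dilated = FALSE, se = FALSE, se_cfg = NULL) {
  stopifnot(height %in% 4:7)
  if (dilated && height != 4L)
    stop("dilated (F) blocks have height 4")
  if (se && is.null(se_cfg))
    stop("se = TRUE requires an se_config")
  structure(list(name = name, height = as.integer(height),
                 in_ch = as.integer(in_ch), mid_ch = as.integer(mid_ch),
                 out_ch = as.integer(out_ch), dilated = isTRUE(dilated),
                 se = isTRUE(se), se_cfg = se_cfg),
            class = "stage_spec")
}

# ---- weight initialisation --------------------------------------------------

# He-normal conv kernel (3x3 unless stated), zero bias, identity BN
.init_rebnconv <- function(cin, cout, k = 3L) {
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout),
       gamma = rep(1, cout),
       beta = numeric(cout))
}

.init_se <- function(cfg, channels) {
  if (cfg$mode == "shared_group") {
    if (channels %% cfg$group_size != 0L)
      stop("channel count ", channels, " not divisible by SE group size ",
           cfg$group_size)
    cin <- cfg$group_size
  } else {
    cin <- channels
  }
  out <- list(w1 = matrix(stats::rnorm(cfg$bottleneck * cin, sd = sqrt(2 / cin)),
                          cfg$bottleneck, cin),
              w2 = matrix(stats::rnorm(cin * cfg$bottleneck,
                                       sd = sqrt(1 / cfg$bottleneck)),
                          cin, cfg$bottleneck))
  if (cfg$bias) {
    out$b1 <- numeric(cfg$bottleneck)
    out$b2 <- numeric(cin)
  }
  out
}

# unit names of a stage, in forward order, with their (cin, cout, dilation)
.stage_units <- function(spec) {
  h <- spec$height
  u <- list(list(name = "in", cin = spec$in_ch, cout = spec$out_ch, dil = 1L))
  if (!spec$dilated) {
    u <- c(u, list(list(name = "enc1", cin = spec$out_ch, cout = spec$mid_ch,
                        dil = 1L)))
    for (l in 2:(h - 1))
      u <- c(u, list(list(name = paste0("enc", l), cin = spec$mid_ch,
                          cout = spec$mid_ch, dil = 1L)))
    u <- c(u, list(list(name = paste0("enc", h), cin = spec$mid_ch,
                        cout = spec$mid_ch, dil = 2L)))
    for (l in (h - 1):2)
      u <- c(u, list(list(name = paste0("dec", l), cin = 2L * spec$mid_ch,
                          cout = spec$mid_ch, dil = 1L)))
    u <- c(u, list(list(name = "dec1", cin = 2L * spec$mid_ch,
                        cout = spec$out_ch, dil = 1L)))
  } else {
    dils <- c(1L, 2L, 4L)
    u <- c(u, list(list(name = "enc1", cin = spec$out_ch, cout = spec$mid_ch,
                        dil = 1L)))
    for (l in 2:3)
      u <- c(u, list(list(name = paste0("enc", l), cin = spec$mid_ch,
                          cout = spec$mid_ch, dil = dils[l])))
    u <- c(u, list(list(name = "enc4", cin = spec$mid_ch, cout = spec$mid_ch,
                        dil = 8L)))
    for (l in 3:2)
      u <- c(u, list(list(name = paste0("dec", l), cin = 2L * spec$mid_ch,
                          cout = spec$mid_ch, dil = dils[l])))
    u <- c(u, list(list(name = "dec1", cin = 2L * spec$mid_ch,
                        cout = spec$out_ch, dil = 1L)))
  }
  u
}

#' Initialise the weights of one residual U-block
#'
#' Draws He-normal convolution kernels and identity batch-norm affine
#' parameters for every unit of the stage, plus the SE unit when the stage
#' carries one.  Uses the current RNG state.
#'
#' @param spec a [stage_spec()].
#' @param prefix string prepended to every weight name.
#' @return list with `weights` (flat named list of arrays) and `bn` (named
#'   list of running-moment pairs, one per conv unit).
#' @export
init_stage_weights <- function(spec, prefix = "") {
  W <- list()
  bn <- list()
  for (u in .stage_units(spec)) {
    p <- .init_rebnconv(u$cin, u$cout)
    nm <- paste0(prefix, spec$name, ".", u$name)
    W[[paste0(nm, ".w")]] <- p$w
    W[[paste0(nm, ".b")]] <- p$b
    W[[paste0(nm, ".gamma")]] <- p$gamma
    W[[paste0(nm, ".beta")]] <- p$beta
    bn[[nm]] <- list(mean = numeric(u$cout), var = rep(1, u$cout))
  }
  if (spec$se) {
    se <- .init_se(spec$se_cfg, spec$out_ch)
    for (k in names(se))
      W[[paste0(prefix, spec$name, ".se.", k)]] <- se[[k]]
  }
  list(weights = W, bn = bn)
}

# ---- forward passes (autograd) ---------------------------------------------

# ctx: environment with W (flat weight list), bn (state env), training flag,
# pnodes (cache of parameter nodes created this pass)
.make_ctx <- function(weights, bn_env, training) {
  ctx <- new.env(parent = emptyenv())
  ctx$W <- weights
  ctx$bn <- bn_env
  ctx$training <- training
  ctx$pnodes <- new.env(parent = emptyenv())
  ctx
}

.pnode <- function(ctx, name) {
  nd <- ctx$pnodes[[name]]
  if (is.null(nd)) {
    v <- ctx$W[[name]]
    if (is.null(v)) stop("missing weight: ", name)
    nd <- ag_param(v, name)
    ctx$pnodes[[name]] <- nd
  }
  nd
}

.fw_rebnconv <- function(ctx, x, name, dil) {
  cv <- ag_conv2d(x, .pnode(ctx, paste0(name, ".w")),
                  .pnode(ctx, paste0(name, ".b")), pad = dil, dil = dil)
  bn <- ag_bn(cv, .pnode(ctx, paste0(name, ".gamma")),
              .pnode(ctx, paste0(name, ".beta")), ctx$bn, name, ctx$training)
  ag_relu(bn)
}

.fw_se <- function(ctx, r, name, cfg) {
  d <- dim(r$value)
  C <- d[3]
  s <- ag_gap(r)                                     # (C, N)
  w1 <- .pnode(ctx, paste0(name, ".w1"))
  w2 <- .pnode(ctx, paste0(name, ".w2"))
  b1 <- if (cfg$bias) .pnode(ctx, paste0(name, ".b1")) else ag_const(0)
  b2 <- if (cfg$bias) .pnode(ctx, paste0(name, ".b2")) else ag_const(0)
  if (cfg$mode == "shared_group") {
    g <- cfg$group_size
    s <- ag_reshape(s, c(g, (C %/% g) * d[4]))
    z <- ag_relu(ag_affine(w1, s, b1))
    gates <- ag_sigmoid(ag_affine(w2, z, b2))
    gates <- ag_reshape(gates, c(C, d[4]))
  } else {
    z <- ag_relu(ag_affine(w1, s, b1))
    gates <- ag_sigmoid(ag_affine(w2, z, b2))
  }
  ag_se_scale(r, gates)
}

# one residual U-block (plain, dilated, or SE-augmented)
.fw_stage <- function(ctx, x, spec, prefix = "") {
  nm <- function(u) paste0(prefix, spec$name, ".", u)
  hin <- .fw_rebnconv(ctx, x, nm("in"), 1L)
  resid <- if (spec$se) .fw_se(ctx, hin, nm("se"), spec$se_cfg) else hin
  h <- spec$height
  if (!spec$dilated) {
    d <- dim(x$value)
    need <- 2^(h - 2)
    if (d[1] %% need != 0L || d[2] %% need != 0L)
      stop("RSU-", h, " needs spatial size divisible by ", need,
           ", got ", d[1], "x", d[2])
    e <- vector("list", h - 1)
    e[[1]] <- .fw_rebnconv(ctx, hin, nm("enc1"), 1L)
    for (l in 2:(h - 1))
      e[[l]] <- .fw_rebnconv(ctx, ag_maxpool2(e[[l - 1]]), nm(paste0("enc", l)), 1L)
    dcd <- .fw_rebnconv(ctx, e[[h - 1]], nm(paste0("enc", h)), 2L)
    for (l in (h - 1):1) {
      dcd <- .fw_rebnconv(ctx, ag_concat_c(dcd, e[[l]]), nm(paste0("dec", l)), 1L)
      if (l > 1) {
        sz <- dim(e[[l - 1]]$value)
        dcd <- ag_upsample(dcd, sz[1], sz[2])
      }
    }
  } else {
    e1 <- .fw_rebnconv(ctx, hin, nm("enc1"), 1L)
    e2 <- .fw_rebnconv(ctx, e1, nm("enc2"), 2L)
    e3 <- .fw_rebnconv(ctx, e2, nm("enc3"), 4L)
    bt <- .fw_rebnconv(ctx, e3, nm("enc4"), 8L)
    d3 <- .fw_rebnconv(ctx, ag_concat_c(bt, e3), nm("dec3"), 4L)
    d2 <- .fw_rebnconv(ctx, ag_concat_c(d3, e2), nm("dec2"), 2L)
    dcd <- .fw_rebnconv(ctx, ag_concat_c(d2, e1), nm("dec1"), 1L)
  }
  ag_add(dcd, resid)
}

# ---- public array-in / array-out operations --------------------------------

.bn_env_from_list <- function(bn) {
  e <- new.env(parent = emptyenv())
  for (k in names(bn)) e[[k]] <- bn[[k]]
  e
}

#' Convolution + batch normalization + rectifier unit
#'
#' A stride-1 "same" 3x3 convolution (padding equal to the dilation), batch
#' normalization and ReLU, applied in evaluation mode with the supplied
#' running moments (identity moments by default).
#'
#' @param x feature map, (H, W, C, N) array.
#' @param weights list with `w` (3,3,in_ch,out_ch), `b`, `gamma`, `beta`,
#'   e.g. from [init_stage_weights()] or built by hand; if `NULL`, freshly
#'   initialised for `in_ch`/`out_ch` using the current RNG.
#' @param in_ch,out_ch channel counts (used when `weights` is `NULL` and
#'   checked otherwise).
#' @param dilation kernel dilation.
#' @param bn_state optional list with `mean` and `var` running moments.
#' @return (H, W, out_ch, N) array.
#' @export
conv_bn_relu <- function(x, in_ch, out_ch, dilation = 1L, weights = NULL,
                         bn_state = NULL) {
  x <- .as_feature_map(x)
  if (dim(x)[3] != in_ch)
    stop("input has ", dim(x)[3], " channels, expected ", in_ch)
  if (is.null(weights)) weights <- .init_rebnconv(in_ch, out_ch)
  if (is.null(bn_state))
    bn_state <- list(mean = numeric(out_ch), var = rep(1, out_ch))
  W <- list(u.w = weights$w, u.b = weights$b, u.gamma = weights$gamma,
            u.beta = weights$beta)
  ctx <- .make_ctx(W, .bn_env_from_list(list(u = bn_state)), FALSE)
  .fw_rebnconv(ctx, ag_const(x), "u", as.integer(dilation))$value
}

#' Squeeze-and-excitation recalibration of a feature map
#'
#' Channel descriptors by global average pooling, a bottlenecked pair of
#' affine maps with ReLU then logistic activation producing per-channel
#' gates in (0,1), followed by the residual form `gates * x + x`.
#'
#' @param x feature map, (H, W, C, N) array.
#' @param cfg an [se_config()].
#' @param weights list with `w1`, `w2` (and `b1`, `b2` when `cfg$bias`); if
#'   `NULL`, freshly initialised.
#' @return array of the same shape as `x`.
#' @export
se_recalibrate <- function(x, cfg, weights = NULL) {
  x <- .as_feature_map(x)
  if (is.null(weights)) weights <- .init_se(cfg, dim(x)[3])
  W <- list()
  for (k in names(weights)) W[[paste0("u.", k)]] <- weights[[k]]
  ctx <- .make_ctx(W, new.env(parent = emptyenv()), FALSE)
  .fw_se(ctx, ag_const(x), "u", cfg)$value
}

.run_stage <- function(x, spec, weights, bn, training = FALSE) {
  x <- .as_feature_map(x)
  if (dim(x)[3] != spec$in_ch)
    stop("input has ", dim(x)[3], " channels, stage expects ", spec$in_ch)
  ctx <- .make_ctx(weights, .bn_env_from_list(bn), training)
  .fw_stage(ctx, ag_const(x), spec)$value
}

#' Forward pass of a residual U-block
#'
#' Runs one RSU stage in evaluation mode: input convolution producing the
#' residual branch, an encoder chain with 2x max pooling, a dilated bottom
#' convolution, a decoder chain on concatenated skip/upsampled features with
#' bilinear upsampling, and the final residual addition.  Spatial size is
#' preserved end to end (input size must be divisible by `2^(height-2)`).
#'
#' `rsu4f_forward()` runs the dilated variant (dilations 1,2,4, bottom 8,
#' mirrored decoder; no resampling, any spatial size); `se_rsu_forward()`
#' the SE-augmented one (residual branch recalibrated before the addition).
#'
#' @param x feature map, (H, W, in_ch, N) array.
#' @param spec a [stage_spec()].
#' @param weights,bn as produced by [init_stage_weights()] (both `NULL` to
#'   initialise fresh weights with the current RNG).
#' @return (H, W, out_ch, N) array.
#' @export
rsu_forward <- function(x, spec, weights = NULL, bn = NULL) {
  if (spec$dilated) stop("use rsu4f_forward for dilated stages")
  if (is.null(weights)) {
    ini <- init_stage_weights(spec)
    weights <- ini$weights
    bn <- ini$bn
  }
  .run_stage(x, spec, weights, bn)
}

#' @rdname rsu_forward
#' @export
rsu4f_forward <- function(x, spec, weights = NULL, bn = NULL) {
  if (!spec$dilated) stop("rsu4f_forward expects a dilated stage_spec")
  if (is.null(weights)) {
    ini <- init_stage_weights(spec)
    weights <- ini$weights
    bn <- ini$bn
  }
  .run_stage(x, spec, weights, bn)
}

#' @rdname rsu_forward
#' @export
se_rsu_forward <- function(x, spec, weights = NULL, bn = NULL) {
  if (!spec$se) stop("se_rsu_forward expects a stage_spec with se = TRUE")
  if (is.null(weights)) {
    ini <- init_stage_weights(spec)
    weights <- ini$weights
    bn <- ini$bn
  }
  .run_stage(x, spec, weights, bn)
}

# coerce (H,W), (H,W,C) or (H,W,C,N) to (H,W,C,N)
.as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 2 to 4 dimensions")
  x
}

#' Count elements of a weight list
#'
#' @param weights flat or nested list of numeric arrays.
#' @return integer total of array element counts.
#' @export
n_params <- function(weights) {
  sum(vapply(weights, length, numeric(1)))
}
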