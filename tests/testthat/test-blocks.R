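# Building blocks: shape contracts, parameter accounting, SE arithmetic,
# residual behaviour.

test_that("conv_bn_relu preserves spatial size, maps channels, zeroes stay zero", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  y <- conv_bn_relu(x, 3, 4)
  expect_identical(dim(y), c(8L, 8L, 4L, 1L))
  expect_true(all(y >= 0))
  # trainable parameters: 3*3*3*4 + 4 (conv) + 2*4 (BN affine) = 120
  expect_identical(n_params(seunet:::.init_rebnconv(3, 4)), 120)
  # zero conv weights + identity BN give identically zero output
  w0 <- list(w = array(0, c(3, 3, 3, 4)), b = numeric(4),
             gamma = rep(1, 4), beta = numeric(4))
  expect_true(all(conv_bn_relu(x, 3, 4, weights = w0) == 0))
  # channel mismatch is an error
  expect_error(conv_bn_relu(x, 4, 4), "channels")
  # dilation preserves spatial size too
  expect_identical(dim(conv_bn_relu(x, 3, 4, dilation = 4))[1:2], c(8L, 8L))
})

test_that("SE recalibration: zero weights give 1.5x, hand case matches scalars", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 32), c(6, 6, 32, 2))
  cfg <- se_config("shared_group", group_size = 16, bottleneck = 4)
  w0 <- list(w1 = matrix(0, 4, 16), w2 = matrix(0, 16, 4),
             b1 = numeric(4), b2 = numeric(16))
  expect_equal(se_recalibrate(x, cfg, w0), 1.5 * x, tolerance = 1e-12)
  # shared-group parameter overhead: 16*4+4 + 4*16+16 = 148 per SE unit
  expect_identical(n_params(seunet:::.init_se(cfg, 64)), 148)
  expect_identical(n_params(seunet:::.init_se(cfg, 512)), 148)
  # hand-computed per-channel case: C=2, H=W=1, x=(1,3),
  # W1=(1 1), W2=(1,-1)^T, no bias => gates (sigma(4), sigma(-4))
  xs <- array(c(1, 3), c(1, 1, 2, 1))
  cfg2 <- se_config("per_channel", bottleneck = 1)
  wh <- list(w1 = matrix(c(1, 1), 1, 2), w2 = matrix(c(1, -1), 2, 1),
             b1 = 0, b2 = numeric(2))
  got <- se_recalibrate(xs, cfg2, wh)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(as.vector(got), c(1 * (1 + sig(4)), 3 * (1 + sig(-4))),
               tolerance = 1e-12)
  # gates strictly inside (0,1): output strictly between x and 2x for x>0
  xp <- abs(array(rnorm(4 * 4 * 16), c(4, 4, 16, 1))) + 0.1
  yp <- se_recalibrate(xp, se_config("shared_group", 16, 4))
  expect_true(all(yp > xp) && all(yp < 2 * xp))
  # indivisible channel count in shared_group mode errors
  expect_error(se_recalibrate(array(rnorm(4 * 4 * 10), c(4, 4, 10, 1)), cfg),
               "divisible")
})

test_that("RSU blocks preserve shape and match the enumeration oracle", {
  set.seed(3)
  specs <- list(
    stage_spec("a", 7, 3, 8, 16),
    stage_spec("b", 5, 4, 8, 8),
    stage_spec("c", 4, 6, 4, 8))
  sizes <- c(64L, 16L, 8L)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    hw <- sizes[i]
    x <- array(rnorm(hw * hw * s$in_ch), c(hw, hw, s$in_ch, 1))
    y <- rsu_forward(x, s)
    expect_identical(dim(y), c(hw, hw, s$out_ch, 1L), info = s$name)
    ini <- init_stage_weights(s)
    expect_identical(n_params(ini$weights),
                     oracle_rsu_params(s$height, s$in_ch, s$mid_ch, s$out_ch))
  }
  # indivisible spatial size rejected
  s <- specs[[1]]
  expect_error(rsu_forward(array(0, c(33, 33, 3, 1)), s), "divisible")
})

test_that("RSU-4F works at odd sizes and matches its enumeration oracle", {
  set.seed(4)
  s <- stage_spec("f", 4, 8, 4, 8, dilated = TRUE)
  x <- array(rnorm(11 * 13 * 8), c(11, 13, 8, 1))
  y <- rsu4f_forward(x, s)
  expect_identical(dim(y), c(11L, 13L, 8L, 1L))
  ini <- init_stage_weights(s)
  expect_identical(n_params(ini$weights),
                   oracle_rsu_params(4, 8, 4, 8, dilated = TRUE))
})

test_that("zeroed decoder reduces any RSU to its residual branch", {
  set.seed(5)
  for (s in list(stage_spec("p", 5, 3, 4, 6),
                 stage_spec("q", 4, 3, 4, 6, dilated = TRUE))) {
    ini <- init_stage_weights(s)
    W <- ini$weights
    for (nm in grep("\\.dec", names(W), value = TRUE))
      W[[nm]] <- W[[nm]] * 0
    x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
    run <- if (s$dilated) rsu4f_forward else rsu_forward
    out <- run(x, s, W, ini$bn)
    inw <- list(w = W[[paste0(s$name, ".in.w")]], b = W[[paste0(s$name, ".in.b")]],
                gamma = W[[paste0(s$name, ".in.gamma")]],
                beta = W[[paste0(s$name, ".in.beta")]])
    resid <- conv_bn_relu(x, 3, 6, weights = inw)
    expect_equal(out, resid, tolerance = 1e-12)
  }
})

test_that("SE-RSU equals RSU plus SE recalibration of the residual branch", {
  set.seed(6)
  cfg <- se_config("per_channel", bottleneck = 2)
  s_se <- stage_spec("s", 5, 3, 4, 8, se = TRUE, se_cfg = cfg)
  s_plain <- stage_spec("s", 5, 3, 4, 8)
  ini <- init_stage_weights(s_se)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  # zero SE weights force all gates to 0.5: out_se = dec + 1.5 * resid
  W <- ini$weights
  for (nm in grep("\\.se\\.", names(W), value = TRUE)) W[[nm]] <- W[[nm]] * 0
  out_se <- se_rsu_forward(x, s_se, W, ini$bn)
  Wp <- W[setdiff(names(W), grep("\\.se\\.", names(W), value = TRUE))]
  out_plain <- rsu_forward(x, s_plain, Wp, ini$bn)
  inw <- list(w = W[["s.in.w"]], b = W[["s.in.b"]],
              gamma = W[["s.in.gamma"]], beta = W[["s.in.beta"]])
  resid <- conv_bn_relu(x, 3, 8, weights = inw)
  expect_equal(out_se - out_plain, 0.5 * resid, tolerance = 1e-10)
  # parameter additivity: SE-RSU = RSU + one SE unit
  expect_identical(n_params(ini$weights),
                   n_params(init_stage_weights(s_plain)$weights) +
                     n_params(seunet:::.init_se(cfg, 8)))
})
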