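# Training procedure: schedule analytics, optimizer semantics,
# checkpointing, evaluation plumbing.

test_that("cosine schedule hits its printed endpoints and halves mid-cycle", {
  cfg <- schedule_config()  # eta_max 0.0015, eta_min 0, T_i 5400
  expect_identical(cosine_lr(0, cfg), 0.0015)
  expect_equal(cosine_lr(2700, cfg), 0.00075, tolerance = 1e-15)
  clamped <- schedule_config(restart = FALSE)
  expect_equal(cosine_lr(5400, clamped), 0, tolerance = 1e-18)
  expect_equal(cosine_lr(9000, clamped), 0, tolerance = 1e-18)
  # warm restart: the rate returns to eta_max at each cycle start
  expect_identical(cosine_lr(5400, cfg), 0.0015)
  # continuous and non-increasing within a cycle
  lr <- cosine_lr(0:5400, clamped)
  expect_true(all(diff(lr) <= 0))
  expect_lt(max(abs(diff(lr))), 1e-6)
  expect_error(schedule_config(eta_max = 0.001, eta_min = 0.002))
})

test_that("a zero-learning-rate step leaves every weight bit-identical", {
  dat <- list(images = array(runif(32 * 32 * 2), c(32, 32, 2)),
              masks = array(sample(0:1, 32 * 32 * 2, TRUE), c(32, 32, 2)))
  m <- seunet_build(smoke_config(), seed = 4)
  m2 <- seunet_train(m, dat$images, dat$masks,
                     train_config(batch_size = 2, total_iters = 1,
                                  checkpoint_every = 1),
                     schedule_config(eta_max = 0, eta_min = 0, T_i = 10))
  expect_identical(m2$weights, m$weights)
})

test_that("checkpoint cadence and log structure follow the configuration", {
  # the published cadence: total/every = 9000/900 = 10 checkpoints
  expect_identical(train_config()$total_iters %/% train_config()$checkpoint_every,
                   10L)
  dat <- list(images = array(runif(32 * 32 * 2), c(32, 32, 2)),
              masks = array(sample(0:1, 32 * 32 * 2, TRUE), c(32, 32, 2)))
  m <- seunet_build(smoke_config(), seed = 4)
  tcfg <- train_config(batch_size = 1, total_iters = 6, checkpoint_every = 2)
  m2 <- seunet_train(m, dat$images, dat$masks, tcfg,
                     schedule_config(T_i = 6, restart = FALSE))
  expect_length(m2$checkpoints, 3)
  expect_identical(vapply(m2$checkpoints, function(c) c$iter, integer(1)),
                   c(2L, 4L, 6L))
  expect_identical(nrow(m2$log), 6L)
  expect_true(all(is.finite(m2$log$loss)))
  # fixed seed reproduces the first-step loss exactly
  m3 <- seunet_train(m, dat$images, dat$masks, tcfg,
                     schedule_config(T_i = 6, restart = FALSE))
  expect_identical(m2$log$loss[1], m3$log$loss[1])
})

test_that("argmax prediction breaks ties toward background", {
  m <- seunet_build(smoke_config(), seed = 1)
  # zero heads give identically zero logits everywhere: all ties -> class 0
  for (nm in grep("^(side|fuse)", names(m$weights), value = TRUE))
    m$weights[[nm]] <- m$weights[[nm]] * 0
  pred <- seunet_predict(m, array(runif(32 * 32), c(32, 32, 1)))
  expect_true(all(pred == 0L))
})

test_that("evaluation of ground truth is perfect; constant background zeroes kappa", {
  truth <- matrix(sample(0:1, 64, TRUE), 8)
  rep <- metric_report(accumulate(truth, truth), percent = TRUE)
  expect_equal(c(rep$iou, rep$acc, rep$kappa, rep$dice), rep(100, 4))
  rep0 <- metric_report(accumulate(matrix(0L, 8, 8), truth), percent = TRUE)
  expect_equal(rep0$kappa, 0)
  m <- seunet_build(smoke_config(), seed = 1)
  expect_error(seunet_evaluate(m, array(0, c(32, 32, 0)),
                               array(0L, c(32, 32, 0))), "empty")
})

test_that("the fit front end returns a classed model with working methods", {
  dat <- smoke_data(n = 2L)
  imgs <- dat$images[1:64, 1:64, , drop = FALSE]
  msk <- dat$masks[1:64, 1:64, , drop = FALSE]
  fit <- seunet(imgs, msk,
                train = train_config(batch_size = 2, total_iters = 2,
                                     checkpoint_every = 2),
                schedule = schedule_config(T_i = 2, restart = FALSE))
  expect_s3_class(fit, "seunet")
  expect_output(print(fit), "Nested-U")
  pred <- predict(fit, imgs)
  expect_identical(dim(pred), dim(imgs))
  pr <- predict(fit, imgs[, , 1], type = "prob")
  expect_equal(range(apply(pr, c(1, 2, 4), sum)), c(1, 1), tolerance = 1e-6)
  expect_silent(grDevices::pdf(NULL)); plot(fit); grDevices::dev.off()
  # file-level prediction writes binary masks of the input size
  td <- withr::local_tempdir()
  ip <- file.path(td, "in.png")
  png::writePNG(imgs[, , 1], ip)
  mp <- predict_to_png(fit, ip, td)
  mk <- round(png::readPNG(mp) * 255)
  expect_true(all(mk %in% c(0, 255)))
  expect_identical(dim(mk), c(64L, 64L))
})
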