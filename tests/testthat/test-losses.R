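# Loss functions: closed-form values, oracle agreement, mixture linearity,
# deep supervision.

test_that("cross entropy matches closed forms and the scalar-loop oracle", {
  # perfect confident prediction scores zero
  pred <- array(0, c(2, 2, 2, 1)); pred[, , 1, ] <- 1
  target <- array(0L, c(2, 2, 1))
  expect_equal(cross_entropy(pred, target), 0, tolerance = 1e-10)
  # maximal uncertainty scores log 2
  pred[, , 1, ] <- 0.5; pred[, , 2, ] <- 0.5
  expect_equal(cross_entropy(pred, target), log(2), tolerance = 1e-12)
  set.seed(10)
  for (i in 1:20) {
    cs <- random_prob_case(4, 4)
    expect_equal(cross_entropy(cs$pred, cs$target),
                 oracle_ce(cs$pred, cs$target), tolerance = 1e-12)
  }
  # non-normalised input is rejected
  bad <- array(0.4, c(2, 2, 2, 1))
  expect_error(cross_entropy(bad, target), "normalized")
})

test_that("dice loss matches closed forms and a hand-computed soft case", {
  hard <- function(mask) {
    p <- array(0, c(dim(mask), 2, 1)[c(1, 2, 3, 4)])
    p <- array(0, c(nrow(mask), ncol(mask), 2, 1))
    p[, , 2, 1] <- mask; p[, , 1, 1] <- 1 - mask
    p
  }
  m <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(dice_loss(hard(m), array(m, c(2, 2, 1))), 0, tolerance = 1e-5)
  disj <- matrix(c(1, 1, 0, 0), 2)
  tgt <- array(matrix(c(0, 0, 1, 1), 2), c(2, 2, 1))
  expect_equal(dice_loss(hard(disj), tgt), 1, tolerance = 1e-5)
  # soft 2x2 case, hand arithmetic: p1 = (.8,.6,.3,.1), t = (1,0,1,0)
  p <- array(0, c(2, 2, 2, 1))
  p[, , 2, 1] <- matrix(c(0.8, 0.6, 0.3, 0.1), 2)
  p[, , 1, 1] <- 1 - p[, , 2, 1]
  t <- array(matrix(c(1L, 0L, 1L, 0L), 2), c(2, 2, 1))
  inter <- 0.8 + 0.3
  expect_equal(dice_loss(p, t),
               1 - (2 * inter + 1e-6) / (1.8 + 2 + 1e-6), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    cs <- random_prob_case(5, 3)
    expect_equal(dice_loss(cs$pred, cs$target),
                 oracle_dice_loss(cs$pred, cs$target), tolerance = 1e-12)
  }
})

test_that("bce matches closed forms and the loop oracle", {
  p <- array(0, c(2, 2, 2, 1)); p[, , 2, 1] <- 1; p[, , 1, 1] <- 0
  t <- array(1L, c(2, 2, 1))
  expect_equal(bce_loss(p, t), 0, tolerance = 1e-9)
  p[, , 2, 1] <- 0.5; p[, , 1, 1] <- 0.5
  expect_equal(bce_loss(p, t), log(2), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    cs <- random_prob_case(4, 6)
    expect_equal(bce_loss(cs$pred, cs$target),
                 oracle_bce(cs$pred, cs$target), tolerance = 1e-12)
  }
})

test_that("mixture is the 0.7/0.3 weighted sum and is linear in its weights", {
  set.seed(13)
  cs <- random_prob_case(6, 6)
  ce <- cross_entropy(cs$pred, cs$target)
  dl <- dice_loss(cs$pred, cs$target)
  w <- loss_weights()
  expect_identical(c(w$w_ce, w$w_dice), c(0.7, 0.3))
  expect_equal(mixture_loss(cs$pred, cs$target), 0.7 * ce + 0.3 * dl,
               tolerance = 1e-12)
  # linearity under weight scaling
  expect_equal(mixture_loss(cs$pred, cs$target, loss_weights(1.4, 0.6)),
               2 * mixture_loss(cs$pred, cs$target), tolerance = 1e-12)
  expect_true(ce >= 0 && dl >= 0 && bce_loss(cs$pred, cs$target) >= 0)
})

test_that("dice loss on hard masks is 1 - dice coefficient of the same masks", {
  set.seed(14)
  for (i in 1:10) {
    pm <- matrix(sample(0:1, 64, TRUE), 8)
    tm <- matrix(sample(0:1, 64, TRUE), 8)
    p <- array(0, c(8, 8, 2, 1))
    p[, , 2, 1] <- pm; p[, , 1, 1] <- 1 - pm
    cnt <- accumulate(pm, tm)
    expect_equal(dice_loss(p, array(tm, c(8, 8, 1))), 1 - dice_coeff(cnt),
                 tolerance = 1e-4)
  }
})

test_that("deep supervision sums per-output losses; fused-only reproduces mixture", {
  set.seed(15)
  cs <- random_prob_case(4, 4)
  single <- mixture_loss(cs$pred, cs$target)
  outs <- list(fused = cs$pred, sides = rep(list(cs$pred), 6))
  expect_equal(supervised_loss(outs, cs$target), 7 * single, tolerance = 1e-12)
  expect_equal(supervised_loss(outs, cs$target, fused_only = TRUE), single,
               tolerance = 1e-12)
  # the four arms select their component losses
  expect_equal(supervised_loss(outs, cs$target, loss = "ce", fused_only = TRUE),
               cross_entropy(cs$pred, cs$target), tolerance = 1e-12)
  expect_equal(supervised_loss(outs, cs$target, loss = "dice", fused_only = TRUE),
               dice_loss(cs$pred, cs$target), tolerance = 1e-12)
  expect_equal(supervised_loss(outs, cs$target, loss = "bce", fused_only = TRUE),
               bce_loss(cs$pred, cs$target), tolerance = 1e-12)
})
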