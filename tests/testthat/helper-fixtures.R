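# Shared fixtures, built in code at test time.

# The CPU-scale smoke dataset: 8 phantom slices (96x96) with the largest
# lesion cross-sections, normalised to [0,1], with binary lesion masks.
smoke_data <- function(phantom_seed = 7, n = 8L) {
  spec <- phantom_spec(seed = phantom_seed)
  vol <- make_phantom_volume(spec)
  area <- apply(vol$labels > 0, 3, sum)
  zs <- sort(order(area, decreasing = TRUE)[seq_len(n)])
  w <- window_spec()
  imgs <- array(0, c(spec$height, spec$width, n))
  msk <- array(0L, c(spec$height, spec$width, n))
  for (k in seq_len(n)) {
    imgs[, , k] <- slice_to_png(vol$image[, , zs[k]], w) / 255
    msk[, , k] <- (vol$labels[, , zs[k]] > 0) * 1L
  }
  list(images = imgs, masks = msk, slices = zs, spec = spec, volume = vol)
}

# a random normalised probability map and matching random target
random_prob_case <- function(h, w, n_classes = 2L, n = 1L) {
  logits <- array(stats::rnorm(h * w * n_classes * n), c(h, w, n_classes, n))
  list(pred = softmax_classes(logits),
       target = array(sample(0:(n_classes - 1), h * w * n, TRUE), c(h, w, n)))
}

# scalar-loop oracles, written directly from the formula definitions
oracle_ce <- function(pred, target) {
  d <- dim(pred)
  tot <- 0
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    tot <- tot - log(max(pred[i, j, target[i, j, n] + 1, n], 1e-12))
  tot / (d[1] * d[2] * d[4])
}

oracle_dice_loss <- function(pred, target, eps = 1e-6) {
  d <- dim(pred)
  inter <- 0; sp <- 0; st <- 0
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    p1 <- pred[i, j, 2, n]
    t1 <- as.numeric(target[i, j, n] == 1)
    inter <- inter + p1 * t1; sp <- sp + p1; st <- st + t1
  }
  1 - (2 * inter + eps) / (sp + st + eps)
}

oracle_bce <- function(pred, target) {
  d <- dim(pred)
  tot <- 0
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    p1 <- min(max(pred[i, j, 2, n], 1e-12), 1 - 1e-12)
    t1 <- as.numeric(target[i, j, n] == 1)
    tot <- tot - (t1 * log(p1) + (1 - t1) * log(1 - p1))
  }
  tot / (d[1] * d[2] * d[4])
}

oracle_confusion <- function(pred, truth, k = 2L) {
  ia <- pa <- la <- numeric(k)
  for (i in seq_along(pred)) {
    p <- pred[i]; t <- truth[i]
    pa[p + 1] <- pa[p + 1] + 1
    la[t + 1] <- la[t + 1] + 1
    if (p == t) ia[p + 1] <- ia[p + 1] + 1
  }
  list(intersect_area = ia, pred_area = pa, label_area = la)
}

# independent per-block parameter enumeration from the level list:
# conv unit = 9*cin*cout + cout (bias) + 2*cout (BN affine)
oracle_rsu_params <- function(height, inc, mid, out, dilated = FALSE) {
  unit <- function(ci, co) 9 * ci * co + 3 * co
  if (!dilated) {
    unit(inc, out) + unit(out, mid) +
      (height - 2) * unit(mid, mid) + unit(mid, mid) +
      (height - 2) * unit(2 * mid, mid) + unit(2 * mid, out)
  } else {
    unit(inc, out) + unit(out, mid) + 3 * unit(mid, mid) +
      2 * unit(2 * mid, mid) + unit(2 * mid, out)
  }
}
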