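# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A node is an environment holding a value, its parent nodes and a backward
# closure mapping the incoming gradient to one gradient per parent.  The
# graph is rebuilt on every forward pass (dynamic), and ag_backward() runs
# an iterative post-order traversal so deep nested-U graphs do not hit R's
# recursion limit.  Feature-map values are (H, W, C, N) arrays; squeeze
# descriptors are (C, N) matrices; losses are scalars.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

#' @keywords internal
ag_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  e$id <- .ag_counter$n
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_const <- function(value) ag_node(value)

#' @keywords internal
ag_param <- function(value, name) {
  n <- ag_node(value)
  n$name <- name
  n
}

# Reverse sweep: seed the root gradient and accumulate into every ancestor.
#' @keywords internal
ag_backward <- function(root, seed = 1) {
  order <- vector("list", 4096L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    } else if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, expanded = TRUE)
      for (p in nd$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
    }
  }
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim(root$value))
  for (i in seq_len(n_ord)) {
    nd <- order[[n_ord - i + 1L]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- per-channel helpers ----------------------------------------------------

# sum over (H, W, N) for each channel
.csum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# broadcast a length-C vector over an (H, W, C, N) shape
.bcast_c <- function(v, d) {
  aperm(array(v, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# ---- array ops --------------------------------------------------------------

#' @keywords internal
ag_conv2d <- function(x, w, b, pad, dil) {
  y <- .conv2d_fw(x$value, w$value, b$value, as.integer(pad), as.integer(dil))
  ag_node(y, list(x, w, b), function(g) {
    r <- .conv2d_bw(x$value, w$value, g, as.integer(pad), as.integer(dil))
    list(r$gx, r$gw, r$gb)
  })
}

#' @keywords internal
ag_relu <- function(x) {
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

#' @keywords internal
ag_maxpool2 <- function(x) {
  r <- .maxpool2_fw(x$value)
  xd <- dim(x$value)
  ag_node(r$y, list(x),
          function(g) list(.maxpool2_bw(r$idx, g, as.integer(xd))))
}

#' @keywords internal
ag_upsample <- function(x, ho, wo) {
  d <- dim(x$value)
  if (d[1] == ho && d[2] == wo) return(x)
  A <- .interp_matrix(ho, d[1])
  B <- .interp_matrix(wo, d[2])
  ag_node(.resize_sep(x$value, A, B), list(x),
          function(g) list(.resize_sep(g, t(A), t(B))))
}

#' @keywords internal
ag_concat_c <- function(a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  ag_node(y, list(a, b), function(g)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE]))
}

#' @keywords internal
ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

# Batch normalization.  In training mode batch statistics are used and the
# running moments in `state` (an environment keyed by layer name) are
# updated as a side effect; in evaluation mode the stored moments are used,
# making the op a fixed per-channel affine map.
#' @keywords internal
ag_bn <- function(x, gamma, beta, state, name, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- .csum(x$value) / m
    xc <- x$value - .bcast_c(mu, d)
    va <- .csum(xc * xc) / m
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * .bcast_c(istd, d)
    st <- state[[name]]
    ub <- if (m > 1) m / (m - 1) else 1
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * (va * ub)
    state[[name]] <- st
    y <- xhat * .bcast_c(gamma$value, d) + .bcast_c(beta$value, d)
    ag_node(y, list(x, gamma, beta), function(g) {
      dbeta <- .csum(g)
      dgamma <- .csum(g * xhat)
      dx <- .bcast_c(gamma$value * istd, d) *
        (g - .bcast_c(dbeta / m, d) - xhat * .bcast_c(dgamma / m, d))
      list(dx, dgamma, dbeta)
    })
  } else {
    st <- state[[name]]
    istd <- 1 / sqrt(st$var + eps)
    xhat <- (x$value - .bcast_c(st$mean, d)) * .bcast_c(istd, d)
    y <- xhat * .bcast_c(gamma$value, d) + .bcast_c(beta$value, d)
    ag_node(y, list(x, gamma, beta), function(g) {
      list(.bcast_c(gamma$value * istd, d) * g, .csum(g * xhat), .csum(g))
    })
  }
}

# ---- squeeze-and-excitation primitives -------------------------------------

# global average pool: (H, W, C, N) -> (C, N) channel descriptors
#' @keywords internal
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  y <- matrix(colSums(matrix(x$value, hw, d[3] * d[4])) / hw, d[3], d[4])
  ag_node(y, list(x), function(g)
    list(array(rep(as.vector(g) / hw, each = hw), d)))
}

#' @keywords internal
ag_reshape <- function(x, newdim) {
  old <- dim(x$value)
  v <- x$value
  dim(v) <- newdim
  ag_node(v, list(x), function(g) { dim(g) <- old; list(g) })
}

# affine map on a (rows, cols) matrix: W %*% x + b (b per output row)
#' @keywords internal
ag_affine <- function(w, x, b) {
  y <- w$value %*% x$value + b$value
  ag_node(y, list(w, x, b), function(g)
    list(g %*% t(x$value), t(w$value) %*% g, rowSums(g)))
}

#' @keywords internal
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# y = x * (1 + gates) with gates a (C, N) matrix broadcast over (H, W):
# the SE "scale" followed by the residual addition of the recalibrated map.
#' @keywords internal
ag_se_scale <- function(x, gates) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  gb <- array(rep(as.vector(gates$value), each = hw), d)
  ag_node(x$value * (1 + gb), list(x, gates), function(g)
    list(g * (1 + gb),
         matrix(colSums(matrix(g * x$value, hw, d[3] * d[4])), d[3], d[4])))
}

# ---- loss primitives --------------------------------------------------------

# channel softmax of logits (H, W, C, N)
#' @keywords internal
ag_softmax_c <- function(x) {
  d <- dim(x$value)
  C <- d[3]
  xm <- matrix(aperm(x$value, c(3, 1, 2, 4)), C)  # classes x pixels
  mx <- xm[1, ]
  if (C > 1) for (k in 2:C) mx <- pmax(mx, xm[k, ])
  e <- exp(xm - rep(mx, each = C))
  pm <- e / rep(colSums(e), each = C)
  p <- aperm(array(pm, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  ag_node(p, list(x), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2, 4)), C)
    dot <- colSums(gm * pm)
    dz <- pm * (gm - rep(dot, each = C))
    list(aperm(array(dz, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4)))
  })
}

# linear indices of the true-class probabilities in a (H, W, C, N) array
.true_class_index <- function(d, target) {
  hw <- d[1] * d[2]
  pix <- rep(seq_len(hw) - 1L, times = d[4])
  nn <- rep(seq_len(d[4]) - 1L, each = hw)
  pix + hw * (as.integer(target) + d[3] * nn) + 1L
}

#' @keywords internal
ag_ce_probs <- function(p, target, eps = 1e-12) {
  d <- dim(p$value)
  npix <- d[1] * d[2] * d[4]
  lin <- .true_class_index(d, target)
  pt <- pmax(p$value[lin], eps)
  ag_node(-sum(log(pt)) / npix, list(p), function(g) {
    gp <- array(0, d)
    gp[lin] <- -g / (npix * pt)
    list(gp)
  })
}

#' @keywords internal
ag_dice_probs <- function(p, target, eps = 1e-6) {
  d <- dim(p$value)
  t1 <- array(as.numeric(target == 1), c(d[1], d[2], 1, d[4]))
  p1 <- p$value[, , 2, , drop = FALSE]
  inter <- sum(p1 * t1)
  denom <- sum(p1) + sum(t1) + eps
  ag_node(1 - (2 * inter + eps) / denom, list(p), function(g) {
    gp <- array(0, d)
    gp[, , 2, ] <- -g * (2 * t1 * denom - (2 * inter + eps)) / denom^2
    list(gp)
  })
}

#' @keywords internal
ag_bce_probs <- function(p, target, eps = 1e-12) {
  d <- dim(p$value)
  npix <- d[1] * d[2] * d[4]
  t1 <- array(as.numeric(target == 1), c(d[1], d[2], 1, d[4]))
  p1 <- pmin(pmax(p$value[, , 2, , drop = FALSE], eps), 1 - eps)
  v <- -sum(t1 * log(p1) + (1 - t1) * log(1 - p1)) / npix
  ag_node(v, list(p), function(g) {
    gp <- array(0, d)
    gp[, , 2, ] <- g * (-(t1 / p1) + (1 - t1) / (1 - p1)) / npix
    list(gp)
  })
}

# weighted sum of scalar nodes
#' @keywords internal
ag_wsum <- function(nodes, weights) {
  v <- sum(weights * vapply(nodes, function(n) n$value, numeric(1)))
  ag_node(v, nodes, function(g) as.list(weights * g))
}
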