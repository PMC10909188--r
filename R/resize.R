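# Separable bilinear / nearest resampling used by the upsampling op and the
# PNG exporter.  Bilinear uses half-pixel-centre sampling (the convention of
# the mainstream deep-learning frameworks without corner alignment), so
# resizing is linear and its adjoint is the transposed interpolation matrix.

#' @keywords internal
.interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  fr <- src - i0
  lo <- pmin(pmax(i0, 0), n_in - 1) + 1
  hi <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - fr[i])
    A[i, hi[i]] <- A[i, hi[i]] + fr[i]
  }
  A
}

# Apply row operator A (ho x H) and column operator B (wo x W) to every
# channel/sample plane of x (H, W, C, N): y[,,c,n] = A %*% x[,,c,n] %*% t(B).
#' @keywords internal
.resize_sep <- function(x, A, B) {
  d <- dim(x)
  ho <- nrow(A)
  wo <- nrow(B)
  y <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])
  y <- aperm(array(y, c(ho, d[2], d[3], d[4])), c(2, 1, 3, 4))
  y <- B %*% matrix(y, d[2], ho * d[3] * d[4])
  aperm(array(y, c(wo, ho, d[3], d[4])), c(2, 1, 3, 4))
}

#' @keywords internal
.resize_bilinear <- function(x, ho, wo) {
  d <- dim(x)
  if (d[1] == ho && d[2] == wo) return(x)
  .resize_sep(x, .interp_matrix(ho, d[1]), .interp_matrix(wo, d[2]))
}

# Nearest-neighbour resize of a single 2D plane (used for label masks).
#' @keywords internal
.resize_nearest2d <- function(m, ho, wo) {
  d <- dim(m)
  if (d[1] == ho && d[2] == wo) return(m)
  ri <- pmin(pmax(floor((seq_len(ho) - 0.5) * d[1] / ho) + 1, 1), d[1])
  ci <- pmin(pmax(floor((seq_len(wo) - 0.5) * d[2] / wo) + 1, 1), d[2])
  m[ri, ci, drop = FALSE]
}
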