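# CT volume -> 2D slice preprocessing: locate the axial slice range carrying
# liver labels, binarize labels under the PUFH (binary lesion) or LiTS
# (retain tumor label only) convention, window and quantize HU slices to
# 8-bit PNG, and split volume ids 8:1:1 into train/val/test at volume level.

#' Display window for HU normalisation
#'
#' @param hu_min,hu_max window bounds in HU.  The default soft-tissue
#'   inclusive window is [-200, 300].
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(hu_min = -200, hu_max = 300) {
  if (!(hu_min < hu_max)) stop("degenerate window: hu_min must be < hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "window_spec")
}

#' Axial slice range containing liver labels
#'
#' Returns the inclusive 1-based range of axial slices with any relevant
#' label (any positive label under both conventions: lesion voxels for
#' PUFH-style binary labels, liver or tumor voxels for LiTS-style labels).
#'
#' @param labels 3D integer label array (slices along the 3rd axis).
#' @param convention `"pufh_binary"` or `"lits_three_class"`.
#' @return integer vector `c(z_first, z_last)`.
#' @export
liver_slice_range <- function(labels,
                              convention = c("pufh_binary", "lits_three_class")) {
  convention <- match.arg(convention)
  nz <- apply(labels > 0, 3, any)
  if (!any(nz))
    stop("empty range: no labelled voxels in any slice")
  c(which(nz)[1], which(nz)[sum(nz)])
}

#' Binarize a label slice to a lesion mask
#'
#' LiTS convention: tumor label 2 maps to 1, background 0 and liver 1 map
#' to 0 (only the tumor label is retained).  PUFH convention: any positive
#' label maps to 1.
#'
#' @param label_slice integer label matrix.
#' @param convention `"pufh_binary"` or `"lits_three_class"`.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_labels <- function(label_slice,
                            convention = c("pufh_binary", "lits_three_class")) {
  convention <- match.arg(convention)
  legal <- if (convention == "lits_three_class") 0:2 else 0:1
  bad <- setdiff(unique(as.vector(label_slice)), legal)
  if (length(bad))
    stop("unexpected label value ", paste(bad, collapse = ", "),
         " for convention ", convention)
  out <- if (convention == "lits_three_class")
    (label_slice == 2) * 1L else (label_slice > 0) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Window and quantize an HU slice to 8 bits
#'
#' Clips to the window, rescales linearly to 0..255, optionally resizes
#' (bilinear) to `size` x `size`, and rounds half-up.
#'
#' @param image_slice numeric HU matrix (finite values).
#' @param w a [window_spec()].
#' @param size optional output side length in pixels.
#' @return integer matrix with values in 0..255.
#' @export
slice_to_png <- function(image_slice, w = window_spec(), size = NULL) {
  if (any(!is.finite(image_slice))) stop("non-finite HU values in slice")
  v <- (pmin(pmax(image_slice, w$hu_min), w$hu_max) - w$hu_min) /
    (w$hu_max - w$hu_min)
  if (!is.null(size)) {
    dim(v) <- c(dim(v), 1L, 1L)
    v <- .resize_bilinear(v, size, size)[, , 1, 1]
    v <- pmin(pmax(v, 0), 1)
  }
  m <- floor(v * 255 + 0.5)
  storage.mode(m) <- "integer"
  m
}

#' Export a labelled volume as PNG training pairs
#'
#' Writes one image/mask PNG pair per axial slice in the liver slice range,
#' with the convention's binarization rule applied to the masks (nearest-
#' neighbour resized when `size` differs from the native resolution), and a
#' JSON manifest recording volume id, slice indices, paths, window and
#' convention.
#'
#' @param rec a [volume_record()].
#' @param convention `"pufh_binary"` or `"lits_three_class"`.
#' @param out_dir output directory (created if needed).
#' @param w a [window_spec()].
#' @param size optional output side length (default: native size).
#' @return data frame manifest with columns `volume_id`, `slice`, `image`,
#'   `mask`.
#' @export
export_volume <- function(rec, convention, out_dir, w = window_spec(),
                          size = NULL) {
  stopifnot(inherits(rec, "volume_record"))
  rng <- liver_slice_range(rec$labels, convention)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", rng[2] - rng[1] + 1L)
  for (z in rng[1]:rng[2]) {
    ip <- file.path(out_dir, sprintf("%s_%03d_image.png", rec$id, z))
    mp <- file.path(out_dir, sprintf("%s_%03d_mask.png", rec$id, z))
    .write_png8(slice_to_png(rec$image[, , z], w, size), ip)
    mask <- binarize_labels(rec$labels[, , z], convention)
    if (!is.null(size)) mask <- .resize_nearest2d(mask, size, size)
    .write_png8(mask * 255L, mp)
    rows[[z - rng[1] + 1L]] <- data.frame(
      volume_id = rec$id, slice = z, image = ip, mask = mp,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(id = rec$id, convention = convention, window = unclass(w),
         size = if (is.null(size)) dim(rec$image)[1:2] else c(size, size),
         slice_range = rng, pairs = manifest),
    file.path(out_dir, paste0(rec$id, "_manifest.json")), auto_unbox = TRUE)
  manifest
}

#' Volume-level train/validation/test split
#'
#' Shuffles the volume ids under the seed and partitions them in the given
#' ratios with floor allocation for validation and test and the remainder
#' assigned to train.  Splitting at volume level keeps adjacent slices of
#' one scan inside a single split.
#'
#' @param ids character vector of volume ids.
#' @param ratios length-3 numeric ratios for train/val/test (default 8:1:1).
#' @param seed integer seed; identical seeds give identical assignments.
#' @return an object of class `split_assignment`: list with `assignment`
#'   (named character vector id -> split), `splits` (list of id vectors),
#'   `ratios`, `seed`.
#' @export
split_dataset <- function(ids, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  if (length(ids) < sum(ratios > 0))
    stop("need at least ", sum(ratios > 0), " ids for ",
         sum(ratios > 0), " nonzero split parts, got ", length(ids))
  if (anyDuplicated(ids)) stop("duplicated volume ids")
  n <- length(ids)
  perm <- .with_seed(seed, sample(ids))
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  splits <- list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)])
  assignment <- stats::setNames(rep(names(splits), lengths(splits)),
                                unlist(splits, use.names = FALSE))
  structure(list(assignment = assignment[ids], splits = splits,
                 ratios = ratios, seed = as.integer(seed)),
            class = "split_assignment")
}
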