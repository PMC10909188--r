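# Synthetic CT phantom generator: a stack of axial slices containing a
# large bright ellipsoidal "liver" enclosing one or more darker spherical
# "lesion" blobs, with per-voxel Gaussian noise, and paired label volumes
# in either the binary-lesion (PUFH-style) or the three-class
# background/liver/tumor (LiTS-style) convention.  All outputs are
# deterministic functions of the spec, including its seed.

#' Specification of a synthetic CT phantom
#'
#' Default intensities mimic contrast abdominal CT: background air at
#' -1000 HU, liver parenchyma 60 +/- 10 HU, hypodense lesions 0 +/- 15 HU,
#' with 5 HU additive noise everywhere.  The default geometry is a
#' 96 x 96 x 24 volume (fast on CPU); pass `height = width = 512` for
#' full-resolution slices.
#'
#' @param n_slices number of axial slices.
#' @param height,width in-plane size in pixels.
#' @param liver_center (row, col, slice) centre of the liver ellipsoid.
#' @param liver_axes semi-axes of the liver ellipsoid in voxels.
#' @param n_lesions number of spherical lesions.
#' @param lesion_radius_range min/max lesion radius in voxels.
#' @param liver_intensity_mean,liver_intensity_sd liver tissue HU.
#' @param lesion_intensity_mean,lesion_intensity_sd lesion tissue HU.
#' @param background_intensity background HU.
#' @param noise_sd additive Gaussian noise, HU.
#' @param label_convention `"pufh_binary"` (lesion = 1) or
#'   `"lits_three_class"` (liver = 1, tumor = 2).
#' @param spacing voxel spacing in mm (row, col, slice).
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 24L, height = 96L, width = 96L,
                         liver_center = NULL, liver_axes = NULL,
                         n_lesions = 3L, lesion_radius_range = c(3, 7),
                         liver_intensity_mean = 60, liver_intensity_sd = 10,
                         lesion_intensity_mean = 0, lesion_intensity_sd = 15,
                         background_intensity = -1000, noise_sd = 5,
                         label_convention = c("pufh_binary", "lits_three_class"),
                         spacing = c(0.7, 0.7, 5.0), seed = 1L) {
  label_convention <- match.arg(label_convention)
  if (is.null(liver_center))
    liver_center <- c(height / 2, width / 2, n_slices / 2)
  if (is.null(liver_axes))
    liver_axes <- c(0.36 * height, 0.28 * width, 0.38 * n_slices)
  spec <- structure(list(
    n_slices = as.integer(n_slices), height = as.integer(height),
    width = as.integer(width), liver_center = liver_center,
    liver_axes = liver_axes, n_lesions = as.integer(n_lesions),
    lesion_radius_range = lesion_radius_range,
    liver_intensity_mean = liver_intensity_mean,
    liver_intensity_sd = liver_intensity_sd,
    lesion_intensity_mean = lesion_intensity_mean,
    lesion_intensity_sd = lesion_intensity_sd,
    background_intensity = background_intensity, noise_sd = noise_sd,
    label_convention = label_convention, spacing = spacing,
    seed = as.integer(seed)), class = "phantom_spec")
  .check_phantom_spec(spec)
  spec
}

.check_phantom_spec <- function(spec) {
  dims <- c(spec$height, spec$width, spec$n_slices)
  lo <- spec$liver_center - spec$liver_axes
  hi <- spec$liver_center + spec$liver_axes
  if (any(lo < 1) || any(hi > dims))
    stop("phantom geometry infeasible: liver ellipsoid (centre ",
         paste(spec$liver_center, collapse = ","), ", axes ",
         paste(signif(spec$liver_axes, 3), collapse = ","),
         ") does not fit inside a ", paste(dims, collapse = "x"), " volume")
  if (spec$n_lesions > 0 &&
      max(spec$lesion_radius_range) >= min(spec$liver_axes))
    stop("phantom geometry infeasible: maximum lesion radius ",
         max(spec$lesion_radius_range), " must be smaller than the ",
         "smallest liver semi-axis ", signif(min(spec$liver_axes), 3))
  invisible(spec)
}

#' A 3D image/label volume pair
#'
#' @param image 3D numeric array of HU values.
#' @param labels 3D integer label array, congruent with `image`.
#' @param spacing positive voxel spacing in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @param id volume identifier string.
#' @return an object of class `volume_record`.
#' @export
volume_record <- function(image, labels, spacing, affine = NULL, id = "vol") {
  stopifnot(identical(dim(image), dim(labels)), all(spacing > 0))
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  structure(list(image = image, labels = labels, spacing = as.numeric(spacing),
                 affine = affine, id = id),
            class = "volume_record")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic CT phantom volume
#'
#' Lesion centres are sampled strictly inside the liver ellipsoid with the
#' whole sphere contained in the liver, and lesions are kept disjoint (at
#' least one voxel apart) so connected components correspond one-to-one to
#' lesions.  Liver voxels are drawn around the liver intensity, lesion
#' voxels around the lesion intensity, and Gaussian noise of `noise_sd` is
#' added everywhere.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_record()] whose labels follow `spec$label_convention`.
#' @export
make_phantom_volume <- function(spec) {
  .check_phantom_spec(spec)
  .with_seed(spec$seed, {
    dims <- c(spec$height, spec$width, spec$n_slices)
    ax <- spec$liver_axes
    ct <- spec$liver_center
    d2 <- outer(outer(((seq_len(dims[1]) - ct[1]) / ax[1])^2,
                      ((seq_len(dims[2]) - ct[2]) / ax[2])^2, "+"),
                ((seq_len(dims[3]) - ct[3]) / ax[3])^2, "+")
    liver <- d2 <= 1
    lesion <- array(FALSE, dims)
    centres <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    if (spec$n_lesions > 0) {
      rmin <- min(spec$lesion_radius_range)
      rmax <- max(spec$lesion_radius_range)
      for (i in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          r <- stats::runif(1, rmin, rmax)
          c3 <- ct + (2 * stats::runif(3) - 1) * ax
          en <- sqrt(sum(((c3 - ct) / ax)^2))
          if (en > 1 - r / min(ax)) next
          if (nrow(centres) &&
              any(sqrt(colSums((t(centres) - c3)^2)) < radii + r + 1)) next
          centres <- rbind(centres, c3)
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("phantom geometry infeasible: could not place ", spec$n_lesions,
               " disjoint lesions of radius ", rmin, "..", rmax,
               " inside the liver; reduce n_lesions or the radii")
      }
      for (i in seq_along(radii)) {
        c3 <- centres[i, ]
        s2 <- outer(outer((seq_len(dims[1]) - c3[1])^2,
                          (seq_len(dims[2]) - c3[2])^2, "+"),
                    (seq_len(dims[3]) - c3[3])^2, "+")
        lesion <- lesion | (s2 <= radii[i]^2)
      }
    }
    image <- array(spec$background_intensity, dims)
    nl <- sum(liver)
    image[liver] <- stats::rnorm(nl, spec$liver_intensity_mean,
                                 spec$liver_intensity_sd)
    ns <- sum(lesion)
    if (ns > 0)
      image[lesion] <- stats::rnorm(ns, spec$lesion_intensity_mean,
                                    spec$lesion_intensity_sd)
    image <- image + stats::rnorm(length(image), 0, spec$noise_sd)
    labels <- array(0L, dims)
    if (spec$label_convention == "lits_three_class") {
      labels[liver] <- 1L
      labels[lesion] <- 2L
    } else {
      labels[lesion] <- 1L
    }
    volume_record(image, labels, spec$spacing,
                  id = paste0("phantom-", spec$seed))
  })
}

#' Write / read a volume pair as NIfTI
#'
#' `write_nifti()` writes `<stem>_image.nii.gz` and `<stem>_label.nii.gz`
#' carrying the arrays, voxel spacing and affine; `read_nifti()` restores a
#' [volume_record()] that round-trips element-wise.
#'
#' @param rec a [volume_record()].
#' @param stem output path prefix (directories must exist).
#' @return `write_nifti()`: named character vector of the two paths,
#'   invisibly.  `read_nifti()`: a `volume_record`.
#' @export
write_nifti <- function(rec, stem) {
  stopifnot(inherits(rec, "volume_record"))
  paths <- c(image = paste0(stem, "_image.nii.gz"),
             label = paste0(stem, "_label.nii.gz"))
  aff <- structure(rec$affine, code = 2L)
  img <- RNifti::asNifti(rec$image)
  RNifti::pixdim(img) <- rec$spacing
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, paths[["image"]])
  lab <- rec$labels
  storage.mode(lab) <- "integer"
  lab <- RNifti::asNifti(lab)
  RNifti::pixdim(lab) <- rec$spacing
  RNifti::sform(lab) <- aff
  RNifti::writeNifti(lab, paths[["label"]], datatype = "int16")
  invisible(paths)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, "_image.nii.gz"))
  lab <- RNifti::readNifti(paste0(stem, "_label.nii.gz"))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  labs <- as.array(lab)
  storage.mode(labs) <- "integer"
  volume_record(as.array(img), labs,
                spacing = RNifti::pixdim(img), affine = aff,
                id = basename(stem))
}

#' Export a phantom as a 2D PNG slice dataset
#'
#' Generates the phantom and writes one 8-bit grayscale image PNG and one
#' binary lesion-mask PNG (pixel values 0/255) per slice, plus a JSON
#' manifest listing the pairs in slice order.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @param window a [window_spec()] used to normalise HU for display.
#' @return data frame manifest with columns `slice`, `image`, `mask`.
#' @export
make_slice_dataset <- function(spec, out_dir, window = window_spec()) {
  rec <- make_phantom_volume(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lesion_class <- if (spec$label_convention == "lits_three_class") 2L else 1L
  n <- spec$n_slices
  rows <- vector("list", n)
  for (z in seq_len(n)) {
    ip <- file.path(out_dir, sprintf("slice_%03d_image.png", z))
    mp <- file.path(out_dir, sprintf("slice_%03d_mask.png", z))
    .write_png8(slice_to_png(rec$image[, , z], window), ip)
    mask <- 255L * (rec$labels[, , z] == lesion_class)
    .write_png8(mask, mp)
    rows[[z]] <- data.frame(slice = z, image = ip, mask = mp,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(id = rec$id, convention = spec$label_convention,
         window = unclass(window), pairs = manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  manifest
}

# write an integer 0..255 matrix as an 8-bit grayscale PNG
.write_png8 <- function(m, path) {
  png::writePNG(m / 255, path)
}
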