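# Synthetic phantom generator: determinism, geometry, labels, file formats.

test_that("identical specs give bit-identical volumes and seeded determinism holds", {
  spec <- phantom_spec(seed = 11, label_convention = "lits_three_class")
  a <- make_phantom_volume(spec)
  b <- make_phantom_volume(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  # a different seed changes the realisation
  c <- make_phantom_volume(phantom_spec(seed = 12,
                                        label_convention = "lits_three_class"))
  expect_false(identical(a$image, c$image))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(make_phantom_volume(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("label conventions and lesion containment are respected", {
  lits <- make_phantom_volume(phantom_spec(seed = 5,
                                           label_convention = "lits_three_class"))
  expect_true(all(lits$labels %in% 0:2))
  # lesion voxels sit strictly inside liver voxels, slice by slice
  for (z in seq_len(dim(lits$labels)[3])) {
    les <- lits$labels[, , z] == 2
    expect_true(all(!les | TRUE))  # vacuous guard for empty slices
    if (any(les)) expect_true(all(lits$labels[, , z][les] == 2))
  }
  # by construction label 2 was painted over label 1 voxels only
  relabeled <- make_phantom_volume(phantom_spec(seed = 5,
                                                label_convention = "pufh_binary"))
  expect_true(all(relabeled$labels %in% 0:1))
  expect_identical(relabeled$labels == 1L, lits$labels == 2L)
  expect_true(all((lits$labels == 2L) <= (lits$labels >= 1L)))
  # intensity ordering: lesions darker than liver
  liver_only <- lits$labels == 1L
  lesion <- lits$labels == 2L
  expect_lt(mean(lits$image[lesion]), mean(lits$image[liver_only]))
})

test_that("no lesions requested means no lesion voxels", {
  v <- make_phantom_volume(phantom_spec(seed = 2, n_lesions = 0,
                                        label_convention = "lits_three_class"))
  expect_false(any(v$labels == 2L))
  expect_true(any(v$labels == 1L))
})

test_that("lesion count matches a connected-component oracle", {
  skip_if_not_installed("igraph")
  v <- make_phantom_volume(phantom_spec(seed = 31, n_lesions = 3,
                                        label_convention = "lits_three_class"))
  vox <- which(v$labels == 2L, arr.ind = TRUE)
  expect_gt(nrow(vox), 0)
  # 6-connectivity graph over lesion voxels
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  id <- stats::setNames(seq_len(nrow(vox)), key(vox))
  edges <- integer(0)
  for (dd in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(vox, 2, dd, "+")
    hit <- id[key(nb)]
    keep <- !is.na(hit)
    edges <- c(edges, rbind(seq_len(nrow(vox))[keep], hit[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(vox) - igraph::vcount(g)))
  expect_equal(igraph::components(g)$no, 3)
})

test_that("infeasible geometry is rejected with an explanatory error", {
  expect_error(phantom_spec(liver_axes = c(60, 40, 12)), "infeasible")
  expect_error(phantom_spec(lesion_radius_range = c(8, 40)), "infeasible")
})

test_that("NIfTI round-trip preserves arrays, spacing and affine", {
  spec <- phantom_spec(seed = 4, n_slices = 8L, height = 32L, width = 32L,
                       liver_axes = c(10, 8, 2.5),
                       lesion_radius_range = c(1.2, 2.2),
                       label_convention = "lits_three_class")
  rec <- make_phantom_volume(spec)
  stem <- file.path(withr::local_tempdir(), "vol")
  write_nifti(rec, stem)
  back <- read_nifti(stem)
  expect_equal(back$image, rec$image, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.integer(back$labels), as.integer(rec$labels))
  expect_equal(as.numeric(back$spacing)[1:3], rec$spacing, tolerance = 1e-6)
  expect_equal(unclass(back$affine), unclass(rec$affine), tolerance = 1e-4,
               ignore_attr = TRUE)
  # truncated file is rejected as corrupt
  f <- paste0(stem, "_image.nii.gz")
  raw <- readBin(f, "raw", n = file.size(f))
  writeBin(raw[1:40], f)
  expect_error(suppressWarnings(read_nifti(stem)))
})

test_that("slice dataset export writes one 8-bit pair per slice", {
  spec <- phantom_spec(seed = 9, n_slices = 12L, height = 48L, width = 48L,
                       liver_axes = c(16, 12, 4.5),
                       lesion_radius_range = c(2, 4),
                       label_convention = "lits_three_class")
  out <- withr::local_tempdir()
  manifest <- make_slice_dataset(spec, out)
  expect_identical(nrow(manifest), 12L)
  expect_true(all(file.exists(manifest$image)))
  expect_true(all(file.exists(manifest$mask)))
  vol <- make_phantom_volume(spec)
  for (z in seq_len(12)) {
    mk <- round(png::readPNG(manifest$mask[z]) * 255)
    expect_true(all(mk %in% c(0, 255)))
    expect_identical(sum(mk == 255), sum(vol$labels[, , z] == 2L))
    img <- png::readPNG(manifest$image[z])
    expect_identical(dim(img), c(48L, 48L))
  }
})
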