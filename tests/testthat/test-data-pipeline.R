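# NIfTI round trips, normalization, slicing, bicubic degradation, splitting
# and foreground masking.

test_that("NIfTI volumes round-trip within storage precision", {
  vox <- array(runif(8 * 10 * 6), dim = c(8, 10, 6))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(image_volume(vox, spacing = c(0.7, 0.7, 0.7)), path)
  v <- load_volume(path, contrast = "T1w")
  expect_equal(v$voxels, vox, tolerance = 1e-6)
  expect_equal(v$spacing, c(0.7, 0.7, 0.7), tolerance = 1e-6)
  expect_error(load_volume(tempfile(fileext = ".nii")), "not found")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), p4)
  expect_error(load_volume(p4), "4D")
})

test_that("min-max normalization maps onto [0,1] and inverts", {
  vox <- array(runif(4 * 4 * 4, 10, 20), dim = c(4, 4, 4))
  vox[1] <- 10; vox[2] <- 20; vox[3] <- 15
  v <- minmax_normalize(image_volume(vox))
  expect_equal(range(v$voxels), c(0, 1))
  expect_equal(v$voxels[which(vox == 15)[1]], 0.5, tolerance = 1e-12)
  back <- denormalize_volume(v)
  expect_equal(back$voxels, vox, tolerance = 1e-6)
  expect_warning(minmax_normalize(image_volume(array(3, dim = c(2, 2, 2)))),
                 "constant")
})

test_that("central slice extraction is centered with warnings for short volumes", {
  v <- image_volume(array(rep(1:176, each = 4), dim = c(2, 2, 176)))
  sl <- central_slices(v, 100)
  expect_length(sl, 100)
  expect_equal(as.integer(names(sl)[1]), 38L)            # floor((176-100)/2)
  expect_equal(as.integer(names(sl)[100]), 137L)
  v2 <- image_volume(array(0, dim = c(2, 2, 100)))
  expect_length(central_slices(v2, 100), 100)
  v3 <- image_volume(array(0, dim = c(2, 2, 50)))
  expect_warning(sl3 <- central_slices(v3, 100), "all slices")
  expect_length(sl3, 50)
})

test_that("bicubic degradation matches the 2D kernel oracle", {
  # impulse response against a full non-separable direct summation
  imp <- matrix(0, 18, 18); imp[9, 9] <- 1
  lr <- degrade_bicubic(imp, 2)
  expect_equal(dim(lr), c(9L, 9L))
  expect_equal(unclass(lr)[, ], bicubic_down_oracle(imp, 2),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(61)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(unclass(degrade_bicubic(img, 4))[, ], bicubic_down_oracle(img, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("bicubic degradation preserves constants and commutes with affine maps", {
  cst <- matrix(0.3, 24, 24)
  expect_equal(as.vector(degrade_bicubic(cst, 2)), rep(0.3, 144), tolerance = 1e-6)
  set.seed(62)
  x <- matrix(runif(64 * 64), 64, 64)
  a <- 1.7; b <- -0.4
  expect_equal(unclass(degrade_bicubic(a * x + b, 2)),
               unclass(a * degrade_bicubic(x, 2) + b), tolerance = 1e-6)
  expect_equal(dim(degrade_bicubic(x, 2)), c(32L, 32L))
  expect_error(degrade_bicubic(matrix(0, 6, 6), 2), "kernel")
  expect_error(degrade_bicubic(x, 3), "scale factor")
  # non-divisible inputs are cropped, and the crop is recorded
  lr <- degrade_bicubic(matrix(runif(33 * 35), 33, 35), 2)
  expect_equal(dim(lr), c(16L, 17L))
  expect_equal(attr(lr, "crop"), c(1L, 1L))
})

test_that("subject split is deterministic, exhaustive and ratio-faithful", {
  ids <- sprintf("sub-%02d", 1:10)
  sp <- subject_split(ids, seed = 7)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 7L, val = 2L, test = 1L))
  expect_identical(sp, subject_split(ids, seed = 7))
  expect_false(identical(sp$train, subject_split(ids, seed = 8)$train))
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_error(subject_split(c("a", "b")), "at least 3")
  # disjoint and exhaustive over many random draws
  set.seed(63)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    sp_i <- subject_split(sprintf("s%03d", seq_len(n)), seed = sample(1e6, 1))
    ids_i <- c(sp_i$train, sp_i$val, sp_i$test)
    expect_equal(sort(ids_i), sprintf("s%03d", seq_len(n)))
    expect_gte(length(sp_i$test), 1L)
  }
})

test_that("foreground mask finds the head, is idempotent, handles empties", {
  expect_false(any(foreground_mask(matrix(0, 16, 16))))
  ph <- generate_phantom(phantom_spec(shape = c(2L, 64L, 64L), seed = 8))
  sl <- minmax_normalize(ph$volume)$voxels[, , 1]
  fg <- foreground_mask(sl)
  head_area <- sum(!ph$masks$background[, , 1])
  expect_lt(abs(sum(fg) - head_area) / head_area, 0.05)
  masked <- sl * fg
  expect_equal(foreground_mask(masked), fg)
})

test_that("pair building composes normalization, slicing and degradation", {
  vols <- list(
    image_volume(array(runif(16 * 16 * 6, 0, 100), dim = c(16, 16, 6)),
                 subject_id = "s2"),
    image_volume(array(runif(16 * 16 * 8, 0, 50), dim = c(16, 16, 8)),
                 subject_id = "s1"))
  pairs <- build_pairs(vols, r = 2, n_central = 4)
  expect_length(pairs, 8)
  expect_equal(vapply(pairs, function(p) p$subject_id, character(1)),
               rep(c("s1", "s2"), each = 4))              # deterministic order
  for (p in pairs) {
    expect_equal(dim(p$hr), 2L * dim(p$lr))
    expect_true(all(p$hr >= 0 & p$hr <= 1))
  }
  pairs2 <- build_pairs(vols, r = 2, n_central = 4)
  expect_identical(pairs, pairs2)                         # byte-identical rebuild
  manifest <- write_pair_manifest(pairs, tempfile(fileext = ".tsv"))
  expect_equal(nrow(manifest), 8)
})
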