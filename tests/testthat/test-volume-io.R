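# Volume IO and 2.5D slice bookkeeping: NIfTI round trips, window extraction,
# normalization/padding with exact inversion, volume reassembly.

random_volume <- function(d = c(16, 16, 16), seed = 1, spacing = c(1, 1, 1)) {
  withr::with_seed(seed,
    mr_volume(array(runif(prod(d)), d), spacing = spacing, site_id = 0L,
              volume_id = "test"))
}

test_that("NIfTI save/load round trip preserves voxels and spacing", {
  v <- random_volume(spacing = c(1, 1.25, 2))
  path <- tempfile(fileext = ".nii.gz")
  save_volume(v, path)
  v2 <- load_volume(path)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing)
  expect_error(load_volume(tempfile(fileext = ".nii")), "does not exist")

  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(load_volume(p4), "4-D")
})

test_that("2.5D window extraction counts and edge replication are exact", {
  v <- random_volume(c(8, 8, 64))
  s60 <- extract_slices_25d(v, n_central = 60, stride = 1)
  expect_length(s60, 60)
  s20 <- extract_slices_25d(v, n_central = 60, stride = 3)
  expect_length(s20, 20)

  # channels are previous/center/next axial slices
  mid <- s60[[30]]
  ci <- mid$center_index
  expect_identical(mid$pixels[, , 2], v$voxels[, , ci])
  expect_identical(mid$pixels[, , 1], v$voxels[, , ci - 1])
  expect_identical(mid$pixels[, , 3], v$voxels[, , ci + 1])

  # edge replication at the volume boundary
  vall <- extract_slices_25d(random_volume(c(8, 8, 5)))
  expect_identical(vall[[1]]$pixels[, , 1], vall[[1]]$pixels[, , 2])

  thin <- mr_volume(array(0, c(8, 8, 2)))
  expect_error(extract_slices_25d(thin), "at least 3")
})

test_that("channel normalization maps range endpoints and inverts exactly", {
  px <- array(0, c(4, 4, 3))
  px[, , 1] <- matrix(c(0, 50, 100, seq(5, 95, length.out = 13)), 4, 4)
  px[, , 2] <- matrix(rnorm(16), 4, 4)
  px[, , 3] <- 7          # constant channel
  s <- as_slice25d(px)
  n <- normalize_channels(s)
  expect_true(all(n$pixels >= -1 & n$pixels <= 1))
  expect_equal(min(n$pixels[, , 1]), -1)
  expect_equal(max(n$pixels[, , 1]), 1)
  ch1 <- n$pixels[, , 1]
  expect_equal(ch1[px[, , 1] == 50], rep(0, sum(px[, , 1] == 50)))
  expect_true(all(n$pixels[, , 3] == 0))
  expect_true(n$norm_record[[3]]$degenerate)
  expect_false(n$norm_record[[1]]$degenerate)

  back <- denormalize_channels(n)
  expect_equal(back, px, tolerance = 1e-6, ignore_attr = TRUE)

  bad <- as_slice25d(array(c(NA, rep(0, 47)), c(4, 4, 3)))
  expect_error(normalize_channels(bad), "non-finite")
})

test_that("canvas padding centers content and crops back bit-exactly", {
  px <- array(rnorm(200 * 200 * 3), c(200, 200, 3))
  s <- as_slice25d(px)
  p <- pad_to_canvas(s, 256)
  expect_identical(p$pad_record$offset, c(28, 28))
  expect_identical(dim(p$pixels), c(256L, 256L, 3L))
  expect_identical(crop_back(p), px)

  # odd difference: extra pixel goes bottom/right
  s2 <- as_slice25d(array(1, c(5, 5, 3)))
  p2 <- pad_to_canvas(s2, 8)
  expect_identical(p2$pad_record$offset, c(1, 1))
  expect_identical(crop_back(p2), array(1, c(5, 5, 3)))

  big <- as_slice25d(array(0, c(300, 300, 3)))
  expect_error(pad_to_canvas(big, 256), "exceeds")
})

test_that("extract-normalize-pad-reassemble is the identity on the central band", {
  v <- random_volume(c(40, 44, 20), seed = 9)
  slices <- lapply(extract_slices_25d(v, n_central = 10), prep_slice, canvas = 64)
  expect_true(all(vapply(slices, function(s) all(s$pixels >= -1 & s$pixels <= 1), logical(1))))
  out <- reassemble_volume(slices, v)
  centers <- vapply(slices, function(s) s$center_index, integer(1))
  expect_equal(out$voxels[, , centers], v$voxels[, , centers], tolerance = 1e-5)
  # outside the band: copied bit-exactly from the template
  outside <- setdiff(seq_len(20), centers)
  expect_identical(out$voxels[, , outside], v$voxels[, , outside])

  dup <- c(slices, slices[1])
  expect_error(reassemble_volume(dup, v), "duplicate")
})
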