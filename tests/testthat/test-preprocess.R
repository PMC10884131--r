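make_stack <- function(n_slices, size = 16, pixel_mm = 1.6, slice_mm = 1.6,
                       modality = "pet") {
  vox <- array(0, c(size, size, n_slices))
  for (k in seq_len(n_slices)) vox[, , k] <- k  # slice index as intensity
  image_stack(vox, pixel_mm, slice_mm, modality = modality)
}

test_that("align_slice_counts picks nearest physical slices", {
  pet <- make_stack(24)
  out <- align_slice_counts(pet, 16)
  expect_equal(dim(out$voxels)[3], 16)
  # brute-force nearest-position search over all input slices
  L <- 24 * 1.6
  expected <- integer(16)
  for (j in 1:16) {
    target <- (j - 0.5) * L / 16
    best <- 1; bestd <- Inf
    for (i in 1:24) {
      d <- abs((i - 0.5) * 1.6 - target)
      if (d < bestd) { bestd <- d; best <- i }
    }
    expected[j] <- best
  }
  expect_equal(out$voxels[1, 1, ], as.numeric(expected))
  expect_equal(out$slice_mm, L / 16)
})

test_that("align_slice_counts is idempotent and handles degenerate stacks", {
  pet <- make_stack(16)
  expect_identical(align_slice_counts(pet, 16)$voxels, pet$voxels)
  one <- make_stack(1)
  rep5 <- align_slice_counts(one, 5)
  expect_equal(dim(rep5$voxels)[3], 5)
  expect_true(all(rep5$voxels == 1))
})

test_that("resample_and_crop magnifies 2.4 -> 1.6 and center-crops", {
  vox <- array(stats::runif(128 * 128 * 2), c(128, 128, 2))
  spect <- image_stack(vox * 100, 2.4, 2.4, modality = "spect")
  out <- resample_and_crop(spect, 1.6, 128)
  rec <- attr(out, "resample_record")
  expect_equal(rec$scale_factor, 2.4 / 1.6)
  expect_equal(rec$magnified_size, 192)
  expect_equal(dim(out$voxels)[1:2], c(128, 128))
  expect_equal(out$pixel_mm, 1.6)
  expect_error(resample_and_crop(spect, 1.6, 400), "smaller")
  # identical pixel size: center crop only
  same <- resample_and_crop(spect, 2.4, 64)
  expect_identical(same$voxels[1, 1, 1], spect$voxels[33, 33, 1])
})

test_that("a centered disc keeps its center through resample_and_crop", {
  n <- 64
  d <- sqrt(outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+"))
  img <- ifelse(d < 12, 50, 0)
  st <- image_stack(array(img, c(n, n, 1)), 2.4, 2.4, modality = "spect")
  out <- resample_and_crop(st, 1.6, 64)
  sl <- out$voxels[, , 1]
  centroid <- c(sum(row(sl) * sl), sum(col(sl) * sl)) / sum(sl)
  expect_equal(centroid, c(32.5, 32.5), tolerance = 0.05)
})

test_that("8-bit quantization maps the stack maximum to 255 and inverts", {
  vox <- array(stats::runif(10 * 10 * 3) * 73, c(10, 10, 3))
  st <- image_stack(vox, 1.6, 1.6)
  q <- to_uint8(st)
  expect_equal(max(q$voxels), 255)
  expect_equal(q$voxels[which.max(vox)], 255)
  expect_equal(q$scale_record$max, max(vox))
  # all-zero stack: all-zero output, unit scale
  z <- to_uint8(image_stack(array(0, c(4, 4, 1)), 1, 1))
  expect_true(all(z$voxels == 0))
  expect_equal(z$scale_record$max, 1)
  # round trip of an already-quantized stack is lossless (256 levels)
  grid <- image_stack(array(rep(0:255, length.out = 256) / 255 * 60,
                            c(16, 16, 1)), 1, 1)
  expect_equal(from_uint8(to_uint8(grid))$voxels, grid$voxels)
})

test_that("uptake conversion follows 100 * v / 255", {
  st <- image_stack(array(c(255, 0, 51, rep(0, 13)), c(4, 4, 1)), 1, 1,
                    scale = "uint8")
  u <- to_uptake(st)
  expect_equal(u$voxels[1], 100)
  expect_equal(u$voxels[2], 0)
  expect_equal(u$voxels[3], 20)
})

test_that("quantization error is bounded by half a level", {
  set.seed(1)
  vox <- array(stats::runif(20 * 20 * 2) * 100, c(20, 20, 2))
  vox[1] <- 100   # pin the maximum so uptake conversion preserves scale
  st <- image_stack(vox, 1.6, 1.6)
  back <- to_uptake(to_uint8(st))
  expect_lt(max(abs(back$voxels - vox)), 100 / 255 / 2 + 1e-9)
})

test_that("network resizing round-trips constants and keeps impulses centered", {
  const <- matrix(7.5, 32, 32)
  up <- resize_for_network(const, 64)
  expect_equal(dim(up), c(64, 64))
  expect_equal(downsize_after_network(up, 32), const)
  expect_error(resize_for_network(matrix(0, 4, 6), 8), "non-square")
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  rt <- downsize_after_network(resize_for_network(imp, 66), 33)
  peak <- which(rt == max(rt), arr.ind = TRUE)
  expect_true(all(abs(peak - 17) <= 1))
})

test_that("preprocess_pair produces matched geometry on the uptake scale", {
  pair <- quiet_pair(noise_scale = 0.5, seed = 5)
  pp <- preprocess_pair(pair$spect, pair$pet)
  expect_identical(dim(pp$spect$voxels), dim(pp$pet$voxels))
  expect_equal(pp$spect$pixel_mm, pp$pet$pixel_mm)
  expect_equal(max(pp$spect$voxels), 100)
  expect_equal(max(pp$pet$voxels), 100)
})
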