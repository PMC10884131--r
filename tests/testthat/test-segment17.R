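test_that("slab partition follows the 2/2/2/1 grouping with larger basal divisions", {
  p14 <- partition_slabs(14)
  expect_equal(p14$division_sizes, rep(2L, 7))
  expect_equal(p14$ring_slices$basal, 1:4)
  p7 <- partition_slabs(7)
  expect_equal(p7$division_sizes, rep(1L, 7))
  p16 <- partition_slabs(16)
  expect_equal(p16$division_sizes, c(3L, 3L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(sum(p16$division_sizes), 16)
  expect_error(partition_slabs(3))
  expect_warning(p5 <- partition_slabs(5))
  expect_true(all(lengths(p5$ring_slices) >= 1))
})

test_that("radial maximum profiles behave on constructed slices", {
  n <- 51; ctr <- c(26, 26)
  d <- sqrt(outer((1:n - 26)^2, (1:n - 26)^2, "+"))
  ring <- ifelse(d >= 8 & d <= 12, 50, 0)
  prof <- radial_max_profiles(ring, ctr)
  expect_length(prof, 360)
  expect_equal(prof, rep(50, 360))
  # single bright pixel on uniform background
  img <- matrix(10, n, n); img[26, 31] <- 90    # 5 px to the right: angle 0
  prof <- radial_max_profiles(img, ctr)
  expect_equal(prof[1], 90)
  expect_lt(max(abs(prof[16:346] - 10)), 1e-6)
  expect_error(radial_max_profiles(img, c(0, 26)), "inside")
})

test_that("profiles of a blurred ring match the per-ray scan oracle", {
  set.seed(2)
  n <- 41; ctr <- c(21, 21)
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  ring <- exp(-(d - 8)^2 / 6) * 70 + matrix(stats::runif(n * n), n, n)
  prof <- radial_max_profiles(ring, ctr)
  angles <- c(0, 17, 45, 90, 133, 201, 270, 318)
  for (a in angles) {
    expect_equal(prof[a + 1], oracle_ray_max(ring, ctr, a), tolerance = 1e-9)
    # 10x radial oversampling cannot find a much larger maximum
    expect_lt(oracle_ray_max(ring, ctr, a, oversample = 10) - prof[a + 1], 1)
  }
})

test_that("segment tables: uniformity, profile counts, and localized defects", {
  pair <- quiet_pair()
  tb <- segment_table(pair$spect)
  expect_equal(nrow(tb), 17)
  expect_equal(tb$value, rep(80, 17))
  # basal ring of 16-slice stack spans 6 slices: 60 profiles each
  expect_equal(tb$n_profiles[1:6], rep(60L * 6L, 6))
  expect_true(all(tb$n_profiles >= 1))
  # segment #4 scaled by 0.6 from 80 -> 48, non-adjacent segments untouched
  defected <- apply_defect(pair$spect, defect_spec(4, 0.4), c(24.5, 24.5))
  tb4 <- segment_table(defected, center = c(24.5, 24.5))
  expect_equal(tb4$value[4], 48, tolerance = 1e-12)
  expect_equal(tb4$value[setdiff(1:17, 3:5)], rep(80, 14))
})

test_that("segment values are monotone under global scaling", {
  pair <- quiet_pair(noise_scale = 0.5, seed = 11)
  st <- pair$spect
  tb1 <- segment_table(st, c(24.5, 24.5))
  half <- st; half$voxels <- st$voxels * 0.5
  tb2 <- segment_table(half, c(24.5, 24.5))
  expect_equal(tb2$value, tb1$value * 0.5, tolerance = 1e-12)
})

test_that("rotating the pathology by one sector permutes basal/mid values", {
  base <- quiet_pair(defects = list(defect_spec(c(4, 10), 0.4)))
  rot <- quiet_pair(defects = list(defect_spec(c(3, 9), 0.4)))
  tb_base <- segment_table(base$spect, c(24.5, 24.5))$value
  tb_rot <- segment_table(rot$spect, c(24.5, 24.5))$value
  # segment k of the rotated phantom equals segment k+1 of the original
  expect_equal(tb_rot[c(3, 9)], tb_base[c(4, 10)], tolerance = 1e-9)
  expect_equal(tb_rot[c(5, 11)], tb_base[c(6, 12)], tolerance = 1e-9)
})

test_that("representative values equal the brute-force loop implementation", {
  # 3 random noisy phantoms at identical sampling, 1e-9 agreement
  for (seed in 1:3) {
    pair <- random_case(seed, 400, matrix_size = 48,
                        attenuation = if (seed == 2) attenuation_spec(0.85) else NULL)
    ctr <- lv_center(pair$spect)
    tb <- segment_table(pair$spect, ctr)
    expect_equal(tb$value, oracle_segment_table(pair$spect, ctr),
                 tolerance = 1e-9)
  }
})
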