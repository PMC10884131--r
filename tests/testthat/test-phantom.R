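test_that("ring slices are constant annuli matching a per-pixel membership oracle", {
  cfg <- phantom_config(matrix_size = 48, noise_scale = 0)
  n_sl <- round(cfg$lv_length_mm / cfg$spect_slice_mm)
  for (k in c(1L, 8L)) {   # basal and mid slice
    img <- make_ring_slice(cfg, k)
    expect_true(all(img %in% c(0, cfg$baseline_uptake)))
    # independent pixel-count over the annulus inequality
    t <- (k - 0.5) / n_sl
    endo <- cfg$endo_radius_mm * (1 - 0.75 * t)
    epi <- cfg$epi_radius_mm * (1 - 0.40 * t)
    cnt <- 0
    for (r in 1:48) for (c in 1:48) {
      d <- sqrt((r - cfg$ring_center[1])^2 + (c - cfg$ring_center[2])^2) * 2.4
      if (d >= endo && d <= epi) cnt <- cnt + 1
    }
    expect_equal(sum(img > 0), cnt)
  }
  # apex slab slice is a filled disc (no cavity)
  apex <- make_ring_slice(cfg, n_sl)
  ctr <- round(cfg$ring_center)
  expect_gt(apex[ctr[1], ctr[2]], 0)
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_config(endo_radius_mm = 25, epi_radius_mm = 24))
  expect_error(phantom_config(baseline_uptake = 0))
  expect_error(phantom_config(matrix_size = 47))
})

test_that("apply_defect scales listed segments and nothing else", {
  pair <- quiet_pair()
  st <- pair$spect
  # severity 0 is the identity
  expect_identical(apply_defect(st, defect_spec(4, 0))$voxels, st$voxels)
  # severity 1 on segment 13 ablates its representative value
  d13 <- apply_defect(st, defect_spec(13, 1), center = c(24.5, 24.5))
  tb <- segment_table(d13, center = c(24.5, 24.5))
  expect_equal(tb$value[13], 0)
  # severity 0.4 on segment 4 from baseline 80 -> exactly 48 (through segment17)
  d4 <- apply_defect(st, defect_spec(4, 0.4), center = c(24.5, 24.5))
  tb4 <- segment_table(d4, center = c(24.5, 24.5))
  expect_equal(tb4$value[4], 48, tolerance = 1e-12)
  untouched <- setdiff(1:17, c(3, 4, 5))   # sector neighbors see the dilation
  expect_equal(tb4$value[untouched], rep(80, length(untouched)))
  expect_true(all(tb4$value[c(3, 5)] > 72))
})

test_that("attenuation field is a bounded inferior-dominant bump", {
  pair <- quiet_pair()
  spec <- attenuation_spec(min_factor = 0.8)
  att <- apply_attenuation(pair$spect, spec)
  expect_true(all(att$field >= 0.8 - 1e-12 & att$field <= 1 + 1e-12))
  # identity when disabled / min_factor = 1
  expect_identical(apply_attenuation(pair$spect, NULL)$stack$voxels,
                   pair$spect$voxels)
  id <- apply_attenuation(pair$spect, attenuation_spec(min_factor = 1))
  expect_equal(id$stack$voxels, pair$spect$voxels)
  # field minimum sits at the peak direction (270 = inferior, image bottom)
  sl <- att$field[, , 1]
  mins <- which(sl == min(sl), arr.ind = TRUE)
  expect_true(all(mins[, "row"] > 24.5))                # below center
  expect_true(all(abs(mins[, "col"] - 24.5) < 2))        # on the vertical axis
  # inferior segments reduced by the sector-mean of the raised cosine,
  # anterior untouched (analytic oracle: mean factor over [240, 300))
  tb0 <- segment_table(pair$spect, center = c(24.5, 24.5))
  tb1 <- segment_table(att$stack, center = c(24.5, 24.5))
  mean_bump <- 0.5 * (1 + 120 / (60 * pi))   # raised cosine averaged over the sector
  expect_equal(tb1$value[4] / tb0$value[4], 1 - 0.2 * mean_bump, tolerance = 0.01)
  expect_equal(tb1$value[c(1, 2, 6, 7, 8, 12)], tb0$value[c(1, 2, 6, 7, 8, 12)])
})

test_that("generate_patient_pair is deterministic and geometry-consistent", {
  a <- quiet_pair(noise_scale = 0.5, seed = 7)
  b <- quiet_pair(noise_scale = 0.5, seed = 7)
  expect_identical(a$spect$voxels, b$spect$voxels)
  expect_identical(a$pet$voxels, b$pet$voxels)
  # PET slice count = SPECT count * (2.4 / 1.6) for the same LV length
  expect_equal(dim(a$pet$voxels)[3], round(dim(a$spect$voxels)[3] * 2.4 / 1.6))
  expect_identical(dim(a$truth$attenuation_field), dim(a$spect$voxels))
})

test_that("noise-free phantoms conserve baseline on both modalities", {
  pair <- quiet_pair()
  for (st in list(pair$spect, pair$pet)) {
    expect_true(all(st$voxels %in% c(0, 80)))
    tb <- segment_table(st, center = c(24.5, 24.5))
    expect_equal(tb$value, rep(80, 17))
  }
})

test_that("truth tables reproduce baseline * (1 - severity) exactly", {
  defs <- list(defect_spec(c(4, 10), 0.35), defect_spec(15, 0.6))
  pair <- quiet_pair(defects = defs)
  expected <- rep(80, 17); expected[c(4, 10)] <- 80 * 0.65; expected[15] <- 80 * 0.4
  expect_equal(pair$truth$true_segment_values, expected)
  for (st in list(pair$spect, pair$pet)) {
    tb <- segment_table(st, center = c(24.5, 24.5))
    expect_equal(tb$value[c(4, 10, 15)], expected[c(4, 10, 15)], tolerance = 1e-12)
  }
  expect_true(any(pair$truth$defect_map))
})

test_that("stacks survive a PGM round trip", {
  pair <- quiet_pair(noise_scale = 0.5, seed = 3)
  dir <- withr::local_tempdir()
  write_stack_pgm(pair$spect, dir, "case01")
  back <- read_stack_pgm(dir, "case01", "stress", "spect")
  expect_equal(back$voxels, to_uint8(pair$spect)$voxels,
               ignore_attr = TRUE)
  expect_equal(back$pixel_mm, 2.4)
  expect_equal(back$scale_record$max, max(pair$spect$voxels))
  # inverse map through the scale record is exact on the 256 levels
  expect_equal(from_uint8(back)$voxels,
               from_uint8(to_uint8(pair$spect))$voxels)
})
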