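test_that("resampling conserves extent, constants, and mask binarity", {
  cfg <- preprocess_config()
  set.seed(2)
  vals <- array(rnorm(100 * 60 * 8), c(100, 60, 8))
  vol <- volume_sample(vals, c(1, 1, 3))
  m <- make_blob_mask(c(100, 60, 8), seed = 5, n_balls = 2,
                      r_range = c(6, 9))
  masks <- structure_mask_set(m, NULL, geometry_of(vol))
  out <- resample(vol, masks, cfg)
  expect_equal(dim(out$volume$values)[1], 200)  # 100 x 1 mm at 0.5 mm
  expect_equal(dim(out$volume$values)[2], 120)
  expect_equal(dim(out$volume$values)[3], 8)    # slice spacing unchanged
  expect_identical(out$volume$spacing, cfg$target_spacing_mm)
  expect_true(all(out$masks$gland %in% c(0, 1)))

  # mask physical volume conserved within 5% for a blob >= 10 voxels across
  v_in <- mask_volume_cm3(m, c(1, 1, 3))
  v_out <- mask_volume_cm3(out$masks$gland, cfg$target_spacing_mm)
  expect_lt(abs(v_out - v_in) / v_in, 0.05)

  # B-spline reproduces constants (partition of unity)
  const <- volume_sample(array(3.25, c(20, 20, 4)), c(1, 1, 3))
  rc <- resample(const, NULL, cfg)
  expect_lt(max(abs(rc$volume$values - 3.25)), 1e-9)
})

test_that("shape standardization crops/pads symmetrically and reversibly", {
  cfg <- preprocess_config(target_spacing_mm = c(0.5, 0.5, 3),
                           target_shape = c(256, 256, 23))
  vol <- volume_sample(array(seq_len(300 * 300 * 23) %% 17, c(300, 300, 23)),
                       c(0.5, 0.5, 3))
  st <- standardize_shape(vol, NULL, cfg)
  expect_identical(dim(st$volume$values), c(256L, 256L, 23L))
  expect_identical(st$offsets, c(22L, 22L, 0L))
  expect_identical(st$volume$values[1, 1, 1], vol$values[23, 23, 1])

  # identity case
  vol2 <- volume_sample(array(0, c(256, 256, 23)), c(0.5, 0.5, 3))
  st2 <- standardize_shape(vol2, NULL, cfg)
  expect_identical(st2$offsets, c(0L, 0L, 0L))

  # padding keeps mask voxel counts and round-trips
  small <- volume_sample(array(rnorm(40 * 40 * 5), c(40, 40, 5)), c(1, 1, 3))
  m <- make_blob_mask(c(40, 40, 5), seed = 6)
  cfg3 <- preprocess_config(target_spacing_mm = c(1, 1, 3),
                            target_shape = c(64, 64, 9),
                            crop3d_shape = c(32, 32, 9))
  st3 <- standardize_shape(small, structure_mask_set(m, NULL,
                                                     geometry_of(small)),
                           cfg3)
  expect_identical(sum(st3$masks$gland), sum(m))
  back <- unstandardize_mask(st3$masks$gland, st3$offsets, dim(m))
  expect_identical(back + 0L, m + 0L)
})

test_that("slice-wise normalization clips at 3 sd and rescales to [0, 1]", {
  set.seed(9)
  vals <- array(rnorm(32 * 32 * 4, 10, 2), c(32, 32, 4))
  vals[, , 2] <- 7.0  # constant slice
  vol <- normalize_intensity(volume_sample(vals, c(1, 1, 3)))
  for (s in c(1, 3, 4)) {
    sl <- vol$values[, , s]
    expect_identical(range(sl), c(0, 1))
  }
  expect_true(all(vol$values[, , 2] == 0))

  # hand computation: one outlier at +10 sd maps to exactly 1 and shares
  # its value with everything clipped above mean + 3 sd
  set.seed(10)
  x <- rnorm(32 * 32, 0, 1)
  x[1] <- 10
  sl <- array(x, c(32, 32, 1))
  m <- mean(x); s <- sd(x)
  clipped <- pmin(pmax(x, m - 3 * s), m + 3 * s)
  expected <- (clipped - min(clipped)) / (max(clipped) - min(clipped))
  out <- normalize_intensity(volume_sample(sl, c(1, 1, 3)))
  expect_equal(as.numeric(out$values), expected, tolerance = 1e-12)
  expect_identical(out$values[1, 1, 1], 1)

  # idempotence on well-spread slices: a uniform slice keeps mean +/- 3 sd
  # outside [0, 1], so re-normalization leaves it untouched
  set.seed(11)
  u <- normalize_intensity(volume_sample(array(runif(32 * 32 * 2), c(32, 32, 2)),
                                         c(1, 1, 3)))
  again <- normalize_intensity(u)
  expect_lt(max(abs(again$values - u$values)), 1e-6)
})

test_that("2D slice extraction and 3D cropping are exact and reversible", {
  ph <- generate_phantom(tiny_base_spec(seed = 14))
  cfg <- tiny_preprocess_cfg()
  pre <- preprocess_case(ph$volume, ph$masks, cfg)
  slices <- extract_2d_slices(pre$volume, pre$masks)
  expect_length(slices, 8L)
  restack <- array(unlist(lapply(slices, `[[`, "image")),
                   dim(pre$volume$values))
  expect_identical(restack, pre$volume$values)
  expect_identical(slices[[3]]$gland, pre$masks$gland[, , 3])

  cr <- crop_3d(pre$volume, pre$masks, cfg)
  expect_identical(cr$offsets, c(4L, 4L, 0L))
  expect_identical(dim(cr$volume$values), c(8L, 8L, 8L))
  # paste back into zeros then re-crop reproduces the crop
  canvas <- array(0, dim(pre$volume$values))
  canvas[4 + 1:8, 4 + 1:8, 1:8] <- cr$volume$values
  cr2 <- crop_3d(volume_sample(canvas, pre$volume$spacing), NULL, cfg)
  expect_identical(cr2$volume$values, cr$volume$values)
  # full-shape crop is the identity
  cfg_full <- preprocess_config(target_spacing_mm = c(4, 4, 6),
                                target_shape = c(16, 16, 8),
                                crop3d_shape = c(16, 16, 8))
  expect_identical(crop_3d(pre$volume, NULL, cfg_full)$volume$values,
                   pre$volume$values)
  big_crop <- preprocess_config(target_spacing_mm = c(4, 4, 6),
                                target_shape = c(16, 16, 8),
                                crop3d_shape = c(12, 12, 8))
  expect_error(crop_3d(cr$volume, NULL, big_crop), "larger than")

  # spec example: 256 -> 128 crop offsets
  big <- volume_sample(array(0, c(256, 256, 23)), c(0.5, 0.5, 3))
  expect_identical(crop_3d(big, NULL, preprocess_config())$offsets,
                   c(64L, 64L, 0L))
})

test_that("predicted masks restored to original geometry keep their volume", {
  spec <- phantom_spec(grid_shape = c(40, 40, 14), spacing_mm = c(1.6, 1.6, 3.6),
                       gland_volume_cm3 = 20, seed = 20)
  ph <- generate_phantom(spec)
  cfg <- preprocess_config(target_spacing_mm = c(2, 2, 3),
                           target_shape = c(32, 32, 17),
                           crop3d_shape = c(16, 16, 17))
  pre <- preprocess_case(ph$volume, ph$masks, cfg)
  back <- restore_mask(pre$masks$gland, pre, cfg)
  expect_identical(dim(back), dim(ph$masks$gland))
  v_std <- mask_volume_cm3(pre$masks$gland, cfg$target_spacing_mm)
  v_back <- mask_volume_cm3(back, spec$spacing_mm)
  expect_lt(abs(v_back - v_std) / v_std, 0.06)
  expect_gt(dice_score(ph$masks$gland, back), 0.85)
})
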