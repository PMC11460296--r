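square_record <- function() {
  list(structures = list(
    list(name = "prostate", contours = list(
      list(points = c(0, 0, 0, 10, 0, 0, 10, 10, 0, 0, 10, 0))))))
}

test_that("structure-set records parse with point order and units preserved", {
  cs <- read_rtstruct(square_record())
  expect_s3_class(cs, "contour_set")
  expect_named(cs, "prostate")
  expect_length(cs$prostate, 1L)
  expect_equal(dim(cs$prostate[[1]]), c(4L, 3L))
  expect_equal(cs$prostate[[1]][2, ], c(10, 0, 0))

  rec2 <- list(structures = list(
    list(name = "prostate", contours = list(list(points = c(0, 0, 0, 5, 0, 0, 5, 5, 0)))),
    list(name = "pz", contours = list(list(points = c(1, 1, 0, 3, 1, 0, 3, 3, 0))))))
  expect_named(read_rtstruct(rec2), c("prostate", "pz"))

  expect_warning(read_rtstruct(list(structures = list(
    list(name = "prostate", contours = list())))), "no contours")
  expect_error(read_rtstruct(list(structures = list(
    list(name = "x", contours = list(list(points = c(1, 2))))))),
    "divisible by 3")
  expect_error(read_rtstruct(list(foo = 1)), "structures")
  expect_error(read_rtstruct(tempfile()), "cannot read")
})

test_that("JSON round trip preserves contours", {
  cs <- read_rtstruct(square_record())
  f <- withr::local_tempfile(fileext = ".json")
  write_rtstruct(cs, f)
  cs2 <- read_rtstruct(f)
  expect_equal(cs2$prostate[[1]], cs$prostate[[1]])
})

random_orthonormal <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

test_that("patient/index maps are mutually inverse affine transforms", {
  geom <- list(spacing = c(0.5, 0.7, 3), origin = c(10, -4, 2),
               direction = cbind(c(1, 0, 0), c(0, 1, 0)), dim = c(8, 8, 4))
  expect_equal(as.numeric(patient_to_index(geom$origin, geom)), c(0, 0, 0))
  p <- geom$origin + 2 * geom$spacing[1] * geom$direction[, 1]
  expect_equal(as.numeric(patient_to_index(p, geom)), c(2, 0, 0))

  set.seed(4)
  for (rep in 1:4) {
    q <- random_orthonormal()
    geom <- list(spacing = runif(3, 0.3, 4), origin = rnorm(3, 0, 20),
                 direction = q[, 1:2], dim = c(16, 16, 8))
    pts <- matrix(rnorm(300, 0, 30), ncol = 3)
    idx <- patient_to_index(pts, geom)
    back <- index_to_patient(idx, geom)
    expect_lt(max(abs(back - pts)), 1e-9)
  }
  bad <- list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
              direction = cbind(c(1, 0, 0), c(1, 0, 0)), dim = c(4, 4, 4))
  expect_error(patient_to_index(c(0, 0, 0), bad), "singular")
})

test_that("rasterization matches the brute-force even-odd oracle", {
  geom <- list(spacing = c(1, 1, 3), origin = c(0, 0, 0),
               direction = cbind(c(1, 0, 0), c(0, 1, 0)), dim = c(20, 20, 3))
  # 10 x 10 mm axis-aligned square with corners on voxel-centre lines
  sq <- list(structures = list(list(name = "gland", contours = list(
    list(points = c(2, 2, 0, 12, 2, 0, 12, 12, 0, 2, 12, 0))))))
  m <- rasterize(read_rtstruct(sq), geom)
  oracle <- oracle_polygon_fill(c(2, 12, 12, 2), c(2, 2, 12, 12), 20, 20)
  expect_identical(m$gland[, , 1], oracle)
  expect_identical(sum(m$gland), 100L)  # half-open: 10 x 10 centres
  expect_identical(sum(m$gland[, , 2:3]), 0L)

  # collinear (zero-area) triangle: warning, empty mask
  tri <- list(structures = list(list(name = "gland", contours = list(
    list(points = c(1, 1, 0, 5, 5, 0, 9, 9, 0))))))
  expect_warning(m0 <- rasterize(read_rtstruct(tri), geom), "degenerate")
  expect_identical(sum(m0$gland), 0L)

  # two concentric squares on one slice combine to a ring by parity
  ring <- list(structures = list(list(name = "gland", contours = list(
    list(points = c(2, 2, 0, 14, 2, 0, 14, 14, 0, 2, 14, 0)),
    list(points = c(5, 5, 0, 11, 5, 0, 11, 11, 0, 5, 11, 0))))))
  mr <- rasterize(read_rtstruct(ring), geom)
  outer_o <- oracle_polygon_fill(c(2, 14, 14, 2), c(2, 2, 14, 14), 20, 20)
  inner_o <- oracle_polygon_fill(c(5, 11, 11, 5), c(5, 5, 11, 11), 20, 20)
  expect_identical(mr$gland[, , 1], (outer_o + inner_o) %% 2L)

  # orphan contour: plane farther than half slice spacing from any slice
  orphan <- list(structures = list(list(name = "gland", contours = list(
    list(points = c(2, 2, 10, 12, 2, 10, 12, 12, 10))))))
  expect_error(rasterize(read_rtstruct(orphan), geom), "orphan")
})

test_that("mask -> contour -> mask cycles are voxel-exact and idempotent", {
  geom <- list(spacing = c(1.3, 0.9, 2.5), origin = c(5, -3, 1),
               direction = cbind(c(1, 0, 0), c(0, 1, 0)), dim = c(12, 12, 3))
  for (s in 1:50) {
    m <- make_blob_mask(c(12, 12, 3), seed = 1000 + s)
    masks <- structure_mask_set(m, NULL, geom)
    cs <- masks_to_contours(masks)
    back <- rasterize(cs, geom)
    expect_identical(back$gland + 0L, m + 0L)
  }
  # second cycle is the identity
  m <- make_blob_mask(c(12, 12, 3), seed = 77)
  masks <- structure_mask_set(m, NULL, geom)
  once <- rasterize(masks_to_contours(masks), geom)
  twice <- rasterize(masks_to_contours(once), geom)
  expect_identical(twice$gland, once$gland)

  # empty mask -> empty contour set
  empty <- structure_mask_set(array(0L, c(12, 12, 3)), NULL, geom)
  expect_length(masks_to_contours(empty)$gland, 0L)

  # single voxel -> one 4-vertex polygon that re-rasterizes to itself
  one <- array(0L, c(12, 12, 3)); one[6, 7, 2] <- 1L
  cs1 <- masks_to_contours(structure_mask_set(one, NULL, geom))
  expect_length(cs1$gland, 1L)
  expect_identical(nrow(cs1$gland[[1]]), 4L)
  expect_identical(rasterize(cs1, geom)$gland + 0L, one + 0L)
})

test_that("rasterized disc area converges to the polygon area", {
  geom <- list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
               direction = cbind(c(1, 0, 0), c(0, 1, 0)), dim = c(64, 64, 1))
  r <- 12
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  pts <- cbind(31.5 + r * cos(th), 31.5 + r * sin(th), 0)
  rec <- list(structures = list(list(name = "gland",
    contours = list(list(points = as.numeric(t(pts)))))))
  m <- rasterize(read_rtstruct(rec), geom)
  expect_lt(abs(sum(m$gland) - pi * r^2) / (pi * r^2), 0.02)
})

test_that("NIfTI volumes round-trip values and anisotropic geometry", {
  set.seed(8)
  vals <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  vol <- volume_sample(vals, c(0.5, 0.5, 3), origin = c(3, -7, 11))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_lt(max(abs(back$values - vals)), 1e-6)
  expect_identical(back$spacing, c(0.5, 0.5, 3))
  expect_equal(back$origin, c(3, -7, 11), tolerance = 1e-5)
  expect_error(read_volume(file.path(tempdir(), "missing_file.nii")),
               "missing_file")

  # label mask round trip
  m <- make_blob_mask(c(16, 16, 5), seed = 3)
  pzm <- m * 0L; pzm[which(m == 1L)[1:4]] <- 1L
  masks <- structure_mask_set(m, pzm, geometry_of(vol))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_masks(masks, fm)
  back_m <- read_masks(fm)
  expect_identical(back_m$gland + 0L, m + 0L)
  expect_identical(back_m$pz + 0L, pzm + 0L)
})
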