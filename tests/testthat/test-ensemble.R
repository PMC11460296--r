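test_that("folds are balanced, disjoint, covering, and seeded", {
  ids <- sprintf("case%03d", 1:150)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f$valid, 30L)
    expect_length(f$train, 120L)
    expect_length(intersect(f$train, f$valid), 0L)
  }
  all_valid <- unlist(lapply(folds, `[[`, "valid"))
  expect_setequal(all_valid, ids)
  expect_identical(length(all_valid), 150L)
  folds2 <- make_folds(ids, k = 5, seed = 3)
  expect_identical(folds, folds2)
  expect_error(make_folds(1:3, k = 5), "exceed")
  # independent-split variant still splits 80/20
  fr <- make_folds(ids, k = 5, seed = 3, disjoint = FALSE)
  expect_length(fr[[1]]$valid, 30L)
})

test_that("augmentation applies one rigid transform to image and masks", {
  lam0 <- hyperparam_vector()        # all magnitudes zero
  img <- array(runif(16 * 16 * 2), c(16, 16, 2))
  msk <- (img > 0.6) * 1
  out <- augment_batch(img, list(ypg = msk), lam0)
  expect_identical(out$images, img)
  expect_identical(out$masks$ypg, msk)

  # flip-only: result is the image or its mirror, consistently with masks
  lamf <- hyperparam_vector(aug_hflip = TRUE)
  set.seed(2)
  of <- augment_batch(img, list(ypg = msk), lamf)
  for (s in 1:2) {
    flipped <- !isTRUE(all.equal(of$images[, , s], img[, , s]))
    ref_img <- if (flipped) img[, 16:1, s] else img[, , s]
    ref_msk <- if (flipped) msk[, 16:1, s] else msk[, , s]
    expect_equal(of$images[, , s], ref_img)
    expect_equal(of$masks$ypg[, , s], ref_msk)
  }
  # flipping a flipped batch restores the original
  expect_identical(img[, 16:1, ][, 16:1, ], img)

  # small rotation moves an off-centre blob but keeps heavy overlap
  lamr <- hyperparam_vector(aug_rotation_deg = 10)
  blob <- array(0, c(32, 32, 1)); blob[6:12, 20:26, 1] <- 1
  set.seed(40)
  orot <- augment_batch(blob, list(ypg = blob), lamr)
  d <- dice_score(blob, orot$masks$ypg)
  expect_lt(d, 1)
  expect_gt(d, 0.5)
  expect_true(all(orot$masks$ypg %in% c(0, 1)))
})

test_that("member training logs epochs and keeps the best checkpoint", {
  co <- generate_cohort(10, tiny_sampler(), seed = 19)
  cfg <- tiny_preprocess_cfg()
  cases <- lapply(co, function(case) {
    p <- preprocess_case(case$volume, case$masks, cfg)
    list(volume = p$volume, masks = p$masks)
  })
  fold <- list(train = cases[1:8], valid = cases[9:10])
  m <- train_member(tiny_lambda(), "2d", fold, tiny_schedule(30),
                    seed = 4, preprocess = cfg)
  lg <- m$loss_log
  expect_identical(nrow(lg), 30L)
  expect_lt(lg$train_loss[30], lg$train_loss[1])
  expect_lte(m$best_val_loss, lg$val_loss[30])
  expect_identical(m$best_val_loss, min(lg$val_loss))

  m1 <- train_member(tiny_lambda(), "3d", fold, tiny_schedule(1),
                     seed = 4, preprocess = cfg)
  expect_identical(nrow(m1$loss_log), 1L)
})

test_that("pair fusion averages inside the crop and defers to 2D outside", {
  p2 <- array(0.2, c(8, 8, 4))
  p3 <- array(0.6, c(4, 4, 4))
  off <- c(2L, 2L, 0L)
  fused <- fuse_pair(p2, p3, off)
  expect_equal(fused[3, 3, 1], 0.4)
  expect_equal(fused[1, 1, 1], 0.2)
  p2b <- p2; p2b[3:6, 3:6, ] <- 0.6
  expect_equal(fuse_pair(p2b, array(0.6, c(4, 4, 4)), off)[4, 4, 2], 0.6)
  expect_error(fuse_pair(p2, p3, c(6L, 6L, 2L)), "outside")
})

test_that("majority voting follows the strict-majority rule", {
  m1 <- array(1L, c(4, 4, 2)); m0 <- array(0L, c(4, 4, 2))
  expect_identical(majority_vote(list(m1, m1, m1, m1, m1)), m1 + 0L)
  v3 <- majority_vote(list(m1, m1, m1, m0, m0))
  expect_identical(v3, m1 + 0L)
  v2 <- majority_vote(list(m1, m1, m0, m0, m0))
  expect_identical(v2, m0 + 0L)
  expect_error(majority_vote(list(m1, m0)), "odd")
  set.seed(6)
  ms <- lapply(1:5, function(i) (array(runif(32), c(4, 4, 2)) > 0.5) * 1L)
  expect_identical(majority_vote(ms), majority_vote(rev(ms)))
  # vote-threshold equivalence: voting binarized maps equals thresholding
  # the member vote fraction at 0.5
  frac <- Reduce(`+`, ms) / 5
  expect_identical(majority_vote(ms), (frac > 0.5) * 1L)
})

test_that("a degenerate ensemble of identical pairs predicts like one pair", {
  co <- generate_cohort(10, tiny_sampler(), seed = 29)
  cfg <- tiny_preprocess_cfg()
  cases <- lapply(co, function(case) {
    p <- preprocess_case(case$volume, case$masks, cfg)
    list(volume = p$volume, masks = p$masks)
  })
  fold <- list(train = cases[1:8], valid = cases[9:10])
  m2 <- train_member(tiny_lambda(), "2d", fold, tiny_schedule(20),
                     seed = 8, preprocess = cfg)
  m3 <- train_member(tiny_lambda(), "3d", fold, tiny_schedule(20),
                     seed = 9, preprocess = cfg)
  ens <- structure(list(pairs = rep(list(list(m2d = m2, m3d = m3)), 5),
                        lambda_2d = tiny_lambda(), lambda_3d = tiny_lambda(),
                        preprocess = cfg, threshold = 0.5, k = 5,
                        vote = "binarize", loss = loss_config()),
                   class = "pz_ensemble")
  case <- generate_phantom(tiny_base_spec(seed = 99))
  pred <- predict(ens, case$volume)
  pred2 <- predict(ens, case$volume)
  expect_identical(pred$gland, pred2$gland)       # inference determinism
  # single-pair prediction equals the 5-fold degenerate vote
  pre <- preprocess_case(case$volume, NULL, cfg)
  p2 <- pzseg:::member_probs(m2, pre$volume, cfg)
  p3 <- pzseg:::member_probs(m3, pre$volume, cfg)
  fused <- fuse_pair(p2$pg, p3$pg, p3$offsets)
  single <- restore_mask((fused >= 0.5) * 1L, pre, cfg)
  expect_identical(pred$gland + 0L, single + 0L)
})
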