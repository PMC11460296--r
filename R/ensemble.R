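#' Training schedule
#'
#' Defaults follow the full-scale recipe: 3000 epochs for the 2D member,
#' 2000 for the 3D member, Adam with beta1 0.9, beta2 0.999, epsilon 1e-8,
#' learning rate 1e-5, and the checkpoint with the smallest validation loss
#' kept for testing. Scaled-down experiments pass smaller epoch counts and
#' a larger learning rate.
#'
#' @param epochs_2d,epochs_3d training epochs per member (>= 1)
#' @param learning_rate Adam learning rate (> 0)
#' @param beta1,beta2,adam_eps Adam moment constants
#' @param batch_size_2d,batch_size_3d minibatch sizes (samples)
#' @return a `train_schedule`
#' @export
train_schedule <- function(epochs_2d = 3000, epochs_3d = 2000,
                           learning_rate = 1e-5, beta1 = 0.9,
                           beta2 = 0.999, adam_eps = 1e-8,
                           batch_size_2d = 32L, batch_size_3d = 8L) {
  if (epochs_2d < 1 || epochs_3d < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(epochs_2d = as.integer(epochs_2d),
                 epochs_3d = as.integer(epochs_3d),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps,
                 batch_size_2d = as.integer(batch_size_2d),
                 batch_size_3d = as.integer(batch_size_3d)),
            class = "train_schedule")
}

#' Deterministic k-fold split
#'
#' Cases are shuffled once and the validation folds assigned round-robin,
#' so per fold 80%/20% of the cohort goes to training/validation (for
#' k = 5), validation sets across folds are pairwise disjoint and cover the
#' cohort, and fold sizes are balanced within 1. With
#' `disjoint = FALSE` each fold is instead an independent random 80/20
#' split.
#'
#' @param cohort_ids vector of case identifiers
#' @param k number of folds (default 5)
#' @param seed integer seed
#' @param disjoint cross-validation style disjoint validation sets
#'   (default) or independent random splits
#' @return a `fold_split`: list of k elements `list(train, valid)`
#' @export
make_folds <- function(cohort_ids, k = 5L, seed = 1L, disjoint = TRUE) {
  n <- length(cohort_ids)
  if (k > n) stop("k must not exceed the cohort size")
  with_seed(seed, {
    if (disjoint) {
      perm <- sample(cohort_ids)
      fold_of <- rep_len(seq_len(k), n)
      folds <- lapply(seq_len(k), function(f)
        list(train = perm[fold_of != f], valid = perm[fold_of == f]))
    } else {
      folds <- lapply(seq_len(k), function(f) {
        v <- sample(cohort_ids, max(1L, round(0.2 * n)))
        list(train = setdiff(cohort_ids, v), valid = v)
      })
    }
    structure(folds, class = "fold_split", seed = seed, k = k)
  })
}

#' Real-time batch augmentation
#'
#' Each sample independently receives a random in-plane rotation within
#' +/- `aug_rotation_deg`, row/column translations up to the shift
#' fractions, scaling within 1 +/- `aug_zoom`, and (if enabled) a
#' horizontal flip with probability 0.5. The identical spatial transform is
#' applied to the image (bilinear interpolation) and to the masks
#' (nearest-neighbour), so masks stay binary. 3D samples are transformed
#' slice-wise with one transform per sample. Draws come from the current R
#' RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param images array (rows, cols, n) or (rows, cols, slices, n)
#' @param masks named list of mask arrays shaped like `images` (entries may
#'   be `NULL`)
#' @param lambda a [hyperparam_vector()] carrying the magnitudes
#' @return list `(images, masks)`
#' @export
augment_batch <- function(images, masks, lambda) {
  dm <- dim(images)
  is3d <- length(dm) == 4L
  H <- dm[1]; W <- dm[2]
  n <- dm[length(dm)]
  rot <- lambda$aug_rotation_deg
  ws <- lambda$aug_width_shift; hs <- lambda$aug_height_shift
  zm <- lambda$aug_zoom; fl <- isTRUE(lambda$aug_hflip)
  if (rot == 0 && ws == 0 && hs == 0 && zm == 0 && !fl)
    return(list(images = images, masks = masks))
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  grid_r <- matrix(0:(H - 1), H, W)
  grid_c <- matrix(rep(0:(W - 1), each = H), H, W)
  out_img <- images
  out_masks <- masks
  for (s in seq_len(n)) {
    th <- stats::runif(1, -rot, rot) * pi / 180
    dr <- stats::runif(1, -hs, hs) * H
    dc <- stats::runif(1, -ws, ws) * W
    sc <- stats::runif(1, 1 - zm, 1 + zm)
    flip <- fl && stats::runif(1) < 0.5
    # inverse map: output pixel -> input coordinates
    r0 <- grid_r - cr - dr
    c0 <- grid_c - cc - dc
    src_r <- (cos(th) * r0 + sin(th) * c0) / sc + cr
    src_c <- (-sin(th) * r0 + cos(th) * c0) / sc + cc
    if (flip) src_c <- (W - 1) - src_c
    bil <- bilinear_weights(src_r, src_c, H, W)
    nn_idx <- nearest_index(src_r, src_c, H, W)
    if (is3d) {
      for (z in seq_len(dm[3])) {
        out_img[, , z, s] <- apply_bilinear(images[, , z, s], bil)
        for (nm in names(masks)) if (!is.null(masks[[nm]]))
          out_masks[[nm]][, , z, s] <-
            apply_nearest(masks[[nm]][, , z, s], nn_idx)
      }
    } else {
      out_img[, , s] <- apply_bilinear(images[, , s], bil)
      for (nm in names(masks)) if (!is.null(masks[[nm]]))
        out_masks[[nm]][, , s] <- apply_nearest(masks[[nm]][, , s], nn_idx)
    }
  }
  list(images = out_img, masks = out_masks)
}

bilinear_weights <- function(src_r, src_c, H, W) {
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  inside <- src_r >= 0 & src_r <= H - 1 & src_c >= 0 & src_c <= W - 1
  cl <- function(r, c) {
    r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
    r + H * c + 1L
  }
  list(i00 = cl(r0, c0), i10 = cl(r0 + 1, c0),
       i01 = cl(r0, c0 + 1), i11 = cl(r0 + 1, c0 + 1),
       w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
       w01 = (1 - fr) * fc, w11 = fr * fc, inside = inside)
}

apply_bilinear <- function(img, b) {
  v <- img[b$i00] * b$w00 + img[b$i10] * b$w10 +
    img[b$i01] * b$w01 + img[b$i11] * b$w11
  v[!b$inside] <- 0
  matrix(v, nrow(img), ncol(img))
}

nearest_index <- function(src_r, src_c, H, W) {
  r <- round(src_r); c <- round(src_c)
  inside <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
  r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
  list(idx = r + H * c + 1L, inside = inside)
}

apply_nearest <- function(img, nn) {
  v <- img[nn$idx]
  v[!nn$inside] <- 0
  matrix(v, nrow(img), ncol(img))
}

# stack standardized cases into network batches
assemble_2d <- function(cases) {
  imgs <- list(); pgs <- list(); pzs <- list(); has_pz <- TRUE
  for (case in cases) {
    v <- case$volume$values
    imgs[[length(imgs) + 1]] <- v
    pgs[[length(pgs) + 1]] <- case$masks$gland
    if (is.null(case$masks$pz)) has_pz <- FALSE
    else pzs[[length(pzs) + 1]] <- case$masks$pz
  }
  x <- array(unlist(imgs), c(dim(imgs[[1]])[1:2],
                             sum(vapply(imgs, function(v) dim(v)[3], 1))))
  ypg <- array(unlist(pgs), dim(x))
  ypz <- if (has_pz) array(unlist(pzs), dim(x)) else NULL
  list(x = x, ypg = ypg, ypz = ypz)
}

assemble_3d <- function(cases, cfg) {
  xs <- list(); pgs <- list(); pzs <- list(); has_pz <- TRUE
  for (case in cases) {
    cr <- crop_3d(case$volume, case$masks, cfg)
    xs[[length(xs) + 1]] <- cr$volume$values
    pgs[[length(pgs) + 1]] <- cr$masks$gland
    if (is.null(cr$masks$pz)) has_pz <- FALSE
    else pzs[[length(pzs) + 1]] <- cr$masks$pz
  }
  d <- dim(xs[[1]])
  x <- array(unlist(xs), c(d, length(xs)))
  ypg <- array(unlist(pgs), dim(x))
  ypz <- if (has_pz) array(unlist(pzs), dim(x)) else NULL
  list(x = x, ypg = ypg, ypz = ypz)
}

take_samples <- function(batch, idx, is3d) {
  if (is3d) list(x = batch$x[, , , idx, drop = FALSE],
                 ypg = batch$ypg[, , , idx, drop = FALSE],
                 ypz = if (is.null(batch$ypz)) NULL
                       else batch$ypz[, , , idx, drop = FALSE])
  else list(x = batch$x[, , idx, drop = FALSE],
            ypg = batch$ypg[, , idx, drop = FALSE],
            ypz = if (is.null(batch$ypz)) NULL
                  else batch$ypz[, , idx, drop = FALSE])
}

#' Train one ensemble member
#'
#' Fully trains a 2D or 3D network on one fold with the combined
#' soft-Dice loss, the configured Adam constants, and real-time
#' augmentation driven by the candidate's own magnitudes. The weights with
#' the smallest validation loss are kept, along with the per-epoch loss
#' log.
#'
#' @param lambda a [hyperparam_vector()]
#' @param mode `"2d"` or `"3d"`
#' @param fold `list(train =, valid =)` lists of standardized cases
#' @param schedule a [train_schedule()]
#' @param seed integer seed (weights, dropout, augmentation, shuffling)
#' @param loss a [loss_config()]
#' @param preprocess a [preprocess_config()] (for the 3D centre crop)
#' @param lateral_skips passed to [build_network()]
#' @return a `pz_member`: best weights, loss log, and rebuild metadata
#' @export
train_member <- function(lambda, mode, fold, schedule = train_schedule(),
                         seed = 1L, loss = loss_config(),
                         preprocess = preprocess_config(),
                         lateral_skips = TRUE) {
  if (length(fold$train) == 0) stop("empty training fold")
  is3d <- mode == "3d"
  train_b <- if (is3d) assemble_3d(fold$train, preprocess)
             else assemble_2d(fold$train)
  valid_b <- if (length(fold$valid) > 0) {
    if (is3d) assemble_3d(fold$valid, preprocess)
    else assemble_2d(fold$valid)
  } else train_b
  dm <- dim(train_b$x)
  input_shape <- if (is3d) dm[1:3] else dm[1:2]
  n_train <- dm[length(dm)]
  epochs <- if (is3d) schedule$epochs_3d else schedule$epochs_2d
  bs <- if (is3d) schedule$batch_size_3d else schedule$batch_size_2d
  net <- build_network(lambda, mode, input_shape, seed = seed,
                       lateral_skips = lateral_skips)
  has_aug <- lambda$aug_rotation_deg > 0 || lambda$aug_width_shift > 0 ||
    lambda$aug_height_shift > 0 || lambda$aug_zoom > 0 ||
    isTRUE(lambda$aug_hflip)
  eval_loss <- function(b) network_loss(net, b$x, b$ypg, b$ypz, loss)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(loss = Inf, weights = NULL, epoch = NA_integer_)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      eb <- if (has_aug)
        augment_batch(train_b$x, list(ypg = train_b$ypg, ypz = train_b$ypz),
                      lambda)
      else NULL
      ex <- if (is.null(eb)) train_b
            else list(x = eb$images, ypg = eb$masks$ypg, ypz = eb$masks$ypz)
      ord <- sample.int(n_train)
      tr_loss <- 0; nb <- 0
      for (i0 in seq(1, n_train, by = bs)) {
        idx <- ord[i0:min(i0 + bs - 1, n_train)]
        mb <- take_samples(ex, idx, is3d)
        l <- network_train_step(net, mb$x, mb$ypg, mb$ypz, loss,
                                lr = schedule$learning_rate,
                                beta1 = schedule$beta1,
                                beta2 = schedule$beta2,
                                adam_eps = schedule$adam_eps)
        tr_loss <- tr_loss + l; nb <- nb + 1
      }
      if (!is.finite(tr_loss))
        stop("non-finite training loss at epoch ", ep)
      vl <- eval_loss(valid_b)
      log <- rbind(log, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                   val_loss = vl))
      if (vl < best$loss)
        best <- list(loss = vl, weights = network_weights(net), epoch = ep)
    }
  })
  set_network_weights(net, best$weights)
  structure(list(lambda = lambda, mode = mode, input_shape = input_shape,
                 seed = seed, lateral_skips = lateral_skips,
                 weights = best$weights, best_epoch = best$epoch,
                 best_val_loss = best$loss, loss_log = log, net = net),
            class = "pz_member")
}

# rebuild the live network for a (possibly deserialized) member
member_network <- function(member) {
  if (!is.null(member$net) && .ptr_is_valid(member$net$ptr))
    return(member$net)
  net <- build_network(member$lambda, member$mode, member$input_shape,
                       seed = member$seed,
                       lateral_skips = member$lateral_skips)
  set_network_weights(net, member$weights)
  net
}

#' Fuse a 2D-3D member pair's probability maps
#'
#' Inside the 3D crop region the two probabilities are averaged; outside it
#' the 2D probability stands alone (an undefined 3D value must not bias the
#' average toward background). Applied per structure.
#'
#' @param prob_2d full-grid probability array (rows, cols, slices)
#' @param prob_3d crop-grid probability array
#' @param offsets 0-based crop corner indices (from [crop_3d()])
#' @return fused full-grid probability array
#' @export
fuse_pair <- function(prob_2d, prob_3d, offsets) {
  d2 <- dim(prob_2d); d3 <- dim(prob_3d)
  if (any(offsets < 0) || any(offsets + d3 > d2))
    stop("3D crop offsets fall outside the 2D grid")
  idx <- lapply(1:3, function(a) offsets[a] + seq_len(d3[a]))
  fused <- prob_2d
  fused[idx[[1]], idx[[2]], idx[[3]]] <-
    (prob_2d[idx[[1]], idx[[2]], idx[[3]]] + prob_3d) / 2
  fused
}

#' Majority vote over an odd number of binary masks
#'
#' A voxel is set iff more than half the members set it. Even member counts
#' are refused (ties undefined).
#'
#' @param binary_masks list of identically shaped binary arrays
#' @return binary array
#' @export
majority_vote <- function(binary_masks) {
  k <- length(binary_masks)
  if (k %% 2 == 0) stop("majority voting needs an odd number of members")
  d <- dim(binary_masks[[1]])
  for (m in binary_masks) if (!identical(dim(m), d))
    stop("mask shapes differ")
  votes <- Reduce(`+`, binary_masks)
  (votes > k / 2) * 1L
}

#' Train the full 2D-3D ensemble
#'
#' Preprocesses the cohort once, builds the k-fold split, trains a (2D, 3D)
#' member pair per fold, and packages the deployable predictor.
#'
#' @param cohort list of `list(volume, masks)` raw cases
#' @param lambda_2d,lambda_3d hyperparameter vectors for the two families
#' @param preprocess a [preprocess_config()]
#' @param schedule a [train_schedule()]
#' @param k folds (default 5; must be odd for voting)
#' @param seed integer seed
#' @param loss a [loss_config()]
#' @param vote `"binarize"` (threshold each pair, then vote; default) or
#'   `"average"` (average pair probabilities across folds, then threshold)
#' @return a `pz_ensemble`
#' @export
train_ensemble <- function(cohort, lambda_2d, lambda_3d,
                           preprocess = preprocess_config(),
                           schedule = train_schedule(), k = 5L, seed = 1L,
                           loss = loss_config(), vote = c("binarize", "average")) {
  vote <- match.arg(vote)
  pre <- lapply(cohort, function(case)
    preprocess_case(case$volume, case$masks, preprocess))
  std_cases <- lapply(pre, function(p) list(volume = p$volume,
                                            masks = p$masks))
  folds <- make_folds(seq_along(cohort), k = k, seed = seed)
  pairs <- lapply(seq_len(k), function(f) {
    fold <- list(train = std_cases[folds[[f]]$train],
                 valid = std_cases[folds[[f]]$valid])
    m2 <- train_member(lambda_2d, "2d", fold, schedule,
                       seed = seed + 100L * f, loss = loss,
                       preprocess = preprocess)
    m3 <- train_member(lambda_3d, "3d", fold, schedule,
                       seed = seed + 100L * f + 50L, loss = loss,
                       preprocess = preprocess)
    list(m2d = m2, m3d = m3)
  })
  structure(list(pairs = pairs, lambda_2d = lambda_2d,
                 lambda_3d = lambda_3d, preprocess = preprocess,
                 threshold = 0.5, k = k, folds = folds, vote = vote,
                 loss = loss),
            class = "pz_ensemble")
}

member_probs <- function(member, std_volume, preprocess) {
  net <- member_network(member)
  if (member$mode == "2d") {
    out <- network_forward(net, std_volume$values)
    list(pg = out$pg, pz = out$pz, offsets = c(0L, 0L, 0L))
  } else {
    cr <- crop_3d(std_volume, NULL, preprocess)
    out <- network_forward(net, cr$volume$values)
    dm <- dim(cr$volume$values)
    list(pg = array(out$pg, dm), pz = array(out$pz, dm),
         offsets = cr$offsets)
  }
}

#' Segment a raw volume with a trained ensemble
#'
#' Runs the full pipeline: preprocessing, slice-wise 2D inference and
#' centre-crop 3D inference per member pair, probability fusion within each
#' pair, thresholding at 0.5, majority voting across the pairs, and mapping
#' of the voted masks back to the input volume's original grid.
#'
#' @param object a `pz_ensemble`
#' @param volume a raw [volume_sample()]
#' @param return_probs also return the fused per-pair probability maps (on
#'   the standardized grid)
#' @param ... unused
#' @return a [structure_mask_set()] on the original grid; with
#'   `return_probs = TRUE`, `list(masks, probs)`
#' @export
predict.pz_ensemble <- function(object, volume, return_probs = FALSE, ...) {
  pre <- preprocess_case(volume, NULL, object$preprocess)
  fused <- lapply(object$pairs, function(pair) {
    p2 <- member_probs(pair$m2d, pre$volume, object$preprocess)
    p3 <- member_probs(pair$m3d, pre$volume, object$preprocess)
    list(pg = fuse_pair(p2$pg, p3$pg, p3$offsets),
         pz = fuse_pair(p2$pz, p3$pz, p3$offsets))
  })
  vote_mask <- function(structure_name) {
    if (object$vote == "binarize") {
      majority_vote(lapply(fused, function(f)
        (f[[structure_name]] >= object$threshold) * 1L))
    } else {
      mean_p <- Reduce(`+`, lapply(fused, `[[`, structure_name)) /
        length(fused)
      (mean_p >= object$threshold) * 1L
    }
  }
  pg_std <- vote_mask("pg")
  pz_std <- vote_mask("pz")
  pg <- restore_mask(pg_std, pre, object$preprocess)
  pz <- restore_mask(pz_std, pre, object$preprocess)
  geom <- list(spacing = pre$original$spacing, origin = pre$original$origin,
               direction = pre$original$direction, dim = pre$original$dim)
  masks <- structure_mask_set(pg, pz, geom)
  if (return_probs) list(masks = masks, probs = fused) else masks
}

#' Evaluate an ensemble on a cohort
#'
#' One evaluation record per (case, structure): Dice score, Hausdorff
#' distance in mm (NA when either mask is empty), and reference/predicted
#' volumes in cm^3.
#'
#' @param ensemble a `pz_ensemble`
#' @param cohort list of `list(volume, masks)` cases
#' @return data.frame of evaluation records
#' @export
evaluate_cohort <- function(ensemble, cohort) {
  rows <- list()
  for (i in seq_along(cohort)) {
    case <- cohort[[i]]
    pred <- predict(ensemble, case$volume)
    sp <- case$volume$spacing
    for (s in c("gland", "pz")) {
      ref <- case$masks[[s]]
      if (is.null(ref)) next
      est <- pred[[s]]
      hd <- if (sum(ref) > 0 && sum(est) > 0)
        hausdorff_mm(ref, est, sp) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        case_id = i, structure = s,
        dice = dice_score(ref, est),
        hausdorff_mm = hd,
        reference_volume_cm3 = mask_volume_cm3(ref, sp),
        predicted_volume_cm3 = mask_volume_cm3(est, sp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
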