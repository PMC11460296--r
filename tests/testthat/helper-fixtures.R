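# Shared fixtures and independent oracles. All fixtures are generated in
# code; the oracles deliberately use the most direct (brute-force) route so
# they stay independent of the implementation under test.

# -- tiny study configuration (scaled-down grids) -----------------------------

tiny_base_spec <- function(...) {
  args <- list(grid_shape = c(16, 16, 8), spacing_mm = c(4, 4, 6),
               gland_volume_cm3 = 28, pz_fraction = 0.25,
               deformation_amplitude = 0.05, noise_sd = 0.04)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

tiny_sampler <- function(base = tiny_base_spec()) {
  cohort_spec_sampler(base, mean_volume = 28, sd_volume = 5,
                      pz_fraction_range = c(0.2, 0.3), min_volume = 15)
}

tiny_preprocess_cfg <- function() {
  preprocess_config(target_spacing_mm = c(4, 4, 6),
                    target_shape = c(16, 16, 8),
                    crop3d_shape = c(8, 8, 8))
}

tiny_lambda <- function() {
  hyperparam_vector(n_blocks = 1, base_filters = 4, dropout_p = 0)
}

tiny_schedule <- function(epochs = 50) {
  train_schedule(epochs_2d = epochs, epochs_3d = epochs,
                 learning_rate = 2e-3, batch_size_2d = 64L,
                 batch_size_3d = 8L)
}

# -- random mask fixtures -----------------------------------------------------

# a random smooth blob mask: union of a few random balls
make_blob_mask <- function(dims, seed, n_balls = 3, r_range = c(1.5, 3.5)) {
  set.seed(seed)
  d <- dims
  g <- array(0L, d)
  cx <- array(seq_len(d[1]), d)
  cy <- array(rep(seq_len(d[2]), each = d[1]), d)
  cz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  for (b in seq_len(n_balls)) {
    ctr <- c(runif(1, 3, d[1] - 2), runif(1, 3, d[2] - 2),
             runif(1, 2, d[3] - 1))
    r <- runif(1, r_range[1], r_range[2])
    g[(cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2 <= r^2] <- 1L
  }
  g
}

# -- oracles ------------------------------------------------------------------

# voxel-counting Dice oracle
oracle_dice <- function(y, yh) {
  ny <- sum(y == 1); nyh <- sum(yh == 1)
  if (ny + nyh == 0) return(1)
  2 * sum(y == 1 & yh == 1) / (ny + nyh)
}

# exhaustive max-min Hausdorff oracle: full pairwise distance matrix over
# the boundary point sets (boundary = mask voxel with a face neighbour
# outside, recomputed here by direct neighbour checks)
oracle_boundary <- function(mask) {
  d <- dim(mask)
  pts <- which(mask == 1, arr.ind = TRUE)
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      q <- p; q[ax] <- q[ax] + dd
      if (any(q < 1) || any(q > d) || mask[q[1], q[2], q[3]] == 0) {
        keep[i] <- TRUE
      }
    }
  }
  pts[keep, , drop = FALSE]
}

oracle_hausdorff <- function(y, yh, spacing) {
  a <- sweep(oracle_boundary(y), 2, spacing, "*")
  b <- sweep(oracle_boundary(yh), 2, spacing, "*")
  dmat <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2 +
           (a[i, 3] - b[j, 3])^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# brute-force even-odd point-in-polygon (per the documented half-open
# centre-inclusion rule), evaluated centre by centre
oracle_polygon_fill <- function(u, v, nrow_g, ncol_g) {
  n <- length(u)
  out <- matrix(0L, nrow_g, ncol_g)
  for (r in 0:(nrow_g - 1)) for (cc in 0:(ncol_g - 1)) {
    parity <- 0L
    for (e in seq_len(n)) {
      u1 <- u[e]; v1 <- v[e]
      u2 <- u[e %% n + 1]; v2 <- v[e %% n + 1]
      if (u1 == u2) next
      if ((u1 > r) != (u2 > r)) {
        vint <- v1 + (r - u1) * (v2 - v1) / (u2 - u1)
        if (cc < vint) parity <- parity + 1L
      }
    }
    out[r + 1, cc + 1] <- parity %% 2L
  }
  out
}

# closed-form parameter recount from the structural rule (independent of
# architecture_spec): residual block = 3 convs + 3 BN (+ projection when the
# channel count changes); filters double per level and mirror on the way up;
# the PZ decoder's features join the gland head input.
oracle_param_count <- function(lambda, mode, lateral_skips = TRUE) {
  kdim <- if (mode == "3d") 3 else 2
  nb <- lambda$n_blocks; base <- lambda$base_filters
  ks <- c(lambda$kernel_1, lambda$kernel_2, lambda$kernel_3)
  conv <- function(ci, co, k) ci * k^kdim * co + co
  block <- function(ci, co) {
    p <- conv(ci, co, ks[1]) + conv(co, co, ks[2]) + conv(co, co, ks[3]) +
      3 * 2 * co
    if (ci != co) p <- p + conv(ci, co, 1)
    p
  }
  total <- 0
  ci <- 1
  for (i in seq_len(nb)) {
    total <- total + block(ci, base * 2^(i - 1))
    ci <- base * 2^(i - 1)
  }
  total <- total + block(ci, base * 2^nb)
  for (path in 1:2) {
    cp <- base * 2^nb
    for (i in seq_len(nb)) {
      f <- base * 2^(nb - i)
      total <- total + block(cp + if (lateral_skips) f else 0, f)
      cp <- f
    }
  }
  total + conv(base, 1, 1) + conv(2 * base, 1, 1)
}
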