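#' Loss configuration
#'
#' @param alpha nonnegative weight of the peripheral-zone term in the
#'   combined two-structure training loss (default 0.1)
#' @param smooth_eps small nonnegative stabilizer added to the soft Dice
#'   denominator
#' @return a `loss_config` list
#' @export
loss_config <- function(alpha = 0.1, smooth_eps = 1e-6) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (smooth_eps < 0) stop("smooth_eps must be >= 0")
  structure(list(alpha = alpha, smooth_eps = smooth_eps),
            class = "loss_config")
}

#' Soft Dice loss (squared-denominator form)
#'
#' `1 - 2 * sum(p*y) / (sum(p^2) + sum(y^2) + eps)`, differentiable in the
#' predicted probabilities. Note the squared denominator: for binary
#' predictions and `eps = 0` it equals `1 - dice_score`, but on
#' probabilities the two deliberately differ.
#'
#' @param pred_prob probability grid in [0, 1]
#' @param truth binary grid of the same shape
#' @param smooth_eps denominator stabilizer
#' @return scalar loss
#' @export
dice_loss <- function(pred_prob, truth, smooth_eps = 0) {
  if (!identical(dim2(pred_prob), dim2(truth)))
    stop("shape mismatch between prediction and truth")
  num <- 2 * sum(pred_prob * truth)
  den <- sum(pred_prob^2) + sum(truth^2) + smooth_eps
  if (den == 0) return(0)
  1 - num / den
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Combined two-structure training loss
#'
#' Gland Dice loss plus `alpha` times the PZ Dice loss. When the PZ
#' reference is absent (`y_pz = NULL`) the PZ term is skipped with a
#' message.
#'
#' @param pred_pg,pred_pz predicted probability grids
#' @param y_pg,y_pz binary reference grids (`y_pz` may be `NULL`)
#' @param cfg a [loss_config()]
#' @return scalar loss
#' @export
combined_loss <- function(pred_pg, pred_pz, y_pg, y_pz,
                          cfg = loss_config()) {
  loss <- dice_loss(pred_pg, y_pg, cfg$smooth_eps)
  if (is.null(y_pz)) {
    message("no PZ reference; PZ loss term skipped")
    return(loss)
  }
  loss + cfg$alpha * dice_loss(pred_pz, y_pz, cfg$smooth_eps)
}

#' Dice similarity score of two binary masks
#'
#' `2|y ∩ y_hat| / (|y| + |y_hat|)` on voxel cardinalities; two empty masks
#' score 1 by convention.
#'
#' @param y,y_hat binary grids of identical shape
#' @return scalar in [0, 1]
#' @export
dice_score <- function(y, y_hat) {
  if (!identical(dim2(y), dim2(y_hat)))
    stop("shape mismatch between masks")
  a <- sum(y == 1)
  b <- sum(y_hat == 1)
  if (a + b == 0) return(1)
  2 * sum(y == 1 & y_hat == 1) / (a + b)
}

#' Boundary voxels of a binary mask
#'
#' Mask voxels with at least one face-neighbour outside the mask (voxels on
#' the array border count as boundary).
#'
#' @param mask binary 3D array
#' @return integer matrix of 1-based (row, col, slice) boundary coordinates
#' @export
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- array(mask == 1, d)
  interior <- array(TRUE, d)
  pad_shift <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    interior <- interior & pad_shift(m, axis, by)
  which(m & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between two masks, in millimetres
#'
#' Symmetric Hausdorff distance `max(h(y, y_hat), h(y_hat, y))` between the
#' boundary-voxel centre point sets, with `h` the directed maximum of
#' minimum Euclidean distances measured in physical mm. The full maximum is
#' used (not a percentile variant). Either mask empty is an error: the
#' distance is undefined and should be recorded as missing, not 0.
#'
#' @param y,y_hat binary 3D arrays of identical shape
#' @param spacing voxel spacing in mm
#' @return distance in mm
#' @export
hausdorff_mm <- function(y, y_hat, spacing) {
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch between masks")
  if (sum(y == 1) == 0 || sum(y_hat == 1) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  a <- sweep(boundary_voxels(y), 2, spacing, "*")
  b <- sweep(boundary_voxels(y_hat), 2, spacing, "*")
  max(directed_hd(a, b), directed_hd(b, a))
}

# max over rows of A of the min distance to rows of B, chunked so the
# pairwise matrix stays small
directed_hd <- function(A, B) {
  worst <- 0
  step <- max(1L, floor(2e6 / nrow(B)))
  for (i0 in seq(1, nrow(A), by = step)) {
    ii <- i0:min(i0 + step - 1, nrow(A))
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rep(1, nrow(B))) +
      outer(rep(1, length(ii)), rowSums(B^2)) -
      2 * A[ii, , drop = FALSE] %*% t(B)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Pooled voxel-intensity histogram of a cohort
#'
#' @param cohort list of `list(volume, ...)` entries (or bare
#'   [volume_sample()]s); intensities are expected in [0, 1] and are
#'   clamped to that range before binning
#' @param n_bins number of uniform bins on [0, 1]
#' @return numeric vector of bin masses summing to 1, with bin centres as
#'   attribute `"centers"`
#' @export
cohort_histogram <- function(cohort, n_bins = 100) {
  if (length(cohort) == 0) stop("cohort must be nonempty")
  counts <- numeric(n_bins)
  for (case in cohort) {
    vol <- if (inherits(case, "volume_sample")) case else case$volume
    v <- pmin(pmax(as.numeric(vol$values), 0), 1)
    bin <- pmin(floor(v * n_bins) + 1L, n_bins)
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  p <- counts / sum(counts)
  attr(p, "centers") <- (seq_len(n_bins) - 0.5) / n_bins
  p
}

#' Discrepancy between two discrete distributions
#'
#' Three cohort discrepancy metrics on histograms sharing one support:
#' Kullback-Leibler divergence (with epsilon-smoothing of `q`), 1D
#' Wasserstein distance (integral of the CDF difference over the bin grid,
#' reported on the intensity scale), and the Jensen-Shannon distance
#' (square root of the JS divergence with base-2 logs, bounded in [0, 1]).
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1
#'   (tolerance 1e-8)
#' @param metric `"kl"`, `"wasserstein"` or `"js"`
#' @param eps smoothing mass for KL
#' @return scalar discrepancy
#' @export
discrepancy <- function(p, q, metric = c("kl", "wasserstein", "js"),
                        eps = 1e-12) {
  metric <- match.arg(metric)
  if (length(p) != length(q)) stop("p and q must share one support")
  if (any(p < 0) || any(q < 0)) stop("negative masses")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must each sum to 1")
  centers <- attr(p, "centers")
  if (is.null(centers)) centers <- attr(q, "centers")
  switch(metric,
    kl = {
      qs <- (q + eps) / sum(q + eps)
      idx <- p > 0
      sum(p[idx] * log(p[idx] / qs[idx]))
    },
    wasserstein = {
      width <- if (is.null(centers) || length(centers) < 2) 1
               else centers[2] - centers[1]
      sum(abs(cumsum(p) - cumsum(q))) * width
    },
    js = {
      m <- (p + q) / 2
      kl2 <- function(a, b) {
        idx <- a > 0
        sum(a[idx] * log2(a[idx] / b[idx]))
      }
      sqrt(pmax((kl2(p, m) + kl2(q, m)) / 2, 0))
    })
}
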