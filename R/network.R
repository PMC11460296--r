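#' Hyperparameter vector of the network family
#'
#' The 12-component vector searched by Bayesian optimization: 7 architecture
#' components (number of residual blocks per path, base filter count,
#' activation, the 3 kernel sizes shared by every residual block, spatial
#' dropout probability) followed by 5 real-time augmentation magnitudes
#' (rotation, width shift, height shift, zoom, horizontal flip).
#'
#' @param n_blocks residual blocks in the down path and in each up path
#' @param base_filters filters of the first residual block; doubled at each
#'   deeper level and mirrored on the way up
#' @param activation `"relu"`, `"elu"` or `"leaky_relu"`
#' @param kernel_1,kernel_2,kernel_3 odd kernel sizes of the three
#'   convolutional layers inside every residual block
#' @param dropout_p spatial dropout probability in [0, 0.5]
#' @param aug_rotation_deg rotation magnitude (degrees, >= 0)
#' @param aug_width_shift,aug_height_shift shift fractions in [0, 0.5]
#' @param aug_zoom zoom magnitude in [0, 0.5]
#' @param aug_hflip logical, enable horizontal flips
#' @return a `hyperparam_vector`
#' @export
hyperparam_vector <- function(n_blocks = 2, base_filters = 8,
                              activation = "relu",
                              kernel_1 = 3, kernel_2 = 3, kernel_3 = 3,
                              dropout_p = 0.1,
                              aug_rotation_deg = 0, aug_width_shift = 0,
                              aug_height_shift = 0, aug_zoom = 0,
                              aug_hflip = FALSE) {
  hp <- list(n_blocks = as.integer(n_blocks),
             base_filters = as.integer(base_filters),
             activation = activation,
             kernel_1 = as.integer(kernel_1),
             kernel_2 = as.integer(kernel_2),
             kernel_3 = as.integer(kernel_3),
             dropout_p = dropout_p,
             aug_rotation_deg = aug_rotation_deg,
             aug_width_shift = aug_width_shift,
             aug_height_shift = aug_height_shift,
             aug_zoom = aug_zoom,
             aug_hflip = isTRUE(aug_hflip))
  class(hp) <- "hyperparam_vector"
  validate_hyperparams(hp)
  hp
}

validate_hyperparams <- function(hp) {
  if (length(hp) != 12L) stop("a hyperparameter vector has 12 components")
  if (hp$n_blocks < 1) stop("n_blocks must be >= 1")
  if (hp$base_filters < 1) stop("base_filters must be >= 1")
  if (!hp$activation %in% c("relu", "elu", "leaky_relu"))
    stop("unknown activation '", hp$activation, "'")
  for (k in c(hp$kernel_1, hp$kernel_2, hp$kernel_3))
    if (k < 1 || k %% 2 == 0) stop("kernel sizes must be odd and >= 1")
  if (hp$dropout_p < 0 || hp$dropout_p > 0.5)
    stop("dropout_p must lie in [0, 0.5]")
  if (hp$aug_rotation_deg < 0) stop("aug_rotation_deg must be >= 0")
  for (v in c(hp$aug_width_shift, hp$aug_height_shift))
    if (v < 0 || v > 0.5) stop("shift fractions must lie in [0, 0.5]")
  if (hp$aug_zoom < 0 || hp$aug_zoom > 0.5) stop("aug_zoom must lie in [0, 0.5]")
  invisible(hp)
}

#' Build a concrete dual-decoder network from a hyperparameter vector
#'
#' Constructs the U-shaped network: a down-sampling path of `n_blocks`
#' residual blocks (each followed by in-plane 2x2 max-pooling), one middle
#' residual block, and two up-sampling decoder paths (PZ and gland), each
#' with `n_blocks` [spatial dropout -> nearest upsample -> lateral skip
#' concatenation -> residual block] stages. A spatial dropout layer precedes
#' every residual block except the first. The PZ decoder's final features
#' are concatenated into the gland head's input; both heads are 1-kernel
#' convolutions with sigmoid outputs. Pooling and upsampling act in-plane
#' only, so the slice count is preserved at every scale in 3D mode.
#'
#' @param lambda a [hyperparam_vector()]
#' @param mode `"2d"` or `"3d"`
#' @param input_shape spatial input shape: length 2 (rows, cols) for 2D,
#'   length 3 (rows, cols, slices) for 3D; rows and cols must be divisible
#'   by `2^n_blocks`
#' @param seed integer seed for He-uniform weight initialization and
#'   dropout draws
#' @param lateral_skips include U-Net style encoder-to-decoder
#'   concatenation skips (default TRUE)
#' @return a `pz_network` with elements `arch` (the emitted architecture
#'   table) and `parameter_count`
#' @export
build_network <- function(lambda, mode = c("2d", "3d"), input_shape,
                          seed = 1L, lateral_skips = TRUE) {
  validate_hyperparams(lambda)
  mode <- match.arg(mode)
  is3d <- mode == "3d"
  if (is3d) {
    if (length(input_shape) != 3L) stop("3D mode needs a length-3 input_shape")
    d <- input_shape[3]
  } else {
    if (length(input_shape) < 2L) stop("2D mode needs a length-2 input_shape")
    d <- 1L
  }
  div <- 2^lambda$n_blocks
  if (input_shape[1] %% div != 0 || input_shape[2] %% div != 0)
    stop("in-plane input shape must be divisible by 2^n_blocks = ", div)
  ptr <- .nn_create(lambda$n_blocks, lambda$base_filters, lambda$activation,
                    lambda$kernel_1, lambda$kernel_2, lambda$kernel_3,
                    lambda$dropout_p, is3d, lateral_skips,
                    as.integer(d), as.integer(input_shape[1]),
                    as.integer(input_shape[2]), as.integer(seed))
  arch <- architecture_spec(lambda, mode, input_shape, lateral_skips)
  net <- structure(list(ptr = ptr, lambda = lambda, mode = mode,
                        input_shape = as.integer(input_shape),
                        lateral_skips = lateral_skips, seed = as.integer(seed),
                        arch = arch,
                        parameter_count = .nn_n_params(ptr)),
                   class = "pz_network")
  stopifnot(net$parameter_count == sum(arch$params))
  net
}

#' Emitted architecture description
#'
#' Enumerates the network's layers with channel counts, kernels and
#' closed-form trainable parameter counts (convolution weights + biases and
#' batch-norm scale/shift; running statistics are not trainable).
#'
#' @inheritParams build_network
#' @return data.frame with columns `layer`, `type`, `path`, `cin`, `cout`,
#'   `kernel`, `params`
#' @export
architecture_spec <- function(lambda, mode = c("2d", "3d"), input_shape,
                              lateral_skips = TRUE) {
  mode <- match.arg(mode)
  kdim <- if (mode == "3d") 3 else 2
  nb <- lambda$n_blocks
  base <- lambda$base_filters
  ks <- c(lambda$kernel_1, lambda$kernel_2, lambda$kernel_3)
  rows <- list()
  add <- function(layer, type, path, cin, cout, kernel, params)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, type = type, path = path, cin = cin, cout = cout,
      kernel = kernel, params = params, stringsAsFactors = FALSE)
  conv_p <- function(cin, cout, k) cin * k^kdim * cout + cout
  block <- function(name, path, cin, cout) {
    for (j in 1:3) {
      kj <- if (j == 1) ks[1] else if (j == 2) ks[2] else ks[3]
      ci <- if (j == 1) cin else cout
      add(paste0(name, "_conv", j), "conv", path, ci, cout, kj,
          conv_p(ci, cout, kj))
      add(paste0(name, "_bn", j), "batch_norm", path, cout, cout, NA,
          2 * cout)
      add(paste0(name, "_act", j), "activation", path, cout, cout, NA, 0)
    }
    if (cin != cout)
      add(paste0(name, "_proj"), "conv", path, cin, cout, 1,
          conv_p(cin, cout, 1))
  }
  cin <- 1
  for (i in seq_len(nb)) {
    f <- base * 2^(i - 1)
    if (i > 1) add(paste0("down", i, "_dropout"), "spatial_dropout", "down",
                   cin, cin, NA, 0)
    block(paste0("down", i), "down", cin, f)
    add(paste0("down", i, "_pool"), "max_pool", "down", f, f, 2, 0)
    cin <- f
  }
  add("middle_dropout", "spatial_dropout", "middle", cin, cin, NA, 0)
  block("middle", "middle", cin, base * 2^nb)
  for (path in c("up_pz", "up_pg")) {
    c_prev <- base * 2^nb
    for (i in seq_len(nb)) {
      f <- base * 2^(nb - i)
      add(paste0(path, i, "_dropout"), "spatial_dropout", path, c_prev,
          c_prev, NA, 0)
      add(paste0(path, i, "_upsample"), "upsample", path, c_prev, c_prev,
          2, 0)
      ci <- c_prev + if (lateral_skips) f else 0
      block(paste0(path, i), path, ci, f)
      c_prev <- f
    }
  }
  add("head_pz", "conv", "up_pz", base, 1, 1, conv_p(base, 1, 1))
  add("head_pg", "conv", "up_pg", 2 * base, 1, 1, conv_p(2 * base, 1, 1))
  do.call(rbind, rows)
}

# batches to the engine's flat layout (cols fastest, then rows, slices,
# samples) and back
flatten_batch <- function(x, mode) {
  if (is.null(dim(x))) stop("batch must be an array")
  if (mode == "2d") {
    single <- length(dim(x)) == 2L
    if (single) dim(x) <- c(dim(x), 1L)
    n <- dim(x)[3]
    list(x = as.numeric(aperm(x, c(2, 1, 3))), n = n, single = single)
  } else {
    single <- length(dim(x)) == 3L
    if (single) dim(x) <- c(dim(x), 1L)
    n <- dim(x)[4]
    list(x = as.numeric(aperm(x, c(2, 1, 3, 4))), n = n, single = single)
  }
}

unflatten_batch <- function(v, model, n, single = FALSE) {
  h <- model$input_shape[1]; w <- model$input_shape[2]
  out <- if (model$mode == "2d") {
    aperm(array(v, c(w, h, n)), c(2, 1, 3))
  } else {
    d <- model$input_shape[3]
    aperm(array(v, c(w, h, d, n)), c(2, 1, 3, 4))
  }
  if (single) {
    dm <- dim(out)
    dim(out) <- dm[-length(dm)]
  }
  out
}

#' Forward pass through a built network
#'
#' Deterministic in evaluation mode (dropout off, batch-norm running
#' statistics).
#'
#' @param model a `pz_network`
#' @param batch 2D mode: array (rows, cols) or (rows, cols, n); 3D mode:
#'   array (rows, cols, slices) or (rows, cols, slices, n)
#' @param train logical; `TRUE` uses batch statistics and active dropout
#' @return list with probability arrays `pg` and `pz`, same spatial shape
#'   as the input
#' @export
network_forward <- function(model, batch, train = FALSE) {
  fb <- flatten_batch(batch, model$mode)
  out <- .nn_forward(model$ptr, fb$x, fb$n, train)
  list(pg = unflatten_batch(out$pg, model, fb$n, fb$single),
       pz = unflatten_batch(out$pz, model, fb$n, fb$single))
}

#' One optimization step on a batch
#'
#' Forward pass in training mode, exact backpropagation of the combined
#' soft-Dice loss, and one Adam update.
#'
#' @param model a `pz_network`
#' @param batch input batch (see [network_forward()])
#' @param y_pg,y_pz binary reference arrays shaped like `batch`
#'   (`y_pz = NULL` drops the PZ term)
#' @param cfg a [loss_config()]
#' @param lr,beta1,beta2,adam_eps Adam constants
#' @return the combined loss before the update
#' @export
network_train_step <- function(model, batch, y_pg, y_pz = NULL,
                               cfg = loss_config(), lr = 1e-5,
                               beta1 = 0.9, beta2 = 0.999,
                               adam_eps = 1e-8) {
  fb <- flatten_batch(batch, model$mode)
  fg <- flatten_batch(y_pg, model$mode)
  has_pz <- !is.null(y_pz)
  fz <- if (has_pz) flatten_batch(y_pz, model$mode) else list(x = numeric(0))
  .nn_train_step(model$ptr, fb$x, fg$x, fz$x, has_pz, cfg$alpha,
                 cfg$smooth_eps, fb$n, lr, beta1, beta2, adam_eps)
}

#' Combined loss of a batch in evaluation mode
#' @inheritParams network_train_step
#' @return scalar loss
#' @export
network_loss <- function(model, batch, y_pg, y_pz = NULL,
                         cfg = loss_config()) {
  fb <- flatten_batch(batch, model$mode)
  fg <- flatten_batch(y_pg, model$mode)
  has_pz <- !is.null(y_pz)
  fz <- if (has_pz) flatten_batch(y_pz, model$mode) else list(x = numeric(0))
  .nn_loss_forward(model$ptr, fb$x, fg$x, fz$x, has_pz, cfg$alpha,
                   cfg$smooth_eps, fb$n)
}

#' Get / set all network weights
#'
#' The weight list includes batch-norm running statistics, so a restored
#' checkpoint reproduces evaluation-mode outputs exactly.
#'
#' @param model a `pz_network`
#' @return list of numeric vectors
#' @export
network_weights <- function(model) .nn_get_params(model$ptr)

#' @rdname network_weights
#' @param weights list as returned by [network_weights()]
#' @export
set_network_weights <- function(model, weights) {
  .nn_set_params(model$ptr, weights)
  invisible(model)
}

#' @export
print.pz_network <- function(x, ...) {
  cat("<pz_network> ", x$mode, " dual-decoder residual U, ",
      x$lambda$n_blocks, " blocks/path, base ", x$lambda$base_filters,
      " filters, ", format(x$parameter_count, big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}
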