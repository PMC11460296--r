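#' Hyperparameter search space
#'
#' The cross-product domain of the 12 searched components. Each component is
#' an integer range, a real interval, or a categorical set. The default
#' space covers: residual blocks {2,3,4}, base filters {8,16,32}, the three
#' activations, kernel sizes 3 or 5 for each of the three in-block
#' convolutions, spatial dropout 0-0.5, rotation 0-30 degrees, shifts
#' 0-0.2, zoom 0-0.3, and horizontal flip on/off.
#'
#' @param components named list of component definitions; each is
#'   `list(type = "int"|"real"|"cat"|"bool", lower =, upper =)` or
#'   `list(type = "cat", values = ...)`
#' @return a `search_space`
#' @export
search_space <- function(components = default_space_components()) {
  if (length(components) != 12L)
    stop("search space must define exactly 12 components")
  if (!identical(sort(names(components)), sort(hp_component_names())))
    stop("search space components must match the hyperparameter vector")
  for (cmp in components) {
    ok <- switch(cmp$type,
      cat = length(cmp$values) > 0,
      bool = TRUE,
      int = , real = cmp$lower <= cmp$upper,
      FALSE)
    if (!isTRUE(ok)) stop("invalid or empty component domain")
  }
  structure(components, class = "search_space")
}

hp_component_names <- function() {
  c("n_blocks", "base_filters", "activation", "kernel_1", "kernel_2",
    "kernel_3", "dropout_p", "aug_rotation_deg", "aug_width_shift",
    "aug_height_shift", "aug_zoom", "aug_hflip")
}

default_space_components <- function() {
  list(
    n_blocks = list(type = "cat", values = c(2L, 3L, 4L)),
    base_filters = list(type = "cat", values = c(8L, 16L, 32L)),
    activation = list(type = "cat", values = c("relu", "elu", "leaky_relu")),
    kernel_1 = list(type = "cat", values = c(3L, 5L)),
    kernel_2 = list(type = "cat", values = c(3L, 5L)),
    kernel_3 = list(type = "cat", values = c(3L, 5L)),
    dropout_p = list(type = "real", lower = 0, upper = 0.5),
    aug_rotation_deg = list(type = "real", lower = 0, upper = 30),
    aug_width_shift = list(type = "real", lower = 0, upper = 0.2),
    aug_height_shift = list(type = "real", lower = 0, upper = 0.2),
    aug_zoom = list(type = "real", lower = 0, upper = 0.3),
    aug_hflip = list(type = "bool")
  )
}

#' Search configuration
#'
#' @param T iteration budget (>= 1)
#' @param n_init random warm-up trials (1 <= n_init <= T)
#' @param partial_epochs truncated training budget per candidate
#' @param seed integer seed for the whole search
#' @param mode `"2d"` or `"3d"` network family
#' @param acquisition only `"expected_improvement"`
#' @param surrogate only `"gaussian_process"`
#' @param objective optional test seam: `function(lambda)` returning the
#'   loss directly, bypassing network training
#' @param schedule a [train_schedule()] for candidate training
#' @param loss a [loss_config()]
#' @param input_shape_2d,input_shape_3d network input shapes used when
#'   training candidates
#' @param candidate_pool random candidates scored per proposal
#' @return a `search_config`
#' @export
search_config <- function(T = 30, n_init = 5, partial_epochs = 5,
                          seed = 1L, mode = "2d",
                          acquisition = "expected_improvement",
                          surrogate = "gaussian_process",
                          objective = NULL,
                          schedule = train_schedule(),
                          loss = loss_config(),
                          input_shape_2d = c(256, 256),
                          input_shape_3d = c(128, 128, 23),
                          candidate_pool = 1000L) {
  if (T < 1) stop("T must be >= 1")
  if (n_init < 1 || n_init > T) stop("need 1 <= n_init <= T")
  if (partial_epochs < 1) stop("partial_epochs must be >= 1")
  acquisition <- match.arg(acquisition, "expected_improvement")
  surrogate <- match.arg(surrogate, "gaussian_process")
  structure(list(T = as.integer(T), n_init = as.integer(n_init),
                 partial_epochs = as.integer(partial_epochs),
                 seed = as.integer(seed), mode = mode,
                 acquisition = acquisition, surrogate = surrogate,
                 objective = objective, schedule = schedule, loss = loss,
                 input_shape_2d = input_shape_2d,
                 input_shape_3d = input_shape_3d,
                 candidate_pool = as.integer(candidate_pool)),
            class = "search_config")
}

# -- lambda <-> encoding ------------------------------------------------------

sample_lambda <- function(space) {
  pick <- function(v) v[sample.int(length(v), 1)]
  vals <- lapply(names(space), function(nm) {
    cmp <- space[[nm]]
    switch(cmp$type,
      cat = pick(cmp$values),
      bool = stats::runif(1) < 0.5,
      int = pick(seq(cmp$lower, cmp$upper)),
      real = stats::runif(1, cmp$lower, cmp$upper))
  })
  names(vals) <- names(space)
  do.call(hyperparam_vector, vals)
}

# numeric encoding in [0,1]^m with one-hot categoricals
encode_lambda <- function(lambda, space) {
  unlist(lapply(names(space), function(nm) {
    cmp <- space[[nm]]
    v <- lambda[[nm]]
    switch(cmp$type,
      cat = as.numeric(cmp$values == v),
      bool = as.numeric(isTRUE(v)),
      int = if (cmp$upper > cmp$lower)
        (as.numeric(v) - cmp$lower) / (cmp$upper - cmp$lower) else 0.5,
      real = if (cmp$upper > cmp$lower)
        (v - cmp$lower) / (cmp$upper - cmp$lower) else 0.5)
  }))
}

space_is_finite <- function(space) {
  all(vapply(space, function(cmp)
    cmp$type %in% c("cat", "bool") ||
      (cmp$type == "int" && is.finite(cmp$lower) && is.finite(cmp$upper)),
    TRUE))
}

enumerate_space <- function(space, limit = 4096L) {
  doms <- lapply(space, function(cmp) switch(cmp$type,
    cat = cmp$values, bool = c(FALSE, TRUE),
    int = seq(cmp$lower, cmp$upper)))
  if (prod(vapply(doms, length, 1L)) > limit) return(NULL)
  grid <- expand.grid(doms, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(hyperparam_vector, as.list(grid[i, , drop = FALSE]))
  })
}

lambda_key <- function(lambda) paste(vapply(lambda, format, ""), collapse = "|")

# -- Gaussian-process surrogate ----------------------------------------------

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

pairwise_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit the Gaussian-process surrogate
#'
#' Matern-5/2 kernel with a single lengthscale on the unit-scaled encoded
#' inputs; lengthscale and noise variance are chosen by marginal likelihood.
#' Outputs are standardized internally.
#'
#' @param X numeric matrix of encoded hyperparameter vectors (rows)
#' @param y observed losses
#' @return a `gp_fit` usable by [gp_predict()]
#' @export
gp_fit <- function(X, y) {
  X <- as.matrix(X)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  D <- pairwise_dist(X, X)
  nll <- function(par) {
    ell <- exp(par[1]); s2n <- exp(par[2])
    K <- matern52(D, ell) + diag(s2n + 1e-10, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), ys))
    sum(log(diag(ch))) + 0.5 * sum(ys * a)
  }
  opt <- stats::optim(c(log(0.5), log(1e-2)), nll, method = "L-BFGS-B",
                      lower = c(log(0.05), log(1e-8)),
                      upper = c(log(10), log(1)),
                      control = list(maxit = 50))
  ell <- exp(opt$par[1]); s2n <- exp(opt$par[2])
  K <- matern52(D, ell) + diag(s2n + 1e-10, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, chol = ch, alpha = alpha, ell = ell, s2n = s2n,
                 mu_y = mu_y, sd_y = sd_y),
            class = "gp_fit")
}

#' Posterior mean and sd of a fitted surrogate at new points
#' @param fit a [gp_fit()]
#' @param Xnew matrix of encoded candidates (rows)
#' @return list with `mean` and `sd` on the original loss scale
#' @export
gp_predict <- function(fit, Xnew) {
  Ks <- matern52(pairwise_dist(as.matrix(Xnew), fit$X), fit$ell)
  mu <- Ks %*% fit$alpha
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mu) * fit$sd_y + fit$mu_y,
       sd = sqrt(var) * fit$sd_y)
}

expected_improvement <- function(mu, sd, best) {
  z <- (best - mu) / sd
  (best - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Propose the next hyperparameter vector
#'
#' With an empty history, a uniform random point of the space. Otherwise
#' expected improvement under the surrogate is maximized over a candidate
#' pool: every not-yet-evaluated point for small finite spaces, or a random
#' pool for continuous/large ones. Finite-space proposals are deduplicated
#' against the history so small discrete spaces get covered exhaustively.
#'
#' @param fit a [gp_fit()] or `NULL`
#' @param history data.frame with the evaluated lambda components and a
#'   `loss` column (may have 0 rows)
#' @param space a [search_space()]
#' @param cfg a [search_config()]
#' @return a [hyperparam_vector()]
#' @export
propose <- function(fit, history, space, cfg = search_config()) {
  if (length(space) == 0) stop("empty search space")
  if (is.null(history) || nrow(history) == 0 || is.null(fit))
    return(sample_lambda(space))
  seen <- character(0)
  if (!is.null(attr(history, "keys"))) seen <- attr(history, "keys")
  cands <- NULL
  if (space_is_finite(space)) {
    all_pts <- enumerate_space(space)
    if (!is.null(all_pts)) {
      keys <- vapply(all_pts, lambda_key, "")
      cands <- all_pts[!keys %in% seen]
      if (length(cands) == 0) cands <- all_pts
    }
  }
  if (is.null(cands))
    cands <- replicate(cfg$candidate_pool, sample_lambda(space),
                       simplify = FALSE)
  Xc <- do.call(rbind, lapply(cands, encode_lambda, space = space))
  pred <- gp_predict(fit, Xc)
  ei <- expected_improvement(pred$mean, pred$sd, min(history$loss))
  cands[[which.max(ei)]]
}

#' Evaluate one candidate by partial training
#'
#' Builds the network for `lambda`, trains it for `partial_epochs` with the
#' candidate's own augmentation magnitudes, and returns the combined
#' validation loss (1 - soft Dice, plus the weighted PZ term). A
#' `cfg$objective` function short-circuits training (test seam). Training
#' that diverges to a non-finite loss is recorded as the worst loss with a
#' warning so the search can continue.
#'
#' @param lambda a [hyperparam_vector()]
#' @param train_set,valid_set lists of standardized cases
#'   (`list(volume, masks)`)
#' @param cfg a [search_config()]
#' @return scalar validation loss
#' @export
evaluate_candidate <- function(lambda, train_set, valid_set, cfg) {
  if (!is.null(cfg$objective)) return(cfg$objective(lambda))
  if (length(train_set) == 0 || length(valid_set) == 0)
    stop("empty training or validation set")
  sched <- cfg$schedule
  sched$epochs_2d <- cfg$partial_epochs
  sched$epochs_3d <- cfg$partial_epochs
  worst <- 1 + cfg$loss$alpha
  res <- tryCatch(
    train_member(lambda, cfg$mode, list(train = train_set,
                                        valid = valid_set),
                 sched, seed = cfg$seed, loss = cfg$loss),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$best_val_loss)) {
    warning("candidate training diverged; recording worst loss")
    return(worst)
  }
  min(res$best_val_loss, worst)
}

#' Run the sequential Bayesian hyperparameter search
#'
#' `n_init` random warm-up trials followed by surrogate-guided proposals;
#' after each evaluation the trial history is augmented and the surrogate
#' posterior refitted. Returns the incumbent (argmin over the history) and
#' the full trial history.
#'
#' @param space a [search_space()]
#' @param data `list(train =, valid =)` standardized case lists (ignored
#'   when `cfg$objective` is set)
#' @param cfg a [search_config()]
#' @return list with `lambda_star`, `best_loss`, and `history` (one row per
#'   trial: the 12 components plus `loss`)
#' @export
run_search <- function(space, data = NULL, cfg = search_config()) {
  with_seed(cfg$seed, {
    history <- NULL
    keys <- character(0)
    lambdas <- list()
    finite_pts <- if (space_is_finite(space)) enumerate_space(space)
    for (t in seq_len(cfg$T)) {
      if (t <= cfg$n_init) {
        lam <- sample_lambda(space)
        if (!is.null(finite_pts)) {
          fresh <- finite_pts[!vapply(finite_pts, lambda_key, "") %in% keys]
          if (length(fresh) > 0) lam <- fresh[[sample.int(length(fresh), 1)]]
        }
      } else {
        X <- do.call(rbind, lapply(lambdas, encode_lambda, space = space))
        fit <- gp_fit(X, history$loss)
        attr(history, "keys") <- keys
        lam <- propose(fit, history, space, cfg)
      }
      loss <- evaluate_candidate(lam, data$train, data$valid, cfg)
      row <- as.data.frame(lapply(unclass(lam), function(v)
        if (is.character(v)) v else as.numeric(v)),
        stringsAsFactors = FALSE)
      row$loss <- loss
      history <- if (is.null(history)) row else rbind(history, row)
      keys <- c(keys, lambda_key(lam))
      lambdas[[t]] <- lam
    }
    best <- which.min(history$loss)
    list(lambda_star = lambdas[[best]], best_loss = history$loss[best],
         history = history)
  })
}
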