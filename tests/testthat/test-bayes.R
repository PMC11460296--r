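# a search space with only some components active keeps the others at a
# single fixed value, so the effective dimensionality is controlled
fixed_space <- function(active) {
  comps <- list(
    n_blocks = list(type = "cat", values = 1L),
    base_filters = list(type = "cat", values = 4L),
    activation = list(type = "cat", values = "relu"),
    kernel_1 = list(type = "cat", values = 3L),
    kernel_2 = list(type = "cat", values = 3L),
    kernel_3 = list(type = "cat", values = 3L),
    dropout_p = list(type = "cat", values = 0),
    aug_rotation_deg = list(type = "cat", values = 0),
    aug_width_shift = list(type = "cat", values = 0),
    aug_height_shift = list(type = "cat", values = 0),
    aug_zoom = list(type = "cat", values = 0),
    aug_hflip = list(type = "cat", values = FALSE))
  for (nm in names(active)) comps[[nm]] <- active[[nm]]
  search_space(comps)
}

test_that("search space and config enforce their invariants", {
  expect_error(search_space(list()), "12 components")
  expect_error(search_config(T = 3, n_init = 5), "n_init")
  expect_error(search_config(T = 0), "T must be")
  expect_s3_class(search_space(), "search_space")
})

test_that("proposals are feasible, seeded, and surrogate-guided", {
  sp <- fixed_space(list(
    dropout_p = list(type = "real", lower = 0, upper = 0.5),
    kernel_1 = list(type = "cat", values = c(3L, 5L))))
  cfg <- search_config(T = 5, n_init = 2, seed = 1)
  set.seed(3)
  a <- propose(NULL, NULL, sp, cfg)
  set.seed(3)
  b <- propose(NULL, NULL, sp, cfg)
  expect_identical(a, b)
  expect_true(a$kernel_1 %in% c(3L, 5L))
  expect_true(a$dropout_p >= 0 && a$dropout_p <= 0.5)

  # 1-D noiseless quadratic: the proposal lands in the best decile of the
  # exhaustively evaluated grid
  spq <- fixed_space(list(
    aug_rotation_deg = list(type = "int", lower = 0, upper = 40)))
  f <- function(lam) (lam$aug_rotation_deg - 17)^2 / 100
  grid <- pzseg:::enumerate_space(spq)
  truth <- vapply(grid, f, numeric(1))
  set.seed(7)
  obs <- grid[seq(1, 41, by = 4)]   # 11 spread observations
  X <- do.call(rbind, lapply(obs, pzseg:::encode_lambda, space = spq))
  y <- vapply(obs, f, numeric(1))
  fit <- gp_fit(X, y)
  hist <- data.frame(loss = y)
  attr(hist, "keys") <- vapply(obs, pzseg:::lambda_key, "")
  lam <- propose(fit, hist, spq, search_config(T = 12, n_init = 1))
  expect_lte(f(lam), sort(truth)[ceiling(length(truth) / 10)])
})

test_that("the search recovers the exhaustive minimum of a discrete space", {
  sp <- fixed_space(list(
    n_blocks = list(type = "cat", values = c(1L, 2L, 3L)),
    kernel_1 = list(type = "cat", values = c(1L, 3L, 5L, 7L)),
    aug_hflip = list(type = "bool")))        # 3 x 4 x 2 = 24 points
  f <- function(lam) {
    (lam$n_blocks - 2)^2 + 0.3 * (lam$kernel_1 - 5)^2 / 4 +
      0.7 * as.numeric(!lam$aug_hflip)
  }
  all_pts <- pzseg:::enumerate_space(sp)
  best_true <- min(vapply(all_pts, f, numeric(1)))
  cfg <- search_config(T = 24, n_init = 5, seed = 5)
  cfg$objective <- f
  res <- run_search(sp, NULL, cfg)
  expect_equal(res$best_loss, best_true)
  expect_identical(nrow(res$history), 24L)
  # all 24 distinct points were visited (deduplicated proposals)
  keys <- apply(res$history[, c("n_blocks", "kernel_1", "aug_hflip")], 1,
                paste, collapse = "|")
  expect_identical(length(unique(keys)), 24L)
  # best-so-far is non-increasing
  expect_true(all(diff(cummin(res$history$loss)) <= 0))
  # reproducibility
  res2 <- run_search(sp, NULL, cfg)
  expect_identical(res$history, res2$history)
  # T = 1 returns the single evaluated point
  cfg1 <- search_config(T = 1, n_init = 1, seed = 2)
  cfg1$objective <- f
  r1 <- run_search(sp, NULL, cfg1)
  expect_identical(r1$best_loss, r1$history$loss[1])
})

test_that("model-guided search beats matched random search on a smooth objective", {
  sp <- fixed_space(list(
    dropout_p = list(type = "real", lower = 0, upper = 0.5),
    aug_zoom = list(type = "real", lower = 0, upper = 0.3)))
  branin <- function(lam) {
    x <- lam$dropout_p / 0.5 * 15 - 5     # [-5, 10]
    y <- lam$aug_zoom / 0.3 * 15          # [0, 15]
    (y - 5.1 / (4 * pi^2) * x^2 + 5 / pi * x - 6)^2 +
      10 * (1 - 1 / (8 * pi)) * cos(x) + 10
  }
  bo_best <- ran_best <- numeric(10)
  for (s in 1:10) {
    cfg <- search_config(T = 30, n_init = 5, seed = s)
    cfg$objective <- branin
    bo_best[s] <- run_search(sp, NULL, cfg)$best_loss
    set.seed(1000 + s)
    ran_best[s] <- min(vapply(1:30, function(i)
      branin(pzseg:::sample_lambda(sp)), numeric(1)))
  }
  expect_lte(median(bo_best), median(ran_best))
})

test_that("candidate evaluation is seeded and honours the test seam", {
  sp <- fixed_space(list())
  lam <- pzseg:::sample_lambda(sp)
  cfg <- search_config(T = 1, n_init = 1, seed = 4)
  cfg$objective <- function(l) 0.123
  expect_identical(evaluate_candidate(lam, NULL, NULL, cfg), 0.123)

  # real partial-training path: deterministic for a fixed seed
  co <- generate_cohort(6, tiny_sampler(), seed = 3)
  cfgp <- tiny_preprocess_cfg()
  cases <- lapply(co, function(case) {
    p <- preprocess_case(case$volume, case$masks, cfgp)
    list(volume = p$volume, masks = p$masks)
  })
  cfg2 <- search_config(T = 1, n_init = 1, partial_epochs = 2, seed = 6,
                        mode = "2d", schedule = tiny_schedule(2))
  l1 <- evaluate_candidate(tiny_lambda(), cases[1:4], cases[5:6], cfg2)
  l2 <- evaluate_candidate(tiny_lambda(), cases[1:4], cases[5:6], cfg2)
  expect_identical(l1, l2)
  expect_true(l1 >= 0 && l1 <= 1.1)
})
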