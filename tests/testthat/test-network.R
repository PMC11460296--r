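test_that("hyperparameter vectors enforce their domains", {
  expect_error(hyperparam_vector(kernel_1 = 4), "odd")
  expect_error(hyperparam_vector(dropout_p = 0.7), "dropout_p")
  expect_error(hyperparam_vector(n_blocks = 0), "n_blocks")
  expect_error(hyperparam_vector(activation = "tanh"), "activation")
  expect_length(unclass(hyperparam_vector()), 12L)
})

test_that("outputs keep the input spatial shape with sigmoid range", {
  hp <- hyperparam_vector(n_blocks = 2, base_filters = 4)
  net <- build_network(hp, "2d", c(64, 64), seed = 2)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  out <- network_forward(net, x)
  expect_identical(dim(out$pg), c(64L, 64L, 2L))
  expect_identical(dim(out$pz), c(64L, 64L, 2L))
  expect_true(all(out$pg > 0 & out$pg < 1))

  # 3D: in-plane pooling leaves an odd slice count untouched
  net3 <- build_network(hp, "3d", c(32, 32, 7), seed = 2)
  x3 <- array(runif(32 * 32 * 7), c(32, 32, 7))
  out3 <- network_forward(net3, x3)
  expect_identical(dim(out3$pg), c(32L, 32L, 7L))

  expect_error(build_network(hp, "2d", c(30, 30)), "divisible")
  expect_error(network_forward(net, array(0, c(32, 32, 1))), "match")
})

test_that("parameter counts match an independent closed-form recount", {
  set.seed(6)
  for (i in 1:6) {
    hp <- hyperparam_vector(
      n_blocks = sample(1:2, 1), base_filters = sample(c(2, 4), 1),
      activation = sample(c("relu", "elu", "leaky_relu"), 1),
      kernel_1 = sample(c(1, 3, 5), 1), kernel_2 = sample(c(1, 3), 1),
      kernel_3 = sample(c(3, 5), 1), dropout_p = runif(1, 0, 0.5))
    for (mode in c("2d", "3d")) {
      shape <- if (mode == "3d") c(16, 16, 6) else c(16, 16)
      net <- build_network(hp, mode, shape, seed = i)
      expect_identical(net$parameter_count, oracle_param_count(hp, mode))
    }
  }
  # without lateral skips the decoder blocks shrink accordingly
  hp <- hyperparam_vector(n_blocks = 2, base_filters = 4)
  net <- build_network(hp, "2d", c(16, 16), lateral_skips = FALSE)
  expect_identical(net$parameter_count,
                   oracle_param_count(hp, "2d", lateral_skips = FALSE))
})

test_that("the emitted architecture follows the structural placement rules", {
  hp <- hyperparam_vector(n_blocks = 3, base_filters = 8)
  arch <- architecture_spec(hp, "2d", c(64, 64))
  nb <- hp$n_blocks
  # dropout precedes every residual block except the first
  expect_identical(sum(arch$type == "spatial_dropout"),
                   as.integer(2 * nb + (nb - 1) + 1))
  # residual blocks: nb down + 1 middle + nb per decoder, 3 convs each
  expect_identical(sum(grepl("_conv[123]$", arch$layer)),
                   as.integer(3 * (3 * nb + 1)))
  expect_identical(sum(arch$type == "max_pool"), as.integer(nb))
  expect_identical(sum(arch$type == "upsample"), as.integer(2 * nb))
  # both heads are kernel-1 convolutions
  heads <- arch[grepl("head", arch$layer), ]
  expect_identical(heads$kernel, c(1, 1))
  # the gland head sees its own and the PZ decoder's features
  expect_identical(heads$cin[heads$layer == "head_pg"],
                   2 * hp$base_filters)
})

test_that("evaluation-mode inference is deterministic, training mode is not degenerate", {
  hp <- hyperparam_vector(n_blocks = 1, base_filters = 4, dropout_p = 0.3)
  net <- build_network(hp, "2d", c(16, 16), seed = 5)
  x <- array(0, c(16, 16, 2))
  a <- network_forward(net, x)
  b <- network_forward(net, x)
  expect_identical(a$pg, b$pg)
  expect_identical(a$pz, b$pz)
})

test_that("one optimization step strictly decreases the combined loss", {
  hp <- hyperparam_vector(n_blocks = 1, base_filters = 4, dropout_p = 0)
  net <- build_network(hp, "2d", c(16, 16), seed = 11)
  set.seed(11)
  y <- array(0, c(16, 16, 4)); y[6:11, 6:11, ] <- 1
  x <- y + array(rnorm(length(y), 0, 0.1), dim(y))
  l0 <- network_loss(net, x, y, y)
  network_train_step(net, x, y, y, lr = 1e-3)
  l1 <- network_loss(net, x, y, y)
  expect_lt(l1, l0)
})

test_that("capacity grows strictly with width and depth", {
  base <- function(bf, nb) build_network(
    hyperparam_vector(n_blocks = nb, base_filters = bf), "2d",
    c(32, 32))$parameter_count
  expect_true(base(4, 1) < base(8, 1))
  expect_true(base(8, 1) < base(8, 2))
  expect_true(base(8, 2) < base(8, 3))
})

test_that("checkpointed weights restore evaluation outputs exactly", {
  hp <- hyperparam_vector(n_blocks = 1, base_filters = 4)
  net <- build_network(hp, "2d", c(16, 16), seed = 3)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  w0 <- network_weights(net)
  out0 <- network_forward(net, x)
  y <- (x > 0.5) * 1
  for (i in 1:3) network_train_step(net, x, y, y, lr = 1e-2)
  expect_false(identical(network_forward(net, x)$pg, out0$pg))
  set_network_weights(net, w0)
  expect_identical(network_forward(net, x)$pg, out0$pg)
})
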