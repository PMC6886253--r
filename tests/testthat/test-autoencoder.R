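# Stacked autoencoder: configuration contracts, forward passes, training.

small_cfg <- function(...) {
  args <- utils::modifyList(list(layer_sizes = c(32L, 8L, 32L),
                                 epochs = 10L), list(...))
  do.call(sae_config, args)
}

test_that("non-palindromic or even architectures are rejected", {
  expect_error(sae_config(layer_sizes = c(256L, 128L, 64L, 128L)), "odd|palindromic")
  expect_error(sae_config(layer_sizes = c(256L, 64L, 128L)), "palindromic")
  cfg <- sae_config()
  expect_equal(cfg$layer_sizes, c(256L, 128L, 64L, 128L, 256L))
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$learning_rate, 0.01)
})

test_that("encode/reconstruct have contract widths and determinism", {
  set.seed(1)
  X <- matrix(rnorm(40 * 468), 40, 468)
  m <- train_sae(X, sae_config(epochs = 2L, seed = 4L), val_fraction = 0)
  Z <- sae_encode(m, X)
  expect_equal(dim(Z), c(40L, 64L))
  expect_equal(dim(sae_reconstruct(m, X)), c(40L, 468L))
  expect_identical(sae_encode(m, X[3, ]), sae_encode(m, X[3, ]))
  # batch encode row i equals single-vector encode
  expect_equal(Z[5, ], sae_encode(m, X[5, ])[1, ], tolerance = 1e-12)

  m2 <- train_sae(X, sae_config(epochs = 2L, seed = 4L), val_fraction = 0)
  expect_identical(m$history$train_mse, m2$history$train_mse)
  expect_identical(m$net$W, m2$net$W)

  expect_error(sae_encode(m, rnorm(10)), "width")
  X[1, 1] <- NA
  expect_error(train_sae(X, sae_config(epochs = 1L)), "non-finite")
})

test_that("zero model with odd-symmetric activation maps zero to zero", {
  cfg <- small_cfg(activation = "tanh")
  net <- list(W = list(matrix(0, 10, 32), matrix(0, 32, 8),
                       matrix(0, 8, 32), matrix(0, 32, 10)),
              b = list(numeric(32), numeric(8), numeric(32), numeric(10)),
              sizes = c(10L, 32L, 8L, 32L, 10L))
  m <- structure(list(net = net, config = cfg, center = numeric(10),
                      scale = rep(1, 10), history = NULL, input_width = 10L),
                 class = "sae_model")
  expect_equal(sae_encode(m, numeric(10))[1, ], numeric(8))
})

test_that("reconstruction MSE matches the hand-evaluated definition", {
  set.seed(2)
  X <- matrix(rnorm(20 * 12), 20, 12)
  m <- train_sae(X, small_cfg(seed = 1L, epochs = 3L), val_fraction = 0)
  v <- X[7, ]
  vhat <- sae_reconstruct(m, v)[1, ]
  by_hand <- sum((v - vhat)^2) / length(v)
  expect_equal(mse(v, vhat), by_hand, tolerance = 1e-12)
})

test_that("constant data is reconstructed almost exactly", {
  X <- matrix(3.7, 50, 12)
  m <- train_sae(X, small_cfg(seed = 2L, epochs = 5L), val_fraction = 0)
  expect_lt(mse(X, sae_reconstruct(m, X)), 1e-4)
})

test_that("training loss descends on well-conditioned data (3 seeds)", {
  set.seed(3)
  Z <- matrix(rnorm(200 * 4), 200, 4)
  X <- Z %*% matrix(rnorm(4 * 24), 4, 24)
  for (s in 1:3) {
    m <- train_sae(X, sae_config(layer_sizes = c(16L, 8L, 16L),
                                 epochs = 30L, seed = s), val_fraction = 0)
    expect_lt(mean(utils::tail(m$history$train_mse, 5)),
              mean(utils::head(m$history$train_mse, 5)))
  }
})

test_that("train and validation do not diverge on i.i.d. data", {
  set.seed(4)
  X <- matrix(rnorm(300 * 24), 300, 24)
  m <- train_sae(X, sae_config(layer_sizes = c(16L, 8L, 16L), epochs = 50L,
                               seed = 1L), val_fraction = 0.2)
  tr <- utils::tail(m$history$train_mse, 1)
  va <- utils::tail(m$history$val_mse, 1)
  expect_lt(abs(va - tr), 0.5 * tr)
})

test_that("checkpoints round-trip exactly enough to reproduce encodings", {
  set.seed(5)
  X <- matrix(rnorm(30 * 12), 30, 12)
  m <- train_sae(X, small_cfg(seed = 3L, epochs = 2L), val_fraction = 0)
  f <- tempfile(fileext = ".json")
  write_sae(m, f)
  back <- read_sae(f)
  expect_equal(sae_encode(back, X), sae_encode(m, X), tolerance = 1e-12)
  expect_equal(back$center, m$center, tolerance = 1e-12, ignore_attr = TRUE)
})
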