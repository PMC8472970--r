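test_that("cross-entropy loss reproduces hand values and the scalar oracle", {
  expect_equal(bce_loss(1, 0.5), -log(0.5), tolerance = 1e-12)
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(bce_loss(y, y), 1e-6)          # perfect prediction, clipping only
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape mismatch")
  set.seed(51)
  yr <- matrix(rbinom(64, 1, 0.4), 8, 8)
  pr <- matrix(runif(64), 8, 8)
  scalar <- 0
  for (i in 1:8) for (j in 1:8) {
    p <- min(max(pr[i, j], 1e-7), 1 - 1e-7)
    scalar <- scalar - (yr[i, j] * log(p) + (1 - yr[i, j]) * log(1 - p))
  }
  expect_equal(bce_loss(yr, pr), scalar / 64, tolerance = 1e-12)
  expect_gte(bce_loss(yr, pr), 0)
})

test_that("a zero learning rate leaves the weights unchanged", {
  ph <- generate_dataset(phantom_spec(height = 64, width = 64, seed = 52), 2)
  net <- build_network(gsau_config(base_width = 2), seed = 1)
  before <- gsaunet:::flatten_params(net$params)
  res <- train_network(net, ph,
                       train_config(epochs = 1, batch_size = 8, lr = 0,
                                    weight_decay = 0, val_fraction = 0, seed = 1),
                       patch_spec(size = 48, per_image = 8, seed = 1))
  after <- gsaunet:::flatten_params(res$net$params)
  for (nm in names(before))
    if (!grepl("rmean$|rvar$", nm))   # running stats do refresh
      expect_lt(max(abs(after[[nm]] - before[[nm]])), 1e-6)
})

test_that("training is reproducible for a fixed seed", {
  ph <- generate_dataset(phantom_spec(height = 64, width = 64, seed = 53), 2)
  run <- function() {
    net <- build_network(gsau_config(base_width = 2), seed = 4)
    train_network(net, ph,
                  train_config(epochs = 2, batch_size = 8, seed = 9),
                  patch_spec(size = 48, per_image = 16, seed = 9))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$history, r2$history)
  expect_identical(gsaunet:::flatten_params(r1$net$params),
                   gsaunet:::flatten_params(r2$net$params))
})

test_that("one optimization step decreases the loss on a fixed batch", {
  set.seed(54)
  cfg <- gsau_config(base_width = 2)
  x <- array(runif(48 * 48 * 8), c(48, 48, 1, 8))
  y <- array(rbinom(48 * 48 * 8, 1, 0.2), c(48, 48, 1, 8))
  improved <- vapply(c(1e-2, 1e-3, 1e-4), function(lr) {
    net <- build_network(cfg, seed = 6)
    eng <- gsaunet:::cpp_engine_create(gsaunet:::flatten_params(net$params),
                                       unclass(cfg))
    l0 <- gsaunet:::cpp_engine_step(eng, x, y, lr)
    l1 <- gsaunet:::cpp_engine_step(eng, x, y, 0)  # re-measure, no update
    l1 < l0
  }, TRUE)
  expect_true(any(improved))
})

test_that("training loss trends down on a small phantom corpus", {
  ph <- generate_dataset(phantom_spec(height = 128, width = 128, seed = 55), 5)
  net <- build_network(gsau_config(base_width = 8), seed = 2)
  res <- train_network(net, ph,
                       train_config(epochs = 5, batch_size = 32, seed = 2),
                       patch_spec(size = 48, per_image = 200, seed = 2))
  ma <- stats::filter(res$history$loss, rep(1 / 3, 3), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0))
  expect_true(all(res$history$loss >= 0))
  # step decay multiplies the rate by (1 - 0.01) each epoch
  expect_equal(res$history$lr,
               0.001 * (1 - 0.01)^(0:4), tolerance = 1e-12)
})

test_that("empty training sets are refused before any work", {
  net <- build_network(gsau_config(base_width = 2), seed = 1)
  expect_error(train_network(net, list(), train_config(epochs = 1)),
               "empty")
})
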