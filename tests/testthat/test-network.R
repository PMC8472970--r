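variants <- expand.grid(gating = c(TRUE, FALSE),
                        mode = c("adaptive", "bilinear", "deconv"),
                        stringsAsFactors = FALSE)

test_that("all six decoder variants map 48x48 inputs to 48x48 probabilities", {
  set.seed(10)
  x <- array(runif(48 * 48 * 2), c(48, 48, 1, 2))
  for (i in seq_len(nrow(variants))) {
    net <- build_network(gsau_config(base_width = 4,
                                     upsample_mode = variants$mode[i],
                                     gating = variants$gating[i]), seed = 1)
    out <- gsaunet:::net_forward(net, x, training = FALSE)
    expect_identical(dim(out$prob), c(48L, 48L, 1L, 2L))
    expect_true(all(out$prob >= 0 & out$prob <= 1))
  }
})

test_that("indivisible input sizes are rejected at forward time", {
  net <- build_network(gsau_config(base_width = 4), seed = 1)
  x <- array(runif(50 * 48), c(50, 48, 1, 1))
  expect_error(gsaunet:::net_forward(net, x), "divisible")
})

test_that("parameter counting is exact on a known layer and deterministic", {
  lay <- list(conv = list(w = array(0, c(1, 1, 2, 3)), b = rep(0, 3)))
  expect_identical(gsaunet:::count_learnable(lay), 9)
  n1 <- count_parameters(build_network(gsau_config(base_width = 8), seed = 1))
  n2 <- count_parameters(build_network(gsau_config(base_width = 8), seed = 99))
  expect_identical(n1, n2)  # counts depend on config, not on weights
})

test_that("parameter counts order bilinear < adaptive <= deconv at fixed widths", {
  for (bw in c(4L, 8L, 16L)) {
    cnt <- vapply(c("bilinear", "adaptive", "deconv"), function(m)
      count_parameters(build_network(gsau_config(base_width = bw,
                                                 upsample_mode = m), seed = 1)), 0)
    expect_lt(cnt["bilinear"], cnt["adaptive"])
    expect_lte(cnt["adaptive"], cnt["deconv"])
  }
})

test_that("evaluation-mode forward is deterministic and size-preserving", {
  set.seed(11)
  net <- build_network(gsau_config(base_width = 4), seed = 3)
  for (side in c(16L, 32L, 64L)) {
    x <- array(runif(side * side), c(side, side, 1, 1))
    p1 <- gsaunet:::net_forward(net, x)$prob
    p2 <- gsaunet:::net_forward(net, x)$prob
    expect_identical(p1, p2)
    expect_identical(dim(p1)[1:2], c(side, side))
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(12)
  for (cfgi in list(gsau_config(base_width = 2),
                    gsau_config(base_width = 2, upsample_mode = "bilinear",
                                gating = FALSE, norm_order = "conventional"),
                    gsau_config(base_width = 2, upsample_mode = "deconv",
                                gate_channels = "single"))) {
    net <- build_network(cfgi, seed = 3)
    x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
    y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
    lossf <- function(nn)
      bce_loss(y, gsaunet:::net_forward(nn, x, training = TRUE, prec = FALSE)$prob)
    fw <- gsaunet:::net_forward(net, x, training = TRUE, prec = FALSE)
    gr <- gsaunet:::net_backward(net, fw, (fw$prob - y) / length(y), prec = FALSE)
    paths <- list()
    gsaunet:::walk_learnable(gr, function(v, path)
      paths[[length(paths) + 1]] <<- path)
    for (pp in sample(paths, 8)) {
      arr <- get_by_path(net$params, pp)
      i <- sample(length(arr), 1)
      ga <- get_by_path(gr, pp)[i]
      eps <- 1e-7
      n1 <- net; a <- arr; a[i] <- a[i] + eps
      n1$params <- set_by_path(n1$params, pp, a)
      n2 <- net; a <- arr; a[i] <- a[i] - eps
      n2$params <- set_by_path(n2$params, pp, a)
      gn <- (lossf(n1) - lossf(n2)) / (2 * eps)
      expect_lt(abs(gn - ga) / max(abs(gn) + abs(ga), 1e-6), 2e-3)
    }
  }
})

test_that("native engine reproduces the reference loss, gradients and forward", {
  set.seed(13)
  for (i in seq_len(nrow(variants))) {
    cfg <- gsau_config(base_width = 2, upsample_mode = variants$mode[i],
                       gating = variants$gating[i])
    net <- build_network(cfg, seed = 2)
    x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
    y <- array(rbinom(32 * 32 * 3, 1, 0.2), c(32, 32, 1, 3))
    fw <- gsaunet:::net_forward(net, x, training = TRUE, prec = FALSE)
    loss_r <- bce_loss(y, fw$prob)
    gr <- gsaunet:::flatten_params(
      gsaunet:::net_backward(net, fw, (fw$prob - y) / length(y), prec = FALSE))
    eng <- gsaunet:::cpp_engine_create(gsaunet:::flatten_params(net$params),
                                       unclass(cfg))
    loss_e <- gsaunet:::cpp_engine_step(eng, x, y, 0)  # lr 0: step w/o update
    expect_equal(loss_e, loss_r, tolerance = 1e-5)
    ge <- gsaunet:::cpp_engine_grads(eng)
    for (nm in names(gr)) {
      expect_false(is.null(ge[[nm]]), info = nm)
      expect_lt(max(abs(ge[[nm]] - gr[[nm]])) / max(max(abs(gr[[nm]])), 1e-8),
                1e-3)
    }
    # after syncing parameters (incl. refreshed bn statistics) back, the
    # reference eval-mode forward matches the engine's
    net$params <- gsaunet:::unflatten_into(net$params,
                                           gsaunet:::cpp_engine_params(eng))
    pr <- gsaunet:::net_forward(net, x, training = FALSE, prec = FALSE)$prob
    pe <- gsaunet:::cpp_engine_forward(eng, x)
    expect_lt(max(abs(pr - pe)), 1e-4)
  }
})

test_that("every learnable parameter receives gradient in all variants", {
  set.seed(14)
  for (i in seq_len(nrow(variants))) {
    cfg <- gsau_config(base_width = 4, upsample_mode = variants$mode[i],
                       gating = variants$gating[i])
    net <- build_network(cfg, seed = 5)
    eng <- gsaunet:::cpp_engine_create(gsaunet:::flatten_params(net$params),
                                       unclass(cfg))
    acc <- NULL
    for (b in 1:3) {
      x <- array(runif(48 * 48 * 4), c(48, 48, 1, 4))
      y <- array(rbinom(48 * 48 * 4, 1, 0.3), c(48, 48, 1, 4))
      gsaunet:::cpp_engine_step(eng, x, y, 0)
      g <- gsaunet:::cpp_engine_grads(eng)
      acc <- if (is.null(acc)) lapply(g, abs)
             else mapply(function(a, b) a + abs(b), acc, g, SIMPLIFY = FALSE)
    }
    dead <- names(acc)[vapply(acc, function(a) any(a == 0), TRUE)]
    expect_identical(dead, character(0),
                     label = sprintf("dead parameters (%s/%s)",
                                     variants$mode[i], variants$gating[i]))
  }
})

test_that("checkpoints round-trip through disk with their configuration", {
  net <- build_network(gsau_config(base_width = 4, upsample_mode = "deconv",
                                   gating = FALSE), seed = 8)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_checkpoint(net, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".yaml")))
  net2 <- load_checkpoint(path)
  expect_identical(net2$config, net$config)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict(net, x), predict(net2, x))
})
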