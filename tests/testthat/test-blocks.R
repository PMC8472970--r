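test_that("gated skip with zeroed gate gives alpha = 0.5 and concat(1.5E, D)", {
  set.seed(1)
  E <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  D <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  gp <- gate_params(matrix(0, 3, 5), rep(0, 3))
  r <- gated_skip(E, D, gp, return_alpha = TRUE)
  expect_identical(dim(r$y), c(6L, 5L, 5L))
  expect_true(all(r$alpha == 0.5))
  expect_equal(r$y[, , 1:3], 1.5 * E)
  expect_equal(r$y[, , 4:5], D)
})

test_that("all-zero encoder passes through untouched decoder half", {
  set.seed(2)
  E <- array(0, c(4, 4, 2))
  D <- array(rnorm(32), c(4, 4, 2))
  gp <- init_gate_params(2, 2)
  y <- gated_skip(E, D, gp)
  expect_true(all(y[, , 1:2] == 0))
  expect_equal(y[, , 3:4], D)
})

test_that("gated skip matches the per-pixel scalar oracle", {
  set.seed(3)
  for (mode in c("per_channel", "single")) {
    E <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    D <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    co <- if (mode == "per_channel") 4 else 1
    wgt <- matrix(rnorm(co * 8), co, 8)
    bia <- rnorm(co)
    y <- gated_skip(E, D, gate_params(wgt, bia))
    expect_equal(y, ref_gated_skip(E, D, wgt, bia), tolerance = 1e-12)
  }
})

test_that("gated skip validates shapes and channels with informative errors", {
  E <- array(0, c(4, 4, 2)); D <- array(0, c(5, 4, 2))
  gp <- init_gate_params(2, 2)
  expect_error(gated_skip(E, D, gp), "spatial sizes differ")
  D2 <- array(0, c(4, 4, 3))
  expect_error(gated_skip(E, D2, gp), "input channels")
})

test_that("attention map lies strictly in (0,1) and channels add", {
  set.seed(4)
  for (i in 1:10) {
    ce <- sample(1:5, 1); cd <- sample(1:5, 1)
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    E <- array(rnorm(h * w * ce, sd = 3), c(h, w, ce))
    D <- array(rnorm(h * w * cd, sd = 3), c(h, w, cd))
    r <- gated_skip(E, D, init_gate_params(ce, cd), return_alpha = TRUE)
    expect_identical(dim(r$y)[3], ce + cd)
    expect_true(all(r$alpha > 0 & r$alpha < 1))
  }
})

test_that("periodic rearrangement follows the row-major subwindow layout", {
  mid <- array(c(1, 2, 3, 4), c(1, 1, 4))
  out <- pixel_shuffle(mid, 2)
  expect_equal(out[, , 1], matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  x <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  expect_identical(pixel_shuffle(x, 1), x)
})

test_that("rearrangement equals the triple-loop index oracle and inverts exactly", {
  set.seed(5)
  mid <- array(rnorm(8 * 3 * 5), c(3, 5, 8))
  out <- pixel_shuffle(mid, 2)
  for (c0 in 0:1) for (y0 in 0:5) for (x0 in 0:9) {
    ci <- c0 * 4 + (y0 %% 2) * 2 + (x0 %% 2)
    expect_identical(out[y0 + 1, x0 + 1, c0 + 1],
                     mid[y0 %/% 2 + 1, x0 %/% 2 + 1, ci + 1])
  }
  expect_identical(pixel_unshuffle(out, 2), mid)
  expect_identical(sort(as.numeric(out)), sort(as.numeric(mid)))
})

test_that("adaptive upsampling expands channels then rearranges, r-dependent", {
  set.seed(6)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  w <- array(rnorm(3 * 3 * 3 * 8), c(3, 3, 3, 8))  # 2 out channels * r^2
  sp <- upsample_spec("adaptive", r = 2, out_channels = 2)
  y <- adaptive_upsample(x, sp, list(w = w))
  expect_identical(dim(y), c(8L, 12L, 2L))
  mid <- ref_conv3(x, w, NULL, 1, 1)
  expect_equal(y, pixel_shuffle(mid, 2), tolerance = 1e-12)
  wbad <- array(0, c(3, 3, 3, 6))
  expect_error(adaptive_upsample(x, sp, list(w = wbad)), "not divisible|requires")
})

test_that("bilinear resize is exact on constants and at the identity size", {
  k <- 3.25
  x <- matrix(k, 5, 7)
  expect_true(all(abs(bilinear_resize(x, 11, 4) - k) < 1e-12))
  set.seed(7)
  x2 <- matrix(rnorm(35), 5, 7)
  expect_equal(bilinear_resize(x2, 5, 7), x2)
  expect_error(bilinear_resize(x2, 0, 5), "positive")
})

test_that("bilinear resize matches the closed-form four-neighbor oracle", {
  x <- matrix(c(0, 2, 1, 3), 2, 2)  # column-major: [[0,1],[2,3]]
  expect_equal(bilinear_resize(x, 4, 4), ref_bilinear(x, 4, 4), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    oh <- sample(2:64, 1); ow <- sample(2:64, 1)
    x <- matrix(rnorm(h * w), h, w)
    expect_equal(bilinear_resize(x, oh, ow), ref_bilinear(x, oh, ow),
                 tolerance = 1e-10)
  }
})

test_that("transposed-convolution size arithmetic matches the two relations", {
  expect_identical(deconv_output_size(4, 3, 2, 1, 0), 7L)
  expect_identical(deconv_output_size(1, 1, 1, 0, 0), 1L)
  expect_identical(deconv_output_size(5, 3, 2, 1, 1), 10L)
  expect_error(deconv_output_size(4, 3, 2, 1, 2), "rem < s")
  # decoder-doubling configurations
  for (i in 2:16) {
    expect_identical(deconv_output_size(i, 6, 2, 2, 0), 2L * i)
    expect_identical(deconv_output_size(i, 4, 2, 1, 0), 2L * i)
    expect_identical(deconv_output_size(i, 3, 2, 1, 1), 2L * i)
  }
})

test_that("conv block is identity for identity kernels without norm", {
  cin <- 3
  ident <- array(0, c(3, 3, cin, cin))
  for (c in seq_len(cin)) ident[2, 2, c, c] <- 1
  params <- conv_block_params(w1 = ident, b1 = rep(0, cin),
                              w2 = ident, b2 = rep(0, cin))
  x <- array(abs(rnorm(5 * 5 * cin)), c(5, 5, cin))  # non-negative input
  expect_equal(conv_block(x, params), x, tolerance = 1e-12)
  zero <- array(0, c(3, 3, cin, cin))
  pz <- conv_block_params(w1 = zero, b1 = rep(0, cin),
                          w2 = zero, b2 = rep(0, cin))
  expect_true(all(conv_block(x, pz) == 0))
})

test_that("conv block matches the direct-convolution oracle", {
  set.seed(9)
  w1 <- array(rnorm(3 * 3 * 2 * 3, sd = 0.4), c(3, 3, 2, 3))
  w2 <- array(rnorm(3 * 3 * 3 * 3, sd = 0.4), c(3, 3, 3, 3))
  b1 <- rnorm(3); b2 <- rnorm(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y <- conv_block(x, conv_block_params(w1, b1, w2, b2))
  ref <- ref_conv3(ref_conv3(x, w1, b1, 1, 1), w2, b2, 1, 1)
  ref[ref < 0] <- 0
  expect_equal(y, ref, tolerance = 1e-10)
  expect_error(conv_block(array(0, c(6, 6, 5)),
                          conv_block_params(w1, b1, w2, b2)), "channels")
})
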