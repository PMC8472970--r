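test_that("sampler emits the requested number of correctly shaped patches", {
  ph <- generate_phantom(phantom_spec(height = 96, width = 96, seed = 41))
  ps <- sample_patches(ph$image, ph$vessels, ph$fov,
                       patch_spec(per_image = 5, seed = 1))
  expect_identical(dim(ps$images), c(48L, 48L, 1L, 5L))
  expect_identical(dim(ps$labels), c(48L, 48L, 5L))
  expect_true(all(ps$labels %in% c(0L, 1L)))
})

test_that("an exactly patch-sized image admits a single position", {
  img <- matrix(runif(48 * 48), 48, 48)
  lab <- matrix(rbinom(48 * 48, 1, 0.1), 48, 48)
  ps <- sample_patches(img, lab, NULL,
                       patch_spec(per_image = 4, inside_fov = FALSE, seed = 2))
  for (i in 1:4) expect_identical(ps$images[, , 1, i], img)
})

test_that("patch centers respect the FOV and the draw is reproducible", {
  ph <- generate_phantom(phantom_spec(height = 128, width = 128, seed = 42))
  sp <- patch_spec(per_image = 200, seed = 7)
  ps <- sample_patches(ph$image, ph$vessels, ph$fov, sp)
  expect_true(all(ph$fov[ps$centers] == 1L))
  ps2 <- sample_patches(ph$image, ph$vessels, ph$fov, sp)
  expect_identical(ps, ps2)
})

test_that("undersized images are rejected with both sizes named", {
  img <- matrix(0, 40, 60)
  expect_error(sample_patches(img, img, NULL, patch_spec(size = 48)),
               "40 x 60.*48 x 48")
})

test_that("stitching a constant-output stub gives a constant map", {
  img <- matrix(runif(100 * 90), 100, 90)
  stub <- function(tile) matrix(0.7, nrow(tile), ncol(tile))
  out <- tile_and_stitch(img, NULL, stub, tile_spec(48, 24))
  expect_identical(dim(out), dim(img))
  expect_true(all(abs(out - 0.7) < 1e-12))
})

test_that("stitching weights sum to one everywhere (all-ones stub)", {
  img <- matrix(0, 130, 75)
  ones <- function(tile) matrix(1, nrow(tile), ncol(tile))
  out <- tile_and_stitch(img, NULL, ones, tile_spec(48, 24))
  expect_true(all(abs(out - 1) < 1e-12))
})

test_that("disjoint tiles reassemble the input exactly at stride = size", {
  img <- matrix(seq_len(96 * 96) / (96 * 96), 96, 96)
  echo <- function(tile) tile
  out <- tile_and_stitch(img, NULL, echo, tile_spec(48, 48))
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("overlapping stitching matches a per-pixel accumulation oracle", {
  set.seed(43)
  img <- matrix(runif(80 * 70), 80, 70)
  f <- function(tile) tile * 2 + mean(tile)   # deterministic non-trivial stub
  out <- tile_and_stitch(img, NULL, f, tile_spec(48, 24))
  acc <- matrix(0, 80, 70); cnt <- matrix(0, 80, 70)
  oy <- gsaunet:::tile_origins(80, 48, 24)
  ox <- gsaunet:::tile_origins(70, 48, 24)
  for (y in oy) for (x in ox) {
    rr <- y:(y + 47); cc <- x:(x + 47)
    acc[rr, cc] <- acc[rr, cc] + f(img[rr, cc])
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  expect_equal(out, acc / cnt, tolerance = 1e-12)
})

test_that("images smaller than one tile are reflect-padded and cropped back", {
  img <- matrix(runif(30 * 96), 30, 96)
  stub <- function(tile) matrix(0.25, nrow(tile), ncol(tile))
  out <- tile_and_stitch(img, NULL, stub, tile_spec(48, 24))
  expect_identical(dim(out), c(30L, 96L))
  expect_true(all(abs(out - 0.25) < 1e-12))
})
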