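make_disk_dataset <- function(n, dir, seed = 31) {
  ph <- generate_dataset(phantom_spec(height = 64, width = 64, seed = seed),
                         n, seed = seed)
  write_dataset(ph, dir)
  ph
}

test_that("synthetic datasets round-trip through the DRIVE layout losslessly", {
  dir <- withr::local_tempdir()
  ph <- make_disk_dataset(3, dir)
  rec <- load_dataset(dir, "synthetic")
  expect_identical(nrow(rec), 3L)
  expect_false(any(rec$fov_estimated))
  for (i in 1:3) {
    sm <- load_sample(rec[i, ])
    expect_identical(sm$image, ph[[i]]$image)      # 8-bit image, bit exact
    expect_identical(sm$label, ph[[i]]$vessels)    # binary
    expect_identical(sm$fov, ph[[i]]$fov)
  }
})

test_that("empty directories yield an empty record set with a warning", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images"))
  expect_warning(rec <- load_dataset(dir, "synthetic"), "no images")
  expect_identical(nrow(rec), 0L)
})

test_that("size mismatches are reported with the offending sample named", {
  dir <- withr::local_tempdir()
  make_disk_dataset(2, dir)
  png::writePNG(matrix(0.5, 32, 32), file.path(dir, "1st_manual", "sample_002.png"))
  expect_error(load_dataset(dir, "synthetic"), "sample_002")
})

test_that("missing masks in STARE-style layouts trigger FOV estimation", {
  dir <- withr::local_tempdir()
  make_disk_dataset(2, dir)
  unlink(file.path(dir, "mask"), recursive = TRUE)
  rec <- load_dataset(dir, "stare")
  expect_true(all(rec$fov_estimated))
  sm <- load_sample(rec[1, ])
  truth <- generate_phantom(phantom_spec(height = 64, width = 64,
                                         seed = gsaunet:::derive_seed(31, 1)))$fov
  agree <- mean(sm$fov == truth)
  expect_gt(agree, 0.95)   # luminance threshold + largest component
})

test_that("fixed-halves splitting gives the 20/20 protocol shape", {
  rec <- data.frame(id = sprintf("s%02d", 1:40))
  sp <- make_split(rec, split_plan("fixed_halves"))
  expect_identical(sp$train$id, sprintf("s%02d", 1:20))
  expect_identical(sp$test$id, sprintf("s%02d", 21:40))
  rec4 <- data.frame(id = sprintf("s%d", 1:4))
  sp4 <- make_split(rec4, split_plan("fixed_halves"))
  expect_identical(nrow(sp4$train), 2L)
  expect_identical(nrow(sp4$test), 2L)
})

test_that("the 28-image protocol trains on 20 and tests on 8", {
  rec <- data.frame(id = sprintf("c%02d", 1:28))
  sp <- make_split(rec, split_plan("first20_rest8"))
  expect_identical(nrow(sp$train), 20L)
  expect_identical(nrow(sp$test), 8L)
  expect_identical(intersect(sp$train$id, sp$test$id), character(0))
})

test_that("leave-one-out folds partition the records exactly once", {
  rec <- data.frame(id = sprintf("t%02d", 1:7))
  seen <- character(0)
  for (f in 1:7) {
    sp <- make_split(rec, split_plan("leave_one_out", fold = f))
    expect_identical(nrow(sp$test), 1L)
    expect_identical(sort(c(sp$train$id, sp$test$id)), sort(rec$id))
    seen <- c(seen, sp$test$id)
  }
  expect_identical(sort(seen), sort(rec$id))
  expect_error(make_split(rec, split_plan("leave_one_out", fold = 8)),
               "out of range")
})
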