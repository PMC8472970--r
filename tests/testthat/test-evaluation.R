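# 10x10 toy grid with hand-tallied confusion counts: the label marks a
# 3x3 vessel square (9 positives); the prediction shifts it right by one
# column (6 overlap, 3 false positives, 3 misses) inside a circular-ish
# FOV that keeps all 100 pixels.
toy_grid <- function() {
  lab <- matrix(0L, 10, 10); lab[4:6, 4:6] <- 1L
  pred <- matrix(0L, 10, 10); pred[4:6, 5:7] <- 1L
  list(pred = pred, lab = lab, TP = 6L, FP = 3L, FN = 3L, TN = 88L)
}

test_that("confusion counts match hand tallies and conserve totals", {
  g <- toy_grid()
  cc <- confusion(g$pred, g$lab)
  expect_identical(cc$TP, g$TP); expect_identical(cc$FP, g$FP)
  expect_identical(cc$FN, g$FN); expect_identical(cc$TN, g$TN)
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 100L)
  same <- confusion(g$lab, g$lab)
  expect_identical(same$FP + same$FN, 0L)
  inv <- confusion(1 - g$lab, g$lab)
  expect_identical(inv$TP + inv$TN, 0L)
  expect_error(confusion(matrix(0, 2, 3), matrix(0, 2, 2)), "shape mismatch")
})

test_that("counts are restricted to the field of view", {
  g <- toy_grid()
  fov <- matrix(0L, 10, 10); fov[4:6, 4:6] <- 1L   # only the label square
  cc <- confusion(g$pred, g$lab, fov)
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 9L)
  expect_identical(cc$TP, 6L)
  expect_identical(cc$FN, 3L)
})

test_that("threshold metrics reproduce the closed-form ratios", {
  m <- seg_metrics(list(TP = 8, FN = 2, TN = 85, FP = 5))
  expect_equal(m$accuracy, 0.93, tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.8, tolerance = 1e-12)
  expect_equal(m$specificity, 85 / 90, tolerance = 1e-12)
  expect_equal(m$precision, 8 / 13, tolerance = 1e-12)
  expect_equal(m$f_measure, 2 * (8 / 13) * 0.8 / (8 / 13 + 0.8), tolerance = 1e-12)
  perfect <- seg_metrics(list(TP = 10, FN = 0, TN = 90, FP = 0))
  for (k in c("accuracy", "sensitivity", "specificity", "precision", "f_measure"))
    expect_equal(perfect[[k]], 1)
})

test_that("zero denominators yield flagged NA values, never silent zeros", {
  m <- seg_metrics(list(TP = 0, FN = 0, TN = 10, FP = 0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_true(all(c("sensitivity", "precision", "f_measure") %in% m$undefined))
  allz <- seg_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0))
  expect_true(length(allz$undefined) >= 5)
})

test_that("metrics agree with an independent formula evaluation on random tables", {
  set.seed(61)
  for (i in 1:1000) {
    k <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                          c("TP", "FP", "TN", "FN")))
    m <- seg_metrics(k)
    tot <- k$TP + k$FP + k$TN + k$FN
    if (tot > 0)
      expect_equal(m$accuracy, (k$TP + k$TN) / tot, tolerance = 1e-12)
    if (k$TP + k$FN > 0)
      expect_equal(m$sensitivity, k$TP / (k$TP + k$FN), tolerance = 1e-12)
    if (k$TN + k$FP > 0)
      expect_equal(m$specificity, k$TN / (k$TN + k$FP), tolerance = 1e-12)
    if (k$TP + k$FP > 0)
      expect_equal(m$precision, k$TP / (k$TP + k$FP), tolerance = 1e-12)
  }
})

test_that("ROC area is 1 for separable scores and 1/2 for constant scores", {
  lab <- matrix(c(rep(1, 10), rep(0, 10)), 4, 5)
  sep <- matrix(c(runif(10, 0.8, 1), runif(10, 0, 0.2)), 4, 5)
  expect_equal(roc_pr(sep, lab)$auc_roc, 1.0)
  cst <- matrix(0.4, 4, 5)
  expect_equal(roc_pr(cst, lab)$auc_roc, 0.5)
  expect_error(roc_pr(cst, matrix(1, 4, 5)), "negative")
  expect_error(roc_pr(cst, matrix(0, 4, 5)), "positive")
})

test_that("sweep ROC area equals the all-pairs rank statistic, ties halved", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    lab <- matrix(0L, 1, n); lab[1, sample(n, sample(2:(n - 2), 1))] <- 1L
    sc <- matrix(round(runif(n), 2), 1, n)   # rounding forces ties
    r <- roc_pr(sc, lab)
    expect_equal(r$auc_roc, ref_auc_pairs(as.numeric(sc), as.numeric(lab)),
                 tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("pixels outside the FOV cannot influence any metric", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 63))
  set.seed(64)
  pred <- matrix(runif(64 * 64), 64, 64)
  base_cc <- confusion(pred, ph$vessels, ph$fov)
  base_rp <- roc_pr(pred, ph$vessels, ph$fov)
  pred2 <- pred; pred2[ph$fov == 0] <- runif(sum(ph$fov == 0))
  lab2 <- ph$vessels; lab2[ph$fov == 0] <- 1L
  expect_identical(confusion(pred2, lab2, ph$fov), base_cc)
  expect_equal(roc_pr(pred2, lab2, ph$fov)$auc_roc, base_rp$auc_roc)
})

test_that("raising the binarization threshold never increases sensitivity", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 65))
  set.seed(66)
  pred <- matrix(runif(64 * 64), 64, 64) * 0.5 + 0.5 * ph$vessels
  sens <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    seg_metrics(confusion(pred, ph$vessels, ph$fov, th))$sensitivity, 0)
  expect_true(all(diff(sens) <= 0))
})

test_that("a label-echo stub scores a perfect averaged report", {
  ph <- generate_dataset(phantom_spec(height = 64, width = 64, seed = 67), 2)
  # feed the ground truth in as the image; an echo stub then predicts it
  samples <- lapply(ph, function(p)
    list(image = p$vessels + 0, label = p$vessels, fov = p$fov))
  rep1 <- evaluate_model(function(tile) tile, samples, tile_spec(48, 24))
  expect_equal(unname(rep1$mean["f_measure"]), 1)
  expect_equal(unname(rep1$mean["auc_roc"]), 1)
})

test_that("averaging over duplicated images equals the single-image report", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 68))
  sm <- list(image = ph$image, label = ph$vessels, fov = ph$fov)
  blurstub <- function(tile) 1 - tile   # vessels are dark: invert as a score
  r1 <- evaluate_model(blurstub, list(sm), tile_spec(48, 24))
  r2 <- evaluate_model(blurstub, list(sm, sm), tile_spec(48, 24))
  expect_equal(r2$mean, r1$mean)
  expect_error(evaluate_model(blurstub, list(), tile_spec(48, 24)), "empty")
})
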