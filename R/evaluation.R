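#' Confusion counts over the field of view
#'
#' Tallies TP/FP/TN/FN pixels between a binarized prediction and the
#' ground truth, restricted to `fov == 1` pixels. TP counts correctly
#' detected vessel pixels, TN correctly detected background; totals are
#' conserved (`TP + FP + TN + FN` equals the number of FOV pixels).
#'
#' @param pred numeric score/probability matrix (binarized at
#'   `threshold`) or an already binary matrix.
#' @param label 0/1 ground-truth matrix.
#' @param fov 0/1 field-of-view matrix (NULL evaluates every pixel).
#' @param threshold binarization threshold (default 0.5, exceeded
#'   strictly).
#' @return object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(pred, label, fov = NULL, threshold = 0.5) {
  if (!identical(dim(pred), dim(label)))
    stop(sprintf("shape mismatch: pred is %s, label is %s",
                 fmt_shape(pred), fmt_shape(label)))
  if (is.null(fov)) fov <- array(1L, dim(pred))
  if (!identical(dim(pred), dim(fov)))
    stop(sprintf("shape mismatch: pred is %s, fov is %s",
                 fmt_shape(pred), fmt_shape(fov)))
  sel <- fov == 1L
  p <- pred[sel] > threshold
  y <- label[sel] == 1L
  structure(list(TP = sum(p & y), FP = sum(p & !y),
                 TN = sum(!p & !y), FN = sum(!p & y)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and F-measure, the
#' harmonic mean of precision and sensitivity. Ratios with a zero
#' denominator are returned as `NA` and named in the `undefined` field --
#' never silently zero.
#'
#' @param counts a [confusion()] result, or a list with TP/FP/TN/FN.
#' @return object of class `metric_report`: list with the five metrics
#'   and `undefined`, a character vector of metrics whose denominator was
#'   zero.
#' @export
seg_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- ratio(TP + TN, total)
  sen <- ratio(TP, TP + FN)
  spe <- ratio(TN, TN + FP)
  pre <- ratio(TP, TP + FP)
  f <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  vals <- c(accuracy = acc, sensitivity = sen, specificity = spe,
            precision = pre, f_measure = f)
  structure(c(as.list(vals), list(undefined = names(vals)[is.na(vals)])),
            class = "metric_report")
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps the binarization threshold over the unique score values inside
#' the FOV and returns both curves as point lists together with their
#' trapezoidal areas. Tied scores are handled as single sweep points, so
#' the ROC area equals the rank statistic (probability that a random
#' vessel pixel outscores a random background pixel, ties counted half).
#'
#' @param scores numeric matrix of vessel scores in `[0, 1]`.
#' @param label 0/1 ground-truth matrix.
#' @param fov 0/1 field-of-view matrix (NULL evaluates every pixel).
#' @return list with `roc` (data.frame fpr/tpr/threshold), `pr`
#'   (data.frame recall/precision/threshold), `auc_roc`, `auc_pr`.
#' @export
roc_pr <- function(scores, label, fov = NULL) {
  if (!identical(dim(scores), dim(label)))
    stop(sprintf("shape mismatch: scores is %s, label is %s",
                 fmt_shape(scores), fmt_shape(label)))
  if (is.null(fov)) fov <- array(1L, dim(scores))
  sel <- fov == 1L
  s <- as.numeric(scores[sel])
  y <- as.integer(label[sel] == 1L)
  P <- sum(y); N <- length(y) - P
  if (P == 0L) stop("no positive (vessel) pixels inside the FOV")
  if (N == 0L) stop("no negative (background) pixels inside the FOV")

  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  last <- cumsum(rep(1L, length(s)))[!duplicated(s, fromLast = TRUE)]
  # cumulative counts at each unique threshold (predict positive if score >= thr)
  ctp <- cumsum(y)[last]
  cfp <- (last - cumsum(y)[last])
  thr <- s[last]
  tpr <- c(0, ctp / P); fpr <- c(0, cfp / N)
  auc_roc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  recall <- ctp / P
  precision <- ctp / (ctp + cfp)
  rec_pts <- c(0, recall)
  pre_pts <- c(precision[1], precision)
  auc_pr <- sum(diff(rec_pts) * (pre_pts[-1] + pre_pts[-length(pre_pts)]) / 2)

  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
       pr = data.frame(recall = rec_pts, precision = pre_pts,
                       threshold = c(Inf, thr)),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Evaluate a network on a test set
#'
#' Predicts every test image (by tiling), computes FOV-restricted
#' confusion metrics at the given threshold plus ROC/PR areas per image,
#' and the unweighted mean across images (the leave-one-out averaging
#' protocol reduces to this with one image per fold).
#'
#' @param net a `gsau_net`, or a function mapping a tile to scores (for
#'   stubs).
#' @param test list of `phantom`s / image-label-fov lists, or a records
#'   data.frame from [load_dataset()].
#' @param tiles a [tile_spec()].
#' @param threshold binarization threshold.
#' @param fov_restrict evaluate inside the FOV only (the DRIVE-family
#'   convention); FALSE scores every pixel.
#' @return list with `per_image` (data.frame, one row per image) and
#'   `mean` (named numeric vector of column means).
#' @export
evaluate_model <- function(net, test, tiles = tile_spec(), threshold = 0.5,
                           fov_restrict = TRUE) {
  if (is.data.frame(test)) {
    if (!nrow(test)) stop("test set is empty")
    test <- lapply(seq_len(nrow(test)), function(i) load_sample(test[i, ]))
  }
  if (!length(test)) stop("test set is empty")
  samples <- lapply(test, as_training_sample)
  rows <- lapply(seq_along(samples), function(i) {
    sm <- samples[[i]]
    pred <- tryCatch(
      tile_and_stitch(sm$image, sm$fov, net, tiles),
      error = function(e) stop(sprintf("prediction failed on image %d: %s",
                                       i, conditionMessage(e))))
    fov <- if (fov_restrict) sm$fov else NULL
    mt <- seg_metrics(confusion(pred, sm$label, fov, threshold))
    rp <- roc_pr(pred, sm$label, fov)
    data.frame(image = i, accuracy = mt$accuracy, sensitivity = mt$sensitivity,
               specificity = mt$specificity, precision = mt$precision,
               f_measure = mt$f_measure, auc_roc = rp$auc_roc,
               auc_pr = rp$auc_pr)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image,
       mean = colMeans(per_image[, -1, drop = FALSE]))
}
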