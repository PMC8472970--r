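#' Training configuration
#'
#' Optimization hyperparameters. The reference protocol uses 200 epochs,
#' batch size 256, Adam with initial learning rate 0.001 and first-moment
#' decay 0.9, step learning-rate decay with coefficient 0.01 (the rate is
#' multiplied by 1 - 0.01 every `lr_step` epochs) and weight decay 0.0005;
#' `configs/desk.yaml` ships a scaled-down profile for CPU-scale runs.
#'
#' @param epochs training epochs.
#' @param batch_size patches per optimization step.
#' @param lr initial learning rate.
#' @param beta1 Adam first-moment (exponential) decay rate.
#' @param step_decay step-decay coefficient; each decay step multiplies the
#'   learning rate by `1 - step_decay`.
#' @param lr_step epochs between decay steps (default 1).
#' @param weight_decay L2 coefficient added to gradients.
#' @param val_fraction fraction of sampled patches held out for the
#'   per-epoch validation loss.
#' @param seed integer seed controlling shuffling and initialization of the
#'   run.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L, lr = 0.001,
                         beta1 = 0.9, step_decay = 0.01, lr_step = 1L,
                         weight_decay = 0.0005, val_fraction = 0.1, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0, beta1 > 0, beta1 < 1,
            step_decay >= 0, step_decay < 1, lr_step >= 1, weight_decay >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, step_decay = step_decay,
                 lr_step = as.integer(lr_step), weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' `-mean(y * log(p) + (1 - y) * log(1 - p))` with predictions clipped to
#' `[eps, 1 - eps]`, `eps = 1e-7`, so the value is always finite and
#' non-negative (nats per pixel).
#'
#' @param y 0/1 labels (any array shape).
#' @param yhat predicted probabilities in `[0, 1]`, same shape.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat) ||
      !identical(dim(y) %||% length(y), dim(yhat) %||% length(yhat)))
    stop(sprintf("shape mismatch: y is %s, yhat is %s",
                 fmt_shape(y), fmt_shape(yhat)))
  p <- pmin(pmax(as.numeric(yhat), eps), 1 - eps)
  yv <- as.numeric(y)
  -mean(yv * log(p) + (1 - yv) * log(1 - p))
}

as_training_sample <- function(x) {
  if (inherits(x, "phantom"))
    return(list(image = x$image, label = x$vessels, fov = x$fov))
  if (is.list(x) && all(c("image", "label", "fov") %in% names(x)))
    return(x[c("image", "label", "fov")])
  stop("training samples must be phantoms or lists with image/label/fov")
}

#' Train a segmentation network
#'
#' Patch-based training: random patches are sampled from every training
#' image (see [sample_patches()]), then optimized with Adam under the mean
#' pixelwise binary cross-entropy, with step learning-rate decay and
#' weight decay. A fixed `config$seed` makes the
#' run reproducible on one device.
#'
#' @param net a `gsau_net` from [build_network()].
#' @param data list of `phantom` objects or lists with
#'   `image`/`label`/`fov`.
#' @param config a [train_config()].
#' @param patches a [patch_spec()] describing per-image sampling.
#' @param verbose print one line per epoch.
#' @return list with the trained `net` and `history`, a data.frame with
#'   per-epoch training loss, validation loss and learning rate.
#' @export
train_network <- function(net, data, config = train_config(),
                          patches = patch_spec(), verbose = FALSE) {
  stopifnot(inherits(net, "gsau_net"), inherits(config, "train_config"),
            inherits(patches, "patch_spec"))
  if (!length(data)) stop("training set is empty")
  samples <- lapply(data, as_training_sample)
  set.seed(config$seed)

  sz <- patches$size
  nper <- patches$per_image
  M <- nper * length(samples)
  X <- array(0, c(sz, sz, 1L, M))
  Y <- array(0, c(sz, sz, M))
  for (i in seq_along(samples)) {
    sp <- patches
    sp$seed <- derive_seed(config$seed, i)
    ps <- sample_patches(samples[[i]]$image, samples[[i]]$label,
                         samples[[i]]$fov, sp)
    idx <- (i - 1L) * nper + seq_len(nper)
    X[, , 1L, idx] <- ps$images
    Y[, , idx] <- ps$labels
  }

  perm <- sample.int(M)
  n_val <- floor(config$val_fraction * M)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- perm[setdiff(seq_len(M), seq_len(n_val))]
  if (!length(tr_idx)) stop("no training patches left after validation split")

  lr <- config$lr
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_loss = numeric(), lr = numeric())

  # the native single-precision engine holds parameters, Adam state and
  # workspaces between steps; parameters are synced back at the end
  eng <- cpp_engine_create(flatten_params(net$params), unclass(net$config))
  cpp_engine_set_optim(eng, config$beta1, 0.999, 1e-8, config$weight_decay)

  for (epoch in seq_len(config$epochs)) {
    order_ep <- sample(tr_idx)
    losses <- numeric(0)
    for (start in seq(1L, length(order_ep), by = config$batch_size)) {
      sel <- order_ep[start:min(start + config$batch_size - 1L, length(order_ep))]
      xb <- X[, , , sel, drop = FALSE]
      yb <- array(Y[, , sel], c(sz, sz, 1L, length(sel)))
      losses <- c(losses, cpp_engine_step(eng, xb, yb, lr))
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      vl <- numeric(0)
      for (start in seq(1L, length(val_idx), by = config$batch_size)) {
        sel <- val_idx[start:min(start + config$batch_size - 1L, length(val_idx))]
        xb <- X[, , , sel, drop = FALSE]
        yb <- array(Y[, , sel], c(sz, sz, 1L, length(sel)))
        vl <- c(vl, bce_loss(yb, cpp_engine_forward(eng, xb)))
      }
      val_loss <- mean(vl)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val %.5f  lr %.2e",
                      epoch, mean(losses), val_loss, lr))
    if (epoch %% config$lr_step == 0L) lr <- lr * (1 - config$step_decay)
  }
  net$params <- unflatten_into(net$params, cpp_engine_params(eng))
  list(net = net, history = hist)
}
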