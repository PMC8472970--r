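#' Network configuration
#'
#' Architecture hyperparameters for the gated skip-connection network with
#' adaptive upsampling. The encoder has four stages (channel widths
#' `base_width * 2^(t-1)`) joined by stride-2 3x3 downsampling convolutions,
#' with a bridge of `16 * base_width` channels; the decoder mirrors it with
#' four upsampling stages. Input spatial sizes must be divisible by
#' `2^depth = 16` (e.g. 48 -> 24 -> 12 -> 6 -> 3).
#'
#' @param in_channels input image channels (1: grayscale / green channel).
#' @param base_width channels of the first encoder stage (default 32).
#' @param upsample_mode `"adaptive"`, `"bilinear"`, or `"deconv"`.
#' @param gating use gated skip-connections (TRUE) or plain concatenation.
#' @param r subwindow factor of the adaptive upsampling (2 for the
#'   stage-wise decoder; 4 and 6 are accepted for single-shot experiments
#'   outside the standard decoder).
#' @param multiscale_input inject bilinear-downsampled copies of the input
#'   (1/2, 1/4, 1/8 scale) into encoder stages 2--4.
#' @param gate_channels `"per_channel"` (an attention channel per encoder
#'   channel) or `"single"` (one broadcast attention channel).
#' @param norm_order `"deferred"` (conv-norm-conv-norm-relu: one ReLU
#'   closes the block) or `"conventional"` (relu after each norm).
#' @return a `gsau_config` object.
#' @export
gsau_config <- function(in_channels = 1L, base_width = 32L,
                        upsample_mode = c("adaptive", "bilinear", "deconv"),
                        gating = TRUE, r = 2L, multiscale_input = TRUE,
                        gate_channels = c("per_channel", "single"),
                        norm_order = c("deferred", "conventional")) {
  upsample_mode <- match.arg(upsample_mode)
  gate_channels <- match.arg(gate_channels)
  norm_order <- match.arg(norm_order)
  r <- as.integer(r)
  if (upsample_mode == "adaptive" && !r %in% c(2L, 4L, 6L))
    stop("r must be one of 2, 4, 6 for adaptive upsampling")
  if (upsample_mode == "adaptive" && r != 2L)
    stop("the stage-wise decoder doubles resolution per stage and requires r = 2; ",
         "larger r is available through pixel_shuffle()/adaptive_upsample() directly")
  structure(list(in_channels = as.integer(in_channels), depth = 4L,
                 base_width = as.integer(base_width), upsample_mode = upsample_mode,
                 gating = isTRUE(gating), r = r,
                 multiscale_input = isTRUE(multiscale_input),
                 gate_channels = gate_channels, norm_order = norm_order),
            class = "gsau_config")
}

#' Build a segmentation network
#'
#' Instantiates all learnable parameters (He-initialized convolutions,
#' unit-scale batch norms) for the configured architecture: a four-stage
#' encoder with multiscale input injection, a bridge, and a four-stage
#' decoder whose skip-connections are gated when `config$gating` is TRUE.
#' The head is a 1x1 convolution to a single sigmoid channel.
#'
#' @param config a [gsau_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `gsau_net`.
#' @export
build_network <- function(config = gsau_config(), seed = NULL) {
  stopifnot(inherits(config, "gsau_config"))
  if (!is.null(seed)) set.seed(seed)
  bw <- config$base_width
  widths <- bw * 2L^(0:3)        # encoder stage widths
  bridge_w <- bw * 16L
  msc <- bw                      # multiscale embedding channels
  p <- list()
  p$enc <- vector("list", 4L)
  p$enc[[1]] <- new_block(config$in_channels, widths[1])
  for (t in 2:4) {
    cin <- widths[t] + if (config$multiscale_input) msc else 0L
    p$enc[[t]] <- new_block(cin, widths[t])
  }
  p$down <- lapply(1:4, function(t) {
    cout <- if (t < 4) widths[t + 1] else bridge_w
    list(conv = new_conv(3L, widths[t], cout, bias = FALSE), bn = new_bn(cout))
  })
  if (config$multiscale_input)
    p$ms <- lapply(2:4, function(t)
      list(conv = new_conv(3L, config$in_channels, msc, bias = FALSE),
           bn = new_bn(msc)))
  p$bridge <- new_block(bridge_w, bridge_w)
  dec_in <- c(bridge_w, widths[4:2])   # channels entering decoder stage d
  dec_out <- widths[4:1]               # channels after upsampling at stage d
  p$up <- lapply(1:4, function(d) {
    cin <- dec_in[d]; cout <- dec_out[d]
    switch(config$upsample_mode,
      adaptive = {
        # ICNR: tile r^2 identical subkernels per output channel so the
        # initial rearranged output is a smooth (nearest-neighbor-like)
        # upsample rather than checkerboard noise
        w0 <- new_conv(3L, cin, cout, bias = FALSE)$w
        w <- array(0, c(3L, 3L, cin, cout * config$r^2))
        for (co in seq_len(cout))
          for (j in seq_len(config$r^2))
            w[, , , (co - 1L) * config$r^2 + j] <- w0[, , , co]
        list(w = w)
      },
      bilinear = new_conv(3L, cin, cout),
      deconv = new_convt(6L, cin, cout))
  })
  if (config$gating)
    p$gate <- lapply(1:4, function(d) {
      ce <- dec_out[d]
      cout <- if (config$gate_channels == "per_channel") ce else 1L
      new_conv(1L, 2L * ce, cout)
    })
  p$dec <- lapply(1:4, function(d) new_block(2L * dec_out[d], dec_out[d]))
  p$head <- new_conv(1L, widths[1], 1L, gain = 1)
  structure(list(params = p, config = config), class = "gsau_net")
}

#' Count learnable parameters
#'
#' Total number of learnable scalars (convolution kernels and biases,
#' batch-norm scales and shifts; running statistics excluded). Deterministic
#' for a fixed configuration. The upsampling modes order as
#' bilinear < adaptive < deconv at any fixed width: the adaptive expansion
#' convolution is bias-free and the matching k = 6 transposed convolution
#' carries the same weight count plus its biases.
#'
#' @param net a `gsau_net`.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "gsau_net"))
  count_learnable(net$params)
}

#' @export
print.gsau_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<gsau_net> base_width=%d, upsample=%s, gating=%s, ",
                     "multiscale=%s, %s params\n"),
              cfg$base_width, cfg$upsample_mode, cfg$gating,
              cfg$multiscale_input, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# full forward pass over a batch x: (H, W, C_in, N).
# training = TRUE caches intermediates and refreshes bn running stats.
net_forward <- function(net, x, training = FALSE, prec = TRUE) {
  cfg <- net$config
  p <- net$params
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop(sprintf("input spatial size %dx%d is not divisible by 2^depth = 16", d[1], d[2]))
  if (d[3] != cfg$in_channels)
    stop(sprintf("input has %d channels, config expects %d", d[3], cfg$in_channels))
  cache <- if (training) list() else NULL
  keep <- function(slot, val) if (training) cache[[slot]] <<- val

  if (!training) {
    # inference: no caches, bn uses running statistics
    run_block <- function(blk, z) block_f(blk, z, cfg$norm_order, FALSE, prec)$y
    cur <- run_block(p$enc[[1]], x)
    skips <- list(cur)
    for (t in 2:4) {
      cur <- down_f(p$down[[t - 1]], cur, FALSE, prec)$y
      if (cfg$multiscale_input) {
        img <- cpp_bilinear_resize(x, d[1] %/% 2L^(t - 1), d[2] %/% 2L^(t - 1))
        cur <- concat4(cur, ms_f(p$ms[[t - 1]], img, FALSE, prec)$y)
      }
      cur <- run_block(p$enc[[t]], cur)
      skips[[t]] <- cur
    }
    cur <- down_f(p$down[[4]], cur, FALSE, prec)$y
    cur <- run_block(p$bridge, cur)
    for (dd in 1:4) {
      u <- up_f(p$up[[dd]], cur, cfg$upsample_mode, cfg$r, prec)$y
      E <- skips[[5 - dd]]
      m <- if (cfg$gating) gs_f(p$gate[[dd]], E, u, prec)$y else concat4(E, u)
      cur <- run_block(p$dec[[dd]], m)
    }
    logits <- cpp_conv_fwd(cur, p$head$w, p$head$b, 1L, 0L, prec)
    return(list(prob = 1 / (1 + exp(-logits)), logits = logits))
  }

  # training pass
  eb <- list(); skips <- list()
  r1 <- block_f(p$enc[[1]], x, cfg$norm_order, TRUE, prec)
  eb[[1]] <- r1; skips[[1]] <- r1$y
  cur <- r1$y
  dn <- list(); msr <- list()
  for (t in 2:4) {
    dn[[t - 1]] <- down_f(p$down[[t - 1]], cur, TRUE, prec)
    cur <- dn[[t - 1]]$y
    if (cfg$multiscale_input) {
      img <- cpp_bilinear_resize(x, d[1] %/% 2L^(t - 1), d[2] %/% 2L^(t - 1))
      msr[[t - 1]] <- ms_f(p$ms[[t - 1]], img, TRUE, prec)
      cur <- concat4(cur, msr[[t - 1]]$y)
    }
    eb[[t]] <- block_f(p$enc[[t]], cur, cfg$norm_order, TRUE, prec)
    cur <- eb[[t]]$y
    skips[[t]] <- cur
  }
  dn[[4]] <- down_f(p$down[[4]], cur, TRUE, prec)
  br <- block_f(p$bridge, dn[[4]]$y, cfg$norm_order, TRUE, prec)
  cur <- br$y
  ups <- list(); gss <- list(); db <- list()
  for (dd in 1:4) {
    ups[[dd]] <- up_f(p$up[[dd]], cur, cfg$upsample_mode, cfg$r, prec)
    E <- skips[[5 - dd]]
    if (cfg$gating) {
      gss[[dd]] <- gs_f(p$gate[[dd]], E, ups[[dd]]$y, prec)
      m <- gss[[dd]]$y
    } else {
      m <- concat4(E, ups[[dd]]$y)
    }
    db[[dd]] <- block_f(p$dec[[dd]], m, cfg$norm_order, TRUE, prec)
    cur <- db[[dd]]$y
  }
  logits <- cpp_conv_fwd(cur, p$head$w, p$head$b, 1L, 0L, prec)
  prob <- 1 / (1 + exp(-logits))

  # refresh batch-norm running statistics
  upd_bn <- function(bn, newstats) { bn$rmean <- newstats$rmean; bn$rvar <- newstats$rvar; bn }
  for (t in 1:4) {
    p$enc[[t]]$bn1 <- upd_bn(p$enc[[t]]$bn1, eb[[t]]$bn1)
    p$enc[[t]]$bn2 <- upd_bn(p$enc[[t]]$bn2, eb[[t]]$bn2)
    p$down[[t]]$bn <- upd_bn(p$down[[t]]$bn, dn[[t]]$bn)
    p$dec[[t]]$bn1 <- upd_bn(p$dec[[t]]$bn1, db[[t]]$bn1)
    p$dec[[t]]$bn2 <- upd_bn(p$dec[[t]]$bn2, db[[t]]$bn2)
    if (cfg$multiscale_input && t < 4)
      p$ms[[t]]$bn <- upd_bn(p$ms[[t]]$bn, msr[[t]]$bn)
  }
  p$bridge$bn1 <- upd_bn(p$bridge$bn1, br$bn1)
  p$bridge$bn2 <- upd_bn(p$bridge$bn2, br$bn2)

  list(prob = prob, logits = logits, params = p,
       cache = list(eb = eb, dn = dn, msr = msr, br = br,
                    ups = ups, gss = gss, db = db, dec_in = cur))
}

# backward pass; dlogits has the head-output shape (H, W, 1, N).
# Returns a gradient tree matching the learnable entries of net$params.
net_backward <- function(net, fw, dlogits, prec = TRUE) {
  cfg <- net$config
  p <- net$params
  ca <- fw$cache
  g <- list()
  hv <- cpp_conv_bwd(ca$dec_in, p$head$w, dlogits, 1L, 0L, TRUE, prec)
  g$head <- list(w = hv$dw, b = hv$db)
  dcur <- hv$dx
  g$dec <- vector("list", 4L); g$up <- vector("list", 4L)
  if (cfg$gating) g$gate <- vector("list", 4L)
  dskip <- vector("list", 4L)   # gradient flowing into encoder skip t
  for (dd in 4:1) {
    bb <- block_b(p$dec[[dd]], ca$db[[dd]]$cache, dcur, cfg$norm_order, prec)
    g$dec[[dd]] <- bb$g
    dm <- bb$dx
    E <- if (cfg$gating) ca$gss[[dd]]$cache$E else NULL
    ce <- dim(ca$ups[[dd]]$y)[3]
    if (cfg$gating) {
      gb <- gs_b(p$gate[[dd]], ca$gss[[dd]]$cache, dm, prec)
      g$gate[[dd]] <- gb$g
      dE <- gb$dE; dU <- gb$dD
    } else {
      sp <- cpp_split_c(dm, ce)
      dE <- sp$first
      dU <- sp$second
    }
    dskip[[5 - dd]] <- dE
    ub <- up_b(p$up[[dd]], ca$ups[[dd]]$cache, dU, cfg$upsample_mode, cfg$r, prec)
    g$up[[dd]] <- ub$g
    dcur <- ub$dx
  }
  brb <- block_b(p$bridge, ca$br$cache, dcur, cfg$norm_order, prec)
  g$bridge <- brb$g
  d4 <- down_b(p$down[[4]], ca$dn[[4]]$cache, brb$dx, prec)
  g$down <- vector("list", 4L)
  g$down[[4]] <- d4$g
  g$enc <- vector("list", 4L)
  if (cfg$multiscale_input) g$ms <- vector("list", 3L)
  dcur <- d4$dx + dskip[[4]]
  for (t in 4:2) {
    ebk <- block_b(p$enc[[t]], ca$eb[[t]]$cache, dcur, cfg$norm_order, prec)
    g$enc[[t]] <- ebk$g
    dstage <- ebk$dx
    cdown <- dim(ca$dn[[t - 1]]$y)[3]
    if (cfg$multiscale_input) {
      sp <- cpp_split_c(dstage, cdown)
      ddown <- sp$first
      g$ms[[t - 1]] <- ms_b(p$ms[[t - 1]], ca$msr[[t - 1]]$cache, sp$second, prec)$g
    } else {
      ddown <- dstage
    }
    db_ <- down_b(p$down[[t - 1]], ca$dn[[t - 1]]$cache, ddown, prec)
    g$down[[t - 1]] <- db_$g
    dcur <- db_$dx + dskip[[t - 1]]
  }
  e1 <- block_b(p$enc[[1]], ca$eb[[1]]$cache, dcur, cfg$norm_order, prec, need_dx = FALSE)
  g$enc[[1]] <- e1$g
  g
}

#' Segment an image
#'
#' Runs the network in inference mode. Images whose sides are divisible by
#' 16 are processed in a single forward pass; otherwise (or when `tiles` is
#' given) overlapping tiles are predicted and averaged via
#' [tile_and_stitch()].
#'
#' @param object a trained `gsau_net`.
#' @param image numeric (H, W) matrix in `[0, 1]` (or (H, W, C) array
#'   matching the configured input channels).
#' @param tiles optional [tile_spec()]; defaults to 48/24 tiling when the
#'   image size requires it.
#' @param ... unused.
#' @return matrix of vessel probabilities in `[0, 1]`, same size as the input.
#' @export
predict.gsau_net <- function(object, image, tiles = NULL, ...) {
  x <- as_hwc(image, "image")
  d <- dim(x)
  if (is.null(tiles) && d[1] %% 16L == 0L && d[2] %% 16L == 0L &&
      d[1] >= 16L && d[2] >= 16L) {
    out <- net_forward(object, add_batch(x), training = FALSE)
    return(matrix(out$prob, d[1], d[2]))
  }
  tiles <- tiles %||% tile_spec(48L, 24L)
  tile_and_stitch(if (d[3] == 1L) x[, , 1] else x, NULL, object, tiles)
}

#' Save / load a network checkpoint
#'
#' The parameter tree is written with [saveRDS()]; the architecture
#' configuration is serialized alongside as YAML (`<path>.yaml`) so a
#' checkpoint is self-describing.
#'
#' @param net a `gsau_net`.
#' @param path checkpoint file path (e.g. `"run/model.rds"`).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   `gsau_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "gsau_net"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(net$params, path)
  cfg <- net$config
  yaml::write_yaml(unclass(cfg), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfgl <- yaml::read_yaml(paste0(path, ".yaml"))
  cfg <- gsau_config(in_channels = cfgl$in_channels, base_width = cfgl$base_width,
                     upsample_mode = cfgl$upsample_mode, gating = cfgl$gating,
                     r = cfgl$r, multiscale_input = cfgl$multiscale_input,
                     gate_channels = cfgl$gate_channels, norm_order = cfgl$norm_order)
  structure(list(params = readRDS(path), config = cfg), class = "gsau_net")
}
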