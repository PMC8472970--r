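#' Gate parameters for a gated skip-connection
#'
#' The gate is a 1x1 convolution over the channel-wise concatenation of the
#' encoder feature E and the decoder feature D, followed by a sigmoid. Its
#' weight therefore has `in_channels = channels(E) + channels(D)` input
#' channels; by default it emits one gate channel per encoder channel so the
#' elementwise product with E is well defined without broadcasting.
#'
#' @param weight numeric array of shape (out_channels, in_channels, 1, 1) or
#'   an (out_channels x in_channels) matrix.
#' @param bias numeric vector of length out_channels.
#' @return an object of class `gate_params`.
#' @seealso [gated_skip()], [init_gate_params()]
#' @export
gate_params <- function(weight, bias) {
  if (is.matrix(weight)) dim(weight) <- c(dim(weight), 1L, 1L)
  if (!is.array(weight) || length(dim(weight)) != 4L || any(dim(weight)[3:4] != 1L))
    stop("weight must have shape (out_channels, in_channels, 1, 1)")
  d <- dim(weight)
  if (length(bias) != d[1])
    stop(sprintf("bias length %d does not match out_channels %d", length(bias), d[1]))
  # internal conv layout is (kh, kw, in, out)
  w <- array(0, c(1L, 1L, d[2], d[1]))
  w[1, 1, , ] <- t(weight[, , 1, 1, drop = TRUE])
  structure(list(w = w, b = as.numeric(bias),
                 in_channels = d[2], out_channels = d[1]),
            class = "gate_params")
}

#' Randomly initialized gate parameters
#'
#' @param channels_e,channels_d channel counts of the encoder and decoder
#'   features to be gated.
#' @param mode `"per_channel"` (one gate channel per encoder channel, the
#'   default) or `"single"` (one broadcast gate channel).
#' @return a `gate_params` object.
#' @export
init_gate_params <- function(channels_e, channels_d, mode = c("per_channel", "single")) {
  mode <- match.arg(mode)
  cin <- channels_e + channels_d
  cout <- if (mode == "per_channel") channels_e else 1L
  w <- matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
  gate_params(w, rep(0, cout))
}

#' Gated skip-connection
#'
#' Computes the attention map `alpha = sigmoid(conv1x1(concat(E, D)))`, gates
#' the encoder feature `C = E * alpha`, adds the ungated encoder feature back
#' (the skip), and concatenates with the decoder feature:
#' `Y = concat(C + E, D)`. The output therefore has
#' `channels(E) + channels(D)` channels at the shared spatial size, and every
#' entry of `alpha` lies strictly in (0, 1).
#'
#' @param E encoder feature map, (H, W, C_E) array.
#' @param D decoder feature map, (H, W, C_D) array with the same H, W.
#' @param params a [gate_params()] object with
#'   `in_channels = C_E + C_D` and `out_channels = C_E` (or 1).
#' @param return_alpha also return the attention map.
#' @return the gated feature map, or (with `return_alpha`) a list
#'   `list(y, alpha)`.
#' @export
gated_skip <- function(E, D, params, return_alpha = FALSE) {
  E <- as_hwc(E, "E"); D <- as_hwc(D, "D")
  if (!identical(dim(E)[1:2], dim(D)[1:2]))
    stop(sprintf("spatial sizes differ: E is %s, D is %s", fmt_shape(E), fmt_shape(D)))
  if (!inherits(params, "gate_params")) stop("params must be a gate_params object")
  ce <- dim(E)[3]; cd <- dim(D)[3]
  if (params$in_channels != ce + cd)
    stop(sprintf("gate expects %d input channels but E + D have %d + %d = %d",
                 params$in_channels, ce, cd, ce + cd))
  if (!params$out_channels %in% c(ce, 1L))
    stop(sprintf("gate emits %d channels; expected %d (per-channel) or 1 (broadcast)",
                 params$out_channels, ce))
  A <- add_batch(abind3(E, D))
  z <- cpp_conv_fwd(A, params$w, params$b, 1L, 0L, FALSE)
  alpha <- drop_batch(1 / (1 + exp(-z)))
  Cg <- if (params$out_channels == 1L) E * as.vector(alpha) else E * alpha
  y <- abind3(Cg + E, D)
  if (return_alpha) list(y = y, alpha = alpha) else y
}

# channel-wise concatenation of (H,W,C) arrays
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(unlist(xs, use.names = FALSE),
               c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 1))))
  out
}

#' Upsampling specification
#'
#' @param mode one of `"adaptive"` (learned channel expansion + periodic
#'   rearrangement), `"bilinear"`, `"deconv"` (transposed convolution).
#' @param r subwindow/upscaling factor (default 2).
#' @param out_channels channels after upsampling.
#' @export
upsample_spec <- function(mode = c("adaptive", "bilinear", "deconv"),
                          r = 2L, out_channels = NULL) {
  mode <- match.arg(mode)
  r <- as.integer(r)
  if (r < 1L) stop("r must be a positive integer")
  structure(list(mode = mode, r = r, out_channels = out_channels),
            class = "upsample_spec")
}

#' Periodic rearrangement (depth-to-space, sub-pixel shuffle)
#'
#' Rearranges r x r groups of channels into an r-times-larger spatial grid:
#' `out[y, x, c] = in[y %/% r, x %/% r, c*r^2 + (y %% r)*r + (x %% r)]`
#' (0-based, row-major periodic layout). The operation is parameter-free,
#' moves values without arithmetic, and is exactly inverted by
#' [pixel_unshuffle()].
#'
#' @param x (H, W, C) or (H, W, C, N) array with C divisible by `r^2`.
#' @param r subwindow factor.
#' @return array of shape (r*H, r*W, C/r^2) (batch dimension preserved).
#' @export
pixel_shuffle <- function(x, r) {
  batched <- is.array(x) && length(dim(x)) == 4L
  if (!batched) x <- add_batch(as_hwc(x))
  y <- cpp_pixel_shuffle(x, as.integer(r))
  if (batched) y else drop_batch(y)
}

#' @rdname pixel_shuffle
#' @export
pixel_unshuffle <- function(x, r) {
  batched <- is.array(x) && length(dim(x)) == 4L
  if (!batched) x <- add_batch(as_hwc(x))
  y <- cpp_pixel_unshuffle(x, as.integer(r))
  if (batched) y else drop_batch(y)
}

#' Adaptive upsampling
#'
#' A convolution expands the channel count to `out_channels * r^2`; the
#' periodic rearrangement of [pixel_shuffle()] then trades those channel
#' groups for an r-times-larger spatial grid. All learnable parameters live
#' in the convolution; the rearrangement itself is parameter-free and
#' exactly invertible.
#'
#' @param x input feature map, (H, W, C) array.
#' @param spec an [upsample_spec()] with `mode = "adaptive"`.
#' @param conv_params list with element `w`, a (k, k, C, out_channels * r^2)
#'   kernel (bias-free by convention).
#' @return (r*H, r*W, out_channels) array.
#' @export
adaptive_upsample <- function(x, spec, conv_params) {
  x <- as_hwc(x)
  if (!inherits(spec, "upsample_spec") || spec$mode != "adaptive")
    stop("spec must be an upsample_spec with mode = \"adaptive\"")
  w <- conv_params$w
  if (!is.array(w) || length(dim(w)) != 4L)
    stop("conv_params$w must be a (k, k, in, out) kernel array")
  r <- spec$r
  if (dim(w)[4] %% (r * r) != 0L)
    stop(sprintf("expansion emits %d channels, not divisible by r^2 = %d",
                 dim(w)[4], r * r))
  if (!is.null(spec$out_channels) && dim(w)[4] != spec$out_channels * r * r)
    stop(sprintf("expansion emits %d channels but spec requires out_channels * r^2 = %d",
                 dim(w)[4], spec$out_channels * r * r))
  pad <- (dim(w)[1] - 1L) %/% 2L
  mid <- cpp_conv_fwd(add_batch(x), w, conv_params$b, 1L, pad, FALSE)
  drop_batch(cpp_pixel_shuffle(mid, r))
}

#' Bilinear resampling
#'
#' Each output pixel is the convex combination of its four nearest source
#' pixels, with weights summing to one. Sampling is corner-aligned: the
#' first and last output pixels coincide with the first and last source
#' pixels along each axis, so resizing to the input size is the identity.
#'
#' @param x (H, W) matrix or (H, W, C) array.
#' @param out_height,out_width target size in pixels (positive).
#' @return resized map with the input's channel layout.
#' @export
bilinear_resize <- function(x, out_height, out_width) {
  was_mat <- is.matrix(x)
  x <- as_hwc(x)
  if (out_height < 1 || out_width < 1)
    stop(sprintf("target size must be positive, got %d x %d", out_height, out_width))
  y <- drop_batch(cpp_bilinear_resize(add_batch(x),
                                      as.integer(out_height), as.integer(out_width)))
  if (was_mat) y[, , 1] else y
}

#' Transposed-convolution output size
#'
#' For input size i, kernel k, stride s and zero padding p, a transposed
#' convolution produces `o = s*(i - 1) - 2*p + k`, plus a remainder term
#' `rem` (the output padding, `0 <= rem < s`) when the matching forward
#' convolution did not tile the input exactly. With k = 6, s = 2, p = 2
#' (the decoder configuration) this doubles the spatial size.
#'
#' @param i input size (>= 1); vectorized.
#' @param k kernel size (>= 1).
#' @param s stride (>= 1).
#' @param p zero padding (>= 0).
#' @param rem remainder/output padding, `0 <= rem < s`.
#' @return integer output size(s).
#' @export
deconv_output_size <- function(i, k, s, p = 0L, rem = 0L) {
  if (any(i < 1) || any(k < 1) || any(s < 1) || any(p < 0))
    stop("require i, k, s >= 1 and p >= 0")
  if (any(rem < 0) || any(rem >= s))
    stop(sprintf("remainder must satisfy 0 <= rem < s (got rem = %s, s = %s)",
                 paste(rem, collapse = ","), paste(s, collapse = ",")))
  as.integer(s * (i - 1) - 2 * p + k + rem)
}

#' Convolution block parameters
#'
#' Two 3x3 convolutions (spatial size preserved by unit padding), each
#' optionally followed by batch normalization; a single ReLU closes the
#' block. `norm = NULL` disables normalization for that convolution.
#'
#' @param w1,w2 (3, 3, in, out) kernel arrays.
#' @param b1,b2 bias vectors (or NULL).
#' @param bn1,bn2 lists with `gamma`, `beta`, `rmean`, `rvar`, or NULL.
#' @export
conv_block_params <- function(w1, b1 = NULL, w2, b2 = NULL, bn1 = NULL, bn2 = NULL) {
  for (w in list(w1, w2))
    if (!is.array(w) || length(dim(w)) != 4L || dim(w)[1] != dim(w)[2])
      stop("kernels must be (k, k, in, out) arrays")
  if (dim(w1)[4] != dim(w2)[3])
    stop(sprintf("second kernel expects %d input channels but first emits %d",
                 dim(w2)[3], dim(w1)[4]))
  structure(list(conv1 = list(w = w1, b = b1), bn1 = bn1,
                 conv2 = list(w = w2, b = b2), bn2 = bn2),
            class = "conv_block_params")
}

#' Shared convolution block
#'
#' Applies conv -> norm -> conv -> norm -> ReLU (the block's single closing
#' activation); with `norm_order = "conventional"` a ReLU also follows the
#' first normalization. Normalization uses the provided running statistics
#' (inference form); during network training the engine uses batch
#' statistics instead.
#'
#' @param x (H, W, C) feature map.
#' @param params a [conv_block_params()] object.
#' @param norm_order `"deferred"` (default: the single ReLU closes the
#'   block) or `"conventional"` (a ReLU after each normalization).
#' @return feature map with the block's output channels, same spatial size.
#' @export
conv_block <- function(x, params, norm_order = c("deferred", "conventional")) {
  norm_order <- match.arg(norm_order)
  x <- as_hwc(x)
  if (dim(x)[3] != dim(params$conv1$w)[3])
    stop(sprintf("input has %d channels but block expects %d",
                 dim(x)[3], dim(params$conv1$w)[3]))
  pad <- (dim(params$conv1$w)[1] - 1L) %/% 2L
  y <- cpp_conv_fwd(add_batch(x), params$conv1$w, params$conv1$b, 1L, pad, FALSE)
  if (!is.null(params$bn1))
    y <- cpp_bn_infer(y, params$bn1$gamma, params$bn1$beta,
                      params$bn1$rmean, params$bn1$rvar, 1e-5)
  if (norm_order == "conventional") y[y < 0] <- 0
  y <- cpp_conv_fwd(y, params$conv2$w, params$conv2$b, 1L, pad, FALSE)
  if (!is.null(params$bn2))
    y <- cpp_bn_infer(y, params$bn2$gamma, params$bn2$beta,
                      params$bn2$rmean, params$bn2$rvar, 1e-5)
  y[y < 0] <- 0
  drop_batch(y)
}
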