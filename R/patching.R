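#' Random-patch sampling specification
#'
#' The training protocol draws many small square patches at uniformly
#' random positions from each training image (48 x 48 pixels and 10,480
#' patches per image by default). With `inside_fov` the patch centers are
#' restricted to the field of view.
#'
#' @param size patch side length in pixels (>= 8).
#' @param per_image number of patches drawn per image (>= 1).
#' @param inside_fov restrict patch centers to FOV pixels.
#' @param seed integer seed; the same seed reproduces the same patch set.
#' @export
patch_spec <- function(size = 48L, per_image = 10480L, inside_fov = TRUE, seed = 1L) {
  size <- as.integer(size); per_image <- as.integer(per_image)
  if (size < 8L) stop("patch size must be at least 8 pixels")
  if (per_image < 1L) stop("per_image must be at least 1")
  structure(list(size = size, per_image = per_image,
                 inside_fov = isTRUE(inside_fov), seed = as.integer(seed)),
            class = "patch_spec")
}

#' Sample random training patches from one image
#'
#' Draws exactly `spec$per_image` patch pairs whose centers are uniform
#' (with replacement) over the valid positions -- positions where the full
#' patch fits inside the image and, when `inside_fov`, whose center pixel
#' lies in the FOV. Deterministic for a fixed `spec$seed`; the caller's
#' RNG state is preserved.
#'
#' @param image (H, W) numeric matrix.
#' @param label (H, W) 0/1 matrix (vessel ground truth).
#' @param mask (H, W) 0/1 FOV matrix (may be NULL when `inside_fov` is
#'   FALSE).
#' @param spec a [patch_spec()].
#' @return a `patch_set`: list with `images` (size, size, 1, n) array,
#'   `labels` (size, size, n) array, and `centers` (n x 2 matrix of
#'   row/col patch centers).
#' @export
sample_patches <- function(image, label, mask = NULL, spec = patch_spec()) {
  stopifnot(inherits(spec, "patch_spec"))
  H <- nrow(image); W <- ncol(image); sz <- spec$size
  if (H < sz || W < sz)
    stop(sprintf("image (%d x %d) is smaller than the patch size (%d x %d)",
                 H, W, sz, sz))
  if (!identical(dim(image), dim(label)))
    stop(sprintf("image is %dx%d but label is %s", H, W, fmt_shape(label)))
  off <- sz %/% 2L                      # center offset from patch top-left
  tops <- seq_len(H - sz + 1L)
  lefts <- seq_len(W - sz + 1L)
  valid <- expand.grid(top = tops, left = lefts)
  if (spec$inside_fov) {
    if (is.null(mask)) stop("inside_fov = TRUE requires a mask")
    keep <- mask[cbind(valid$top + off - 1L, valid$left + off - 1L)] == 1L
    valid <- valid[keep, , drop = FALSE]
    if (!nrow(valid)) stop("no valid patch centers inside the FOV")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  pick <- valid[sample.int(nrow(valid), spec$per_image, replace = TRUE), ]

  n <- spec$per_image
  imgs <- array(0, c(sz, sz, 1L, n))
  labs <- array(0L, c(sz, sz, n))
  for (i in seq_len(n)) {
    rr <- pick$top[i]:(pick$top[i] + sz - 1L)
    cc <- pick$left[i]:(pick$left[i] + sz - 1L)
    imgs[, , 1L, i] <- image[rr, cc]
    labs[, , i] <- label[rr, cc]
  }
  structure(list(images = imgs, labels = labs,
                 centers = cbind(row = pick$top + off - 1L,
                                 col = pick$left + off - 1L)),
            class = "patch_set")
}

#' Tiling specification for full-image inference
#'
#' @param size tile side length (pixels).
#' @param stride step between tile origins, `1 <= stride <= size`.
#' @export
tile_spec <- function(size = 48L, stride = 24L) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (stride < 1L || stride > size)
    stop(sprintf("stride must satisfy 1 <= stride <= size, got %d / %d", stride, size))
  structure(list(size = size, stride = stride), class = "tile_spec")
}

tile_origins <- function(n, size, stride) {
  o <- seq(1L, max(n - size + 1L, 1L), by = stride)
  last <- n - size + 1L
  if (o[length(o)] != last) o <- c(o, last)
  o
}

reflect_pad <- function(m, target_h, target_w) {
  H <- nrow(m); W <- ncol(m)
  if (H < target_h) {
    extra <- target_h - H
    m <- rbind(m, m[H - seq_len(extra), , drop = FALSE])
  }
  if (W < target_w) {
    extra <- target_w - W
    m <- cbind(m, m[, W - seq_len(extra), drop = FALSE])
  }
  m
}

#' Predict a full image from a patch-trained network by tiling
#'
#' Overlapping tiles are predicted and averaged per pixel by overlap
#' count; images smaller than one tile are reflect-padded and cropped
#' back. The per-pixel averaging weights sum to one everywhere, so a
#' constant-output network yields a constant prediction.
#'
#' @param image (H, W) numeric matrix.
#' @param mask optional FOV matrix (carried through for API symmetry; all
#'   tiles are predicted).
#' @param net a `gsau_net`, or any function mapping a (size x size) matrix
#'   to a (size x size) matrix of scores (useful for stubs and oracles).
#' @param tiles a [tile_spec()].
#' @return (H, W) matrix of averaged predictions.
#' @export
tile_and_stitch <- function(image, mask = NULL, net, tiles = tile_spec()) {
  stopifnot(inherits(tiles, "tile_spec"))
  H <- nrow(image); W <- ncol(image); sz <- tiles$size
  padded <- reflect_pad(image, sz, sz)
  Hp <- nrow(padded); Wp <- ncol(padded)
  oy <- tile_origins(Hp, sz, tiles$stride)
  ox <- tile_origins(Wp, sz, tiles$stride)
  acc <- matrix(0, Hp, Wp)
  cnt <- matrix(0, Hp, Wp)
  grid <- expand.grid(y = oy, x = ox)
  if (inherits(net, "gsau_net")) {
    bs <- 64L
    for (start in seq(1L, nrow(grid), by = bs)) {
      sel <- start:min(start + bs - 1L, nrow(grid))
      xb <- array(0, c(sz, sz, 1L, length(sel)))
      for (k in seq_along(sel)) {
        gy <- grid$y[sel[k]]; gx <- grid$x[sel[k]]
        xb[, , 1L, k] <- padded[gy:(gy + sz - 1L), gx:(gx + sz - 1L)]
      }
      pb <- net_forward(net, xb, training = FALSE)$prob
      for (k in seq_along(sel)) {
        gy <- grid$y[sel[k]]; gx <- grid$x[sel[k]]
        acc[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] <-
          acc[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] + pb[, , 1L, k]
        cnt[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] <-
          cnt[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] + 1
      }
    }
  } else if (is.function(net)) {
    for (k in seq_len(nrow(grid))) {
      gy <- grid$y[k]; gx <- grid$x[k]
      tile <- padded[gy:(gy + sz - 1L), gx:(gx + sz - 1L)]
      acc[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] <-
        acc[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] + net(tile)
      cnt[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] <-
        cnt[gy:(gy + sz - 1L), gx:(gx + sz - 1L)] + 1
    }
  } else stop("net must be a gsau_net or a function")
  (acc / cnt)[seq_len(H), seq_len(W)]
}
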