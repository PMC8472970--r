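#' Write phantoms to a DRIVE-style directory layout
#'
#' Creates `images/`, `1st_manual/` (ground truth) and `mask/` (FOV)
#' subdirectories and writes each phantom as 8-bit grayscale PNG files with
#' a shared basename, mirroring the layout of the public retinal-vessel
#' datasets.
#'
#' @param phantoms list of `phantom` objects (see [generate_phantom()]).
#' @param root output directory (created if needed).
#' @param prefix file basename prefix.
#' @return the root path, invisibly.
#' @export
write_dataset <- function(phantoms, root, prefix = "sample") {
  for (d in c("images", "1st_manual", "mask"))
    dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    nm <- sprintf("%s_%03d.png", prefix, i)
    png::writePNG(ph$image, file.path(root, "images", nm))
    png::writePNG(ph$vessels + 0, file.path(root, "1st_manual", nm))
    png::writePNG(ph$fov + 0, file.path(root, "mask", nm))
  }
  invisible(root)
}

read_png_gray <- function(path, channel = c("green", "gray", "rgb")) {
  channel <- match.arg(channel)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) return(x)
  if (channel == "rgb") return(x[, , 1:3])
  if (dim(x)[3] >= 3L) {
    if (channel == "green") x[, , 2] else
      0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else x[, , 1]
}

# largest connected component of a binary matrix, 4-connectivity,
# via column-run merging with union-find
largest_component <- function(b) {
  H <- nrow(b); W <- ncol(b)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  runs <- vector("list", W)   # per column: matrix (start, end, id)
  for (j in seq_len(W)) {
    col <- b[, j]
    if (!any(col)) { runs[[j]] <- matrix(0L, 0, 3); next }
    d <- diff(c(0L, col, 0L))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    ids <- integer(length(st))
    for (k in seq_along(st)) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      ids[k] <- length(parent)
    }
    runs[[j]] <- cbind(st, en, ids)
    if (j > 1L && nrow(runs[[j - 1]])) {
      prev <- runs[[j - 1]]
      for (k in seq_along(st))
        for (m in seq_len(nrow(prev)))
          if (st[k] <= prev[m, 2] && en[k] >= prev[m, 1]) {
            a <- find(ids[k]); bb <- find(prev[m, 3])
            if (a != bb) parent[a] <- bb
          }
    }
  }
  sizes <- numeric(length(parent))
  for (j in seq_len(W)) {
    r <- runs[[j]]
    for (k in seq_len(nrow(r))) {
      root <- find(r[k, 3])
      sizes[root] <- sizes[root] + (r[k, 2] - r[k, 1] + 1L)
    }
  }
  if (!length(sizes) || max(sizes) == 0) return(matrix(0L, H, W))
  best <- which.max(sizes)
  out <- matrix(0L, H, W)
  for (j in seq_len(W)) {
    r <- runs[[j]]
    for (k in seq_len(nrow(r)))
      if (find(r[k, 3]) == best) out[r[k, 1]:r[k, 2], j] <- 1L
  }
  out
}

#' Estimate a field-of-view mask from image luminance
#'
#' For datasets shipped without FOV masks (STARE-style), thresholds the
#' luminance at a fraction of its maximum and keeps the largest connected
#' component.
#'
#' @param image (H, W) numeric matrix in `[0, 1]`.
#' @param threshold luminance threshold relative to the image maximum.
#' @return (H, W) 0/1 integer matrix.
#' @export
estimate_fov <- function(image, threshold = 0.2) {
  largest_component(image > threshold * max(image))
}

#' Load a fundus segmentation dataset
#'
#' Scans a DRIVE/CHASE/STARE-style directory tree and returns one record
#' per sample with validated, size-consistent image / ground-truth / mask
#' files. The `drive`, `chase` and `synthetic` layouts expect `images/`,
#' `1st_manual/` and `mask/` subdirectories (PNG files, paired by sorted
#' order); the `stare` layout accepts `labels/` as the ground-truth
#' directory and tolerates a missing `mask/`, in which case the FOV is
#' estimated from luminance at load time ([estimate_fov()]) and the record
#' is flagged.
#'
#' @param root dataset directory.
#' @param layout one of `"synthetic"`, `"drive"`, `"chase"`, `"stare"`.
#' @return a data.frame with columns `id`, `image_path`, `label_path`,
#'   `mask_path` (`NA` when the FOV must be estimated), `fov_estimated`,
#'   `height`, `width`.
#' @export
load_dataset <- function(root, layout = c("synthetic", "drive", "chase", "stare")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop(sprintf("dataset root does not exist: %s", root))
  label_dir <- if (layout == "stare" && dir.exists(file.path(root, "labels")))
    "labels" else "1st_manual"
  imgs <- sort(list.files(file.path(root, "images"), full.names = TRUE,
                          pattern = "\\.png$", ignore.case = TRUE))
  labs <- sort(list.files(file.path(root, label_dir), full.names = TRUE,
                          pattern = "\\.png$", ignore.case = TRUE))
  msks <- sort(list.files(file.path(root, "mask"), full.names = TRUE,
                          pattern = "\\.png$", ignore.case = TRUE))
  if (!length(imgs)) {
    warning(sprintf("no images found under %s", file.path(root, "images")))
    return(data.frame(id = character(), image_path = character(),
                      label_path = character(), mask_path = character(),
                      fov_estimated = logical(), height = integer(),
                      width = integer(), stringsAsFactors = FALSE))
  }
  if (length(labs) != length(imgs))
    stop(sprintf("found %d images but %d ground-truth files",
                 length(imgs), length(labs)))
  has_mask <- length(msks) == length(imgs)
  if (!has_mask && layout != "stare")
    stop(sprintf("found %d images but %d mask files", length(imgs), length(msks)))
  rec <- data.frame(
    id = sub("\\.png$", "", basename(imgs), ignore.case = TRUE),
    image_path = imgs, label_path = labs,
    mask_path = if (has_mask) msks else NA_character_,
    fov_estimated = !has_mask, stringsAsFactors = FALSE)
  sizes <- t(vapply(seq_len(nrow(rec)), function(i) {
    img <- tryCatch(read_png_gray(rec$image_path[i]),
                    error = function(e) stop(sprintf("cannot decode %s: %s",
                                                     rec$image_path[i], conditionMessage(e))))
    lab <- read_png_gray(rec$label_path[i], "gray")
    if (!identical(dim(img)[1:2], dim(lab)[1:2]))
      stop(sprintf("sample %s: image is %s but ground truth is %s",
                   rec$id[i], fmt_shape(img), fmt_shape(lab)))
    if (has_mask) {
      msk <- read_png_gray(rec$mask_path[i], "gray")
      if (!identical(dim(img)[1:2], dim(msk)[1:2]))
        stop(sprintf("sample %s: image is %s but mask is %s",
                     rec$id[i], fmt_shape(img), fmt_shape(msk)))
    }
    dim(img)[1:2]
  }, integer(2)))
  rec$height <- sizes[, 1]
  rec$width <- sizes[, 2]
  rec
}

#' Read one sample into memory
#'
#' @param record one row of the data.frame returned by [load_dataset()].
#' @param channel channel mode for RGB images: `"green"` (fundus
#'   convention), `"gray"`, or `"rgb"`.
#' @return list with `image` (numeric in `[0, 1]`), `label` and `fov`
#'   (0/1 integer matrices; 8-bit labels are binarized at the 127.5
#'   midpoint).
#' @export
load_sample <- function(record, channel = "green") {
  img <- read_png_gray(record$image_path, channel)
  lab <- read_png_gray(record$label_path, "gray")
  fov <- if (is.na(record$mask_path)) {
    estimate_fov(if (is.matrix(img)) img else img[, , 1])
  } else {
    m <- read_png_gray(record$mask_path, "gray")
    matrix(as.integer(m > 127.5 / 255), nrow(m), ncol(m))
  }
  list(image = img,
       label = matrix(as.integer(lab > 127.5 / 255), nrow(lab), ncol(lab)),
       fov = fov)
}

#' Train/test split plans
#'
#' @param scheme `"fixed_halves"` (first half train, second half test, the
#'   40-image DRIVE protocol), `"first20_rest8"` (the 28-image CHASE
#'   protocol), or `"leave_one_out"` (the STARE protocol: the `fold`-th
#'   sample is the test set).
#' @param fold 1-based test fold for leave-one-out.
#' @export
split_plan <- function(scheme = c("fixed_halves", "first20_rest8", "leave_one_out"),
                       fold = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, fold = as.integer(fold)), class = "split_plan")
}

#' Partition dataset records into train and test sets
#'
#' All schemes are deterministic (no randomness) and produce disjoint,
#' exhaustive partitions of the records.
#'
#' @param records data.frame from [load_dataset()].
#' @param plan a [split_plan()].
#' @return list with `train` and `test` data.frames.
#' @export
make_split <- function(records, plan) {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(records)
  idx <- switch(plan$scheme,
    fixed_halves = {
      k <- n %/% 2L
      list(train = seq_len(k), test = setdiff(seq_len(n), seq_len(k)))
    },
    first20_rest8 = {
      if (n < 21L) stop(sprintf("first20_rest8 needs more than 20 records, got %d", n))
      list(train = 1:20, test = 21:n)
    },
    leave_one_out = {
      if (plan$fold < 1L || plan$fold > n)
        stop(sprintf("fold %d out of range for %d records", plan$fold, n))
      list(train = setdiff(seq_len(n), plan$fold), test = plan$fold)
    })
  list(train = records[idx$train, , drop = FALSE],
       test = records[idx$test, , drop = FALSE])
}
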