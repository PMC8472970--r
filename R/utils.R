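`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_shape <- function(x) paste(dim(x) %||% length(x), collapse = "x")

#' @noRd
as_hwc <- function(x, what = "x") {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a (height, width, channels) array, got shape %s",
                 what, fmt_shape(x)), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite entries", what), call. = FALSE)
  x
}

# lift (H,W,C) to the engine's (H,W,C,N=1) layout
add_batch <- function(x) { dim(x) <- c(dim(x), 1L); x }
drop_batch <- function(x) { d <- dim(x); dim(x) <- d[1:3]; x }

#' Construct a feature map
#'
#' A feature map is a stack of real-valued channel planes, stored as a
#' numeric array with dimensions (height, width, channels). Matrices are
#' promoted to single-channel maps. All entries must be finite.
#'
#' @param values numeric matrix or 3-d array.
#' @return a numeric (height, width, channels) array.
#' @export
feature_map <- function(values) as_hwc(values, "values")

# deterministic child seeds; kept below .Machine$integer.max
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2011 + as.numeric(i) * 7919) %% 2147483629)
}
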