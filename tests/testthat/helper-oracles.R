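# Independent scalar-loop oracles used to check the vectorized operators.

# direct (triple-loop) 2-d convolution on a single (H, W, C) map
ref_conv3 <- function(x, w, b = NULL, stride = 1, pad = 0) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
    acc <- if (is.null(b)) 0 else b[co]
    for (c in seq_len(cin))
      acc <- acc + sum(xp[(i - 1) * stride + seq_len(k),
                          (j - 1) * stride + seq_len(k), c] * w[, , c, co])
    y[i, j, co] <- acc
  }
  y
}

# per-pixel evaluation of the gated skip-connection:
# alpha = sigmoid(conv1x1(concat(E, D))), Y = concat(E * alpha + E, D)
ref_gated_skip <- function(E, D, weight, bias) {
  ce <- dim(E)[3]; cd <- dim(D)[3]
  H <- dim(E)[1]; W <- dim(E)[2]
  co <- nrow(weight)
  out <- array(0, c(H, W, ce + cd))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- c(E[i, j, ], D[i, j, ])
    alpha <- 1 / (1 + exp(-(weight %*% v + bias)))
    a_full <- if (co == 1) rep(alpha, ce) else as.numeric(alpha)
    out[i, j, seq_len(ce)] <- E[i, j, ] * a_full + E[i, j, ]
    out[i, j, ce + seq_len(cd)] <- D[i, j, ]
  }
  out
}

# corner-aligned four-neighbor bilinear interpolation, scalar form
ref_bilinear <- function(x, oh, ow) {
  H <- nrow(x); W <- ncol(x)
  y <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- if (oh == 1 || H == 1) 0 else (i - 1) * (H - 1) / (oh - 1)
    sx <- if (ow == 1 || W == 1) 0 else (j - 1) * (W - 1) / (ow - 1)
    y0 <- min(floor(sy), H - 2); x0 <- min(floor(sx), W - 2)
    if (H == 1) y0 <- 0
    if (W == 1) x0 <- 0
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    p <- c(x[y0 + 1, x0 + 1], x[y1 + 1, x0 + 1], x[y0 + 1, x1 + 1], x[y1 + 1, x1 + 1])
    wgt <- c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
    y[i, j] <- sum(wgt * p)
  }
  y
}

# all-pairs rank statistic: P(score_pos > score_neg) + 0.5 P(equal)
ref_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# navigate nested parameter trees by mixed name/index paths
get_by_path <- function(p, path) {
  for (nm in path) {
    i <- suppressWarnings(as.integer(nm))
    p <- if (!is.na(i) && is.null(names(p))) p[[i]] else p[[nm]]
  }
  p
}

set_by_path <- function(p, path, v) {
  nm <- path[1]
  i <- suppressWarnings(as.integer(nm))
  key <- if (!is.na(i) && is.null(names(p))) i else nm
  if (length(path) == 1) { p[[key]] <- v; return(p) }
  p[[key]] <- set_by_path(p[[key]], path[-1], v)
  p
}

# small phantom spec shared by training-related tests
tiny_phantom_spec <- function(seed = 1L) {
  phantom_spec(height = 128L, width = 128L, seed = seed)
}
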