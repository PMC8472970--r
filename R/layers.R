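# Internal batched layers used by the training engine. All functions operate
# on (H, W, C, N) arrays; `prec` selects the single-precision GEMM path.
# Forward functions return the values needed by the matching backward pass;
# batch-norm forwards also return updated running statistics.

new_conv <- function(k, cin, cout, bias = TRUE, gain = 2) {
  list(w = array(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = if (bias) rep(0, cout) else NULL)
}

new_convt <- function(k, cin, cout, bias = TRUE, gain = 2) {
  # transposed-conv weight layout: (k, k, cout, cin)
  list(w = array(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                 c(k, k, cout, cin)),
       b = if (bias) rep(0, cout) else NULL)
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rmean = rep(0, c), rvar = rep(1, c))
}

new_block <- function(cin, cout) {
  list(conv1 = new_conv(3L, cin, cout, bias = FALSE), bn1 = new_bn(cout),
       conv2 = new_conv(3L, cout, cout, bias = FALSE), bn2 = new_bn(cout))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

concat4 <- function(a, b) cpp_concat_c(a, b)

relu_f <- function(x) cpp_relu_fwd(x)

bn_f <- function(bn, x, training) {
  if (!training) {
    return(list(y = cpp_bn_infer(x, bn$gamma, bn$beta, bn$rmean, bn$rvar, BN_EPS)))
  }
  r <- cpp_bn_fwd(x, bn$gamma, bn$beta, BN_EPS)
  m <- prod(dim(x)[c(1, 2, 4)])
  unbias <- if (m > 1) m / (m - 1) else 1
  var_b <- (1 / r$invstd)^2 - BN_EPS
  list(y = r$y, x = x, mean = r$mean, invstd = r$invstd,
       rmean = (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * r$mean,
       rvar = (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * var_b * unbias)
}

# conv -> bn -> [relu] -> conv -> bn -> relu ("deferred" omits the middle relu)
block_f <- function(blk, x, norm_order, training, prec) {
  y1 <- cpp_conv_fwd(x, blk$conv1$w, blk$conv1$b, 1L, 1L, prec)
  n1 <- bn_f(blk$bn1, y1, training)
  a1 <- if (norm_order == "conventional") relu_f(n1$y) else n1$y
  y2 <- cpp_conv_fwd(a1, blk$conv2$w, blk$conv2$b, 1L, 1L, prec)
  n2 <- bn_f(blk$bn2, y2, training)
  out <- relu_f(n2$y)
  list(y = out,
       cache = list(x = x, y1 = y1, n1 = n1, a1 = a1, y2 = y2, n2 = n2, out = out),
       bn1 = if (training) list(rmean = n1$rmean, rvar = n1$rvar),
       bn2 = if (training) list(rmean = n2$rmean, rvar = n2$rvar))
}

block_b <- function(blk, cache, dy, norm_order, prec, need_dx = TRUE) {
  dy <- cpp_relu_bwd(dy, cache$out)
  b2 <- cpp_bn_bwd(cache$y2, blk$bn2$gamma, cache$n2$mean, cache$n2$invstd, dy)
  c2 <- cpp_conv_bwd(cache$a1, blk$conv2$w, b2$dx, 1L, 1L, TRUE, prec)
  da1 <- c2$dx
  if (norm_order == "conventional") da1 <- cpp_relu_bwd(da1, cache$a1)
  b1 <- cpp_bn_bwd(cache$y1, blk$bn1$gamma, cache$n1$mean, cache$n1$invstd, da1)
  c1 <- cpp_conv_bwd(cache$x, blk$conv1$w, b1$dx, 1L, 1L, need_dx, prec)
  list(dx = if (need_dx) c1$dx,
       g = list(conv1 = list(w = c1$dw), bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2 = list(w = c2$dw), bn2 = list(gamma = b2$dgamma, beta = b2$dbeta)))
}

# stride-2 3x3 downsampling: conv -> bn -> relu
down_f <- function(dn, x, training, prec) {
  y <- cpp_conv_fwd(x, dn$conv$w, NULL, 2L, 1L, prec)
  n <- bn_f(dn$bn, y, training)
  out <- relu_f(n$y)
  list(y = out, cache = list(x = x, y = y, n = n, out = out),
       bn = if (training) list(rmean = n$rmean, rvar = n$rvar))
}

down_b <- function(dn, cache, dy, prec) {
  dy <- cpp_relu_bwd(dy, cache$out)
  b <- cpp_bn_bwd(cache$y, dn$bn$gamma, cache$n$mean, cache$n$invstd, dy)
  cv <- cpp_conv_bwd(cache$x, dn$conv$w, b$dx, 2L, 1L, TRUE, prec)
  list(dx = cv$dx,
       g = list(conv = list(w = cv$dw), bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

# multiscale image embedding: 3x3 conv -> bn -> relu (no grad to the image)
ms_f <- function(msl, img, training, prec) {
  y <- cpp_conv_fwd(img, msl$conv$w, NULL, 1L, 1L, prec)
  n <- bn_f(msl$bn, y, training)
  out <- relu_f(n$y)
  list(y = out, cache = list(img = img, y = y, n = n, out = out),
       bn = if (training) list(rmean = n$rmean, rvar = n$rvar))
}

ms_b <- function(msl, cache, dy, prec) {
  dy <- cpp_relu_bwd(dy, cache$out)
  b <- cpp_bn_bwd(cache$y, msl$bn$gamma, cache$n$mean, cache$n$invstd, dy)
  cv <- cpp_conv_bwd(cache$img, msl$conv$w, b$dx, 1L, 1L, FALSE, prec)
  list(g = list(conv = list(w = cv$dw),
                bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

# gated skip-connection on batches: Y = concat(E * alpha + E, D)
gs_f <- function(gate, E, D, prec) {
  A <- concat4(E, D)
  z <- cpp_conv_fwd(A, gate$w, gate$b, 1L, 0L, prec)
  alpha <- 1 / (1 + exp(-z))
  ce <- dim(E)[3]
  af <- if (dim(alpha)[3] == 1L && ce > 1L) {
    array(alpha[, , rep(1L, ce), , drop = FALSE], dim(E))
  } else alpha
  y <- concat4(E * af + E, D)
  list(y = y, cache = list(A = A, E = E, alpha = alpha, af = af, ce = ce))
}

gs_b <- function(gate, cache, dY, prec) {
  ce <- cache$ce
  sp <- cpp_split_c(dY, ce)
  dYl <- sp$first
  dD <- sp$second
  dE <- dYl + dYl * cache$af
  dalpha_full <- dYl * cache$E
  dalpha <- if (dim(cache$alpha)[3] == 1L && ce > 1L) {
    da <- array(0, dim(cache$alpha))
    for (c in seq_len(ce)) da <- da + dalpha_full[, , c, , drop = FALSE]
    da
  } else dalpha_full
  dz <- dalpha * cache$alpha * (1 - cache$alpha)
  cv <- cpp_conv_bwd(cache$A, gate$w, dz, 1L, 0L, TRUE, prec)
  spa <- cpp_split_c(cv$dx, ce)
  dE <- dE + spa$first
  dD <- dD + spa$second
  list(dE = dE, dD = dD, g = list(w = cv$dw, b = cv$db))
}

# decoder upsampling, three interchangeable modes
up_f <- function(up, x, mode, r, prec) {
  if (mode == "adaptive") {
    mid <- cpp_conv_fwd(x, up$w, NULL, 1L, 1L, prec)
    list(y = cpp_pixel_shuffle(mid, r), cache = list(x = x))
  } else if (mode == "bilinear") {
    t <- cpp_conv_fwd(x, up$w, up$b, 1L, 1L, prec)
    d <- dim(t)
    list(y = cpp_bilinear_resize(t, r * d[1], r * d[2]),
         cache = list(x = x, th = d[1], tw = d[2]))
  } else {
    list(y = cpp_convt_fwd(x, up$w, up$b, 2L, 2L, 0L, prec), cache = list(x = x))
  }
}

up_b <- function(up, cache, dy, mode, r, prec) {
  if (mode == "adaptive") {
    dmid <- cpp_pixel_unshuffle(dy, r)
    cv <- cpp_conv_bwd(cache$x, up$w, dmid, 1L, 1L, TRUE, prec)
    list(dx = cv$dx, g = list(w = cv$dw))
  } else if (mode == "bilinear") {
    dt <- cpp_bilinear_resize_bwd(dy, cache$th, cache$tw)
    cv <- cpp_conv_bwd(cache$x, up$w, dt, 1L, 1L, TRUE, prec)
    list(dx = cv$dx, g = list(w = cv$dw, b = cv$db))
  } else {
    cv <- cpp_convt_bwd(cache$x, up$w, dy, 2L, 2L, TRUE, prec)
    list(dx = cv$dx, g = list(w = cv$dw, b = cv$db))
  }
}

# ---- parameter-tree utilities ------------------------------------------

# flatten the nested parameter tree into a named list keyed by dotted
# paths ("enc.1.conv1.w", ...) -- the addressing used by the native engine
flatten_params <- function(p, path = character()) {
  if (is.numeric(p)) return(setNames(list(p), paste(path, collapse = ".")))
  out <- list()
  nms <- names(p) %||% rep("", length(p))
  for (i in seq_along(p)) {
    if (is.null(p[[i]])) next
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, flatten_params(p[[i]], c(path, nm)))
  }
  out
}

# write flat dotted-path values back into the nested tree, preserving the
# original leaf attributes (dim)
unflatten_into <- function(p, flat, path = character()) {
  if (is.numeric(p)) {
    v <- flat[[paste(path, collapse = ".")]]
    if (is.null(v)) return(p)
    attributes(v) <- attributes(p)
    return(v)
  }
  if (is.list(p)) {
    nms <- names(p) %||% rep("", length(p))
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      p[[i]] <- unflatten_into(p[[i]], flat, c(path, nm))
    }
  }
  p
}

LEARNABLE <- c("w", "b", "gamma", "beta")

walk_learnable <- function(p, fn, path = character()) {
  if (is.numeric(p)) {
    nm <- path[length(path)]
    if (nm %in% LEARNABLE) fn(p, path)
    return(invisible())
  }
  if (is.list(p)) {
    nms <- names(p) %||% rep("", length(p))
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      walk_learnable(p[[i]], fn, c(path, nm))
    }
  }
  invisible()
}

count_learnable <- function(p) {
  total <- 0
  walk_learnable(p, function(v, path) total <<- total + length(v))
  total
}

zeros_like_grads <- function(g) {
  if (is.numeric(g)) return(array(0, dim(g) %||% length(g)))
  lapply(g, zeros_like_grads)
}

# elementwise accumulate two grad trees of identical structure
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a)) return(a + b)
  mapply(acc_grads, a, b, SIMPLIFY = FALSE)
}

# one Adam step over matching param/grad trees; state holds m, v
adam_step <- function(params, grads, state, lr, beta1, beta2, eps, wd, t) {
  step1 <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      m <- m %||% vector("list", length(g))
      v <- v %||% vector("list", length(g))
      names(m) <- names(g); names(v) <- names(g)
      keys <- names(g) %||% seq_along(g)   # named trees align by name, others by position
      for (nm in keys) {
        r <- step1(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    g <- g + wd * p
    m <- if (is.null(m)) (1 - beta1) * g else beta1 * m + (1 - beta1) * g
    v <- if (is.null(v)) (1 - beta2) * g^2 else beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  step1(params, grads, state$m, state$v)
}
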