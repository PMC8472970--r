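#' Specification of a synthetic fundus phantom
#'
#' Parameters of the procedural generator that emulates a fundus photograph
#' with paired vessel ground truth and circular field-of-view (FOV) mask at
#' desk scale. Vessels are drawn as branching random walks of tapering
#' width, dark on a brighter, smoothly illuminated, noisy background --
#' the appearance of the green channel of a fundus image. The seed fully
#' determines the output.
#'
#' @param height,width image size in pixels (default 584 x 565, the DRIVE
#'   raster).
#' @param n_trees number of vessel trees seeded on the FOV boundary.
#' @param branch_prob per-step probability that a walk spawns a side branch.
#' @param width_range vessel diameter range in pixels, widest at the root
#'   tapering towards the tips (thin-vessel cases included by design).
#' @param tortuosity standard deviation (radians) of the per-step heading
#'   change; 0 gives straight vessels.
#' @param vessel_contrast fractional darkening of the background under a
#'   vessel, in `[0, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param illumination_gradient strength of the radial illumination
#'   falloff across the FOV (0 = flat field).
#' @param fov_radius_frac FOV radius as a fraction of `min(height, width)/2`.
#' @param seed integer seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(height = 584L, width = 565L, n_trees = 6L,
                         branch_prob = 0.03, width_range = c(1, 4),
                         tortuosity = 0.35, vessel_contrast = 0.45,
                         noise_sd = 0.035, illumination_gradient = 0.15,
                         fov_radius_frac = 0.96, seed = 1L) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, tortuosity >= 0,
            vessel_contrast >= 0, vessel_contrast <= 1, noise_sd >= 0,
            fov_radius_frac > 0, fov_radius_frac <= 1,
            length(width_range) == 2L, width_range[1] >= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_trees = as.integer(n_trees), branch_prob = branch_prob,
                 width_range = as.numeric(width_range), tortuosity = tortuosity,
                 vessel_contrast = vessel_contrast, noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 fov_radius_frac = fov_radius_frac, seed = as.integer(seed)),
            class = "phantom_spec")
}

# 5x5 Gaussian smoothing via the conv kernel (zero-padded edges)
blur5 <- function(m, sigma = 1) {
  k <- outer(dnorm(-2:2, sd = sigma), dnorm(-2:2, sd = sigma))
  k <- k / sum(k)
  x <- array(m, c(dim(m), 1L, 1L))
  w <- array(k, c(5L, 5L, 1L, 1L))
  matrix(cpp_conv_fwd(x, w, NULL, 1L, 2L, FALSE), nrow(m), ncol(m))
}

# rasterize centerline points with per-point diameters into a 0/1 matrix:
# points are grouped by rounded radius and stamped with precomputed disk
# offsets, so cost scales with vessel pixels rather than image area
rasterize_disks <- function(H, W, py, px, pw) {
  mask <- matrix(0L, H, W)
  if (!length(py)) return(mask)
  r_half <- pmax(round(pw), 1) / 2
  for (rh in unique(r_half)) {
    sel <- r_half == rh
    ri <- ceiling(rh - 0.5)
    off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
    off <- off[off$dy^2 + off$dx^2 <= rh^2, , drop = FALSE]
    rows <- rep(round(py[sel]), each = nrow(off)) + off$dy
    cols <- rep(round(px[sel]), each = nrow(off)) + off$dx
    ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    mask[cbind(rows[ok], cols[ok])] <- 1L
  }
  mask
}

#' Generate a fundus-like phantom
#'
#' Draws branching vessel trees as random walks inside a circular FOV,
#' renders them dark on a brighter background with a smooth radial
#' illumination field and additive Gaussian noise, and quantizes the image
#' to 8-bit levels (so disk round trips are exact). Identical spec implies
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with `image` (H x W matrix in
#'   `[0, 1]`), `vessels` and `fov` (H x W 0/1 integer matrices,
#'   `vessels <= fov` everywhere), and the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  if (H < 16L || W < 16L)
    stop(sprintf("phantom size %dx%d is degenerate (minimum side is 16 px)", H, W))

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad <- spec$fov_radius_frac * min(H, W) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist2 <- (yy - cy)^2 + (xx - cx)^2
  fov <- matrix(as.integer(dist2 <= rad^2), H, W)

  wmin <- spec$width_range[1]; wmax <- spec$width_range[2]
  base_len <- round(1.2 * rad)
  py <- px <- pw <- numeric(0)
  # each walk: (y, x, heading, width, remaining steps)
  stack <- vector("list", 0)
  for (i in seq_len(spec$n_trees)) {
    th <- runif(1, 0, 2 * pi)
    y0 <- cy + 0.92 * rad * sin(th)
    x0 <- cx + 0.92 * rad * cos(th)
    head0 <- th + pi + runif(1, -0.5, 0.5)   # point inwards
    w0 <- runif(1, 0.6 * wmax, wmax)
    stack[[length(stack) + 1L]] <- list(y = y0, x = x0, dir = head0,
                                        width = w0, steps = base_len)
  }
  while (length(stack)) {
    sg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    y <- sg$y; x <- sg$x; dir <- sg$dir; wd <- sg$width
    taper <- (wd - wmin) / max(sg$steps, 1L)
    n_max <- sg$steps
    sy <- sx <- sw <- numeric(n_max)
    used <- 0L
    for (s in seq_len(n_max)) {
      y <- y + sin(dir); x <- x + cos(dir)
      if ((y - cy)^2 + (x - cx)^2 > rad^2) break
      used <- used + 1L
      sy[used] <- y; sx[used] <- x; sw[used] <- wd
      dir <- dir + rnorm(1, 0, spec$tortuosity * 0.35)
      wd <- max(wmin, wd - taper)
      if (wd > 1.3 * wmin && runif(1) < spec$branch_prob &&
          length(stack) < 3L * spec$n_trees) {
        stack[[length(stack) + 1L]] <- list(
          y = y, x = x, dir = dir + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
          width = 0.7 * wd, steps = round((sg$steps - s) * 0.8))
      }
    }
    if (used) {
      py <- c(py, sy[seq_len(used)])
      px <- c(px, sx[seq_len(used)])
      pw <- c(pw, sw[seq_len(used)])
    }
  }
  vessels <- rasterize_disks(H, W, py, px, pw) * fov

  illum <- 0.78 * (1 - spec$illumination_gradient * dist2 / rad^2)
  soft <- blur5(vessels, sigma = 0.8)
  soft <- pmin(soft * 1.6, 1)
  img <- illum * (1 - spec$vessel_contrast * soft)
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W) +
      0.8 * blur5(matrix(rnorm(H * W, 0, spec$noise_sd), H, W), sigma = 1.2)
  }
  img[fov == 0L] <- img[fov == 0L] * 0.06
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255   # 8-bit quantization, lossless disk round trip

  structure(list(image = img, vessels = vessels, fov = fov, spec = spec),
            class = "phantom")
}

#' Generate a reproducible set of phantoms
#'
#' @param spec template [phantom_spec()]; per-item seeds are derived
#'   deterministically from `seed`.
#' @param n number of phantoms (>= 1).
#' @param seed integer master seed.
#' @return list of `phantom` objects.
#' @export
generate_dataset <- function(spec, n, seed = spec$seed) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    si <- spec
    si$seed <- derive_seed(seed, i)
    generate_phantom(si)
  })
}

#' @export
print.phantom <- function(x, ...) {
  fr <- sum(x$vessels) / max(sum(x$fov), 1)
  cat(sprintf("<phantom> %dx%d, vessel fraction in FOV: %.3f, seed %d\n",
              nrow(x$image), ncol(x$image), fr, x$spec$seed))
  invisible(x)
}
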