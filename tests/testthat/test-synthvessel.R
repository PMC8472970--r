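test_that("phantom generation is deterministic and seed-sensitive", {
  sp <- tiny_phantom_spec(seed = 21)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a, b)
  c <- generate_phantom(tiny_phantom_spec(seed = 22))
  expect_false(identical(a$vessels, c$vessels))
  # caller RNG state is untouched
  set.seed(77); before <- .Random.seed
  invisible(generate_phantom(sp))
  expect_identical(.Random.seed, before)
})

test_that("vessels stay inside the FOV with a plausible density", {
  for (s in c(1, 5, 9)) {
    ph <- generate_phantom(tiny_phantom_spec(seed = s))
    expect_true(all(ph$vessels <= ph$fov))
    frac <- sum(ph$vessels) / sum(ph$fov)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.30)
  }
})

test_that("vessels are darker than the surrounding background", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 3))
  v <- mean(ph$image[ph$vessels == 1])
  bgr <- mean(ph$image[ph$fov == 1 & ph$vessels == 0])
  expect_lt(v, bgr)
})

test_that("contrast-free noiseless phantom is the pure illumination field", {
  sp <- tiny_phantom_spec(seed = 4)
  sp$vessel_contrast <- 0; sp$noise_sd <- 0
  ph <- generate_phantom(sp)
  expect_gt(sum(ph$vessels), 0)           # ground truth still present
  inside <- ph$image[ph$fov == 1]
  expect_gt(min(inside), 0.5)             # no dark vessel footprint
  # radially symmetric smooth field: few distinct quantized levels
  expect_lt(length(unique(inside)), 60)
})

test_that("degenerate sizes are rejected", {
  expect_error(generate_phantom(phantom_spec(height = 8, width = 128)),
               "degenerate")
})

test_that("datasets derive per-item seeds deterministically", {
  sp <- tiny_phantom_spec()
  d1 <- generate_dataset(sp, 3, seed = 5)
  d2 <- generate_dataset(sp, 3, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1[[1]]$vessels, d1[[2]]$vessels))
  single <- generate_phantom({ s <- sp; s$seed <- gsaunet:::derive_seed(5, 1); s })
  expect_identical(d1[[1]], single)
})
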