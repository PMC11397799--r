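# brute-force oracle: integer shift maximizing plain spatial
# cross-correlation, searched exhaustively over |dy|,|dx| <= maxs
oracle_int_shift <- function(ref, mov, maxs = 8) {
  best <- c(0, 0); best_v <- -Inf
  a <- ref - mean(ref); b <- mov - mean(mov)
  n <- nrow(ref)
  for (dy in -maxs:maxs) for (dx in -maxs:maxs) {
    rs <- max(1, 1 + dy):min(n, n + dy)
    cs <- max(1, 1 + dx):min(n, n + dx)
    v <- sum(a[rs - dy, cs - dx] * b[rs, cs])
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  as.numeric(best)   # displacement of mov relative to ref
}

reg_scene <- function(seed = 1, nir_shift = c(0, 0), nir_affine = NULL,
                      noise_sd = 0, n = 128, psf_sigma = 0.7) {
  sp <- scene_spec(height = n, width = n,
                   canopy = list(ellipse(n * 0.45, n * 0.55, n * 0.22,
                                         n * 0.16, 0.5),
                                 ellipse(n * 0.68, n * 0.3, n * 0.12,
                                         n * 0.12)),
                   noise_sd = noise_sd, psf_sigma = psf_sigma,
                   nir_shift = nir_shift,
                   nir_affine = nir_affine, seed = seed,
                   band_values = c(red = 0.2, nir = 0.8, chlf = 0.7),
                   background_values = c(red = 0.05, nir = 0.05,
                                         chlf = 0.05))
  generate_scene(sp)
}

test_that("self-alignment and degenerate inputs behave as specified", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  t0 <- estimate_shift(img, img)
  expect_identical(c(t0$dy, t0$dx), c(0, 0))
  expect_gt(t0$peak_confidence, 0.99)
  expect_error(estimate_shift(img, matrix(0.3, 64, 64)),
               class = "canopyspec_degenerate_image_error")
})

test_that("integer NIR shifts are recovered exactly and match the brute-force oracle", {
  sc <- reg_scene(seed = 3, nir_shift = c(3, -5))
  ref <- sc$stack$channels$red; mov <- sc$stack$channels$nir
  est <- estimate_shift(ref, mov)
  expect_identical(c(est$dy, est$dx), c(3, -5))
  expect_identical(oracle_int_shift(ref, mov), c(3, -5))

  set.seed(11)
  for (k in 1:8) {
    v <- sample(-8:8, 2, replace = TRUE)
    sc <- reg_scene(seed = 100 + k, nir_shift = v, noise_sd = 0.01)
    est <- estimate_shift(sc$stack$channels$red, sc$stack$channels$nir)
    expect_identical(c(est$dy, est$dx), as.numeric(v))
  }
})

test_that("subpixel shifts are recovered within 0.1 px at upsample 20", {
  sc <- reg_scene(seed = 5, nir_shift = c(2.5, -1.25))
  est <- estimate_shift(sc$stack$channels$red, sc$stack$channels$nir,
                        upsample = 20)
  expect_lt(max(abs(c(est$dy, est$dx) - c(2.5, -1.25))), 0.1)

  set.seed(21)
  for (k in 1:5) {
    v <- round(runif(2, -3, 3) * 4) / 4
    sc <- reg_scene(seed = 200 + k, nir_shift = v, noise_sd = 0.01)
    est <- estimate_shift(sc$stack$channels$red, sc$stack$channels$nir,
                          upsample = 20)
    expect_lt(max(abs(c(est$dy, est$dx) - v)), 0.1)
  }
})

test_that("identity warp fits to the identity matrix", {
  sc <- reg_scene(seed = 6, noise_sd = 0)
  img <- sc$stack$channels$red
  est <- estimate_affine(img, img, grid = 3)
  expect_lt(max(abs(est$matrix - cbind(diag(2), c(0, 0)))), 1e-6)
  expect_equal(est$peak_confidence, 1)
})

test_that("a known mild affine NIR warp is recovered entrywise", {
  # millipixel-precision check: texture spread over the frame, 16-bit
  # depth and fine pixel-integration sampling so that scene rasterization
  # is not the dominant error source
  G <- matrix(c(1.02, 0, 0, 1.02, 4, 2), 2, 3)
  sc <- generate_scene(scene_spec(
    height = 192, width = 192,
    canopy = list(ellipse(50, 60, 22, 15, 0.4),
                  ellipse(130, 50, 18, 25, 1.1),
                  ellipse(90, 140, 25, 17, -0.5),
                  ellipse(160, 150, 14, 14)),
    noise_sd = 0, nir_affine = G, seed = 7, bit_depth = 16L,
    supersample = 32L,
    band_values = c(red = 0.2, nir = 0.8, chlf = 0.7),
    background_values = c(red = 0.05, nir = 0.05, chlf = 0.05)))
  est <- estimate_affine(sc$stack$channels$red, sc$stack$channels$nir,
                         grid = 4)
  expect_lt(max(abs(est$matrix - G)), 0.005)
  expect_gt(est$peak_confidence, 0.1)
})

test_that("a pure translation scene degenerates the affine fit to a translation", {
  sc <- reg_scene(seed = 8, nir_shift = c(3, -2), n = 192)
  est <- estimate_affine(sc$stack$channels$red, sc$stack$channels$nir,
                         grid = 4)
  expect_lt(abs(est$matrix[1, 2]), 0.01)   # |a01|
  expect_lt(abs(est$matrix[2, 1]), 0.01)   # |a10|
  expect_equal(c(est$dy, est$dx), c(3, -2), tolerance = 0.05)
})

test_that("apply_transform only touches the moving channel and honours identity", {
  sc <- reg_scene(seed = 9, nir_shift = c(3, -5), noise_sd = 0,
                  psf_sigma = 0)
  st <- sc$stack
  out <- apply_transform(st, registration_transform(0, 0))
  expect_identical(out$channels, st$channels)

  tr <- estimate_shift(st$channels$red, st$channels$nir)
  out <- apply_transform(st, tr)
  expect_identical(out$channels$red, st$channels$red)
  expect_identical(out$channels$chlf, st$channels$chlf)
  expect_false(identical(out$channels$nir, st$channels$nir))
  # interior pixels of an integer shift are exact
  clean <- reg_scene(seed = 9, nir_shift = c(0, 0), noise_sd = 0,
                     psf_sigma = 0)
  inner <- 10:118
  expect_equal(out$channels$nir[inner, inner],
               clean$stack$channels$nir[inner, inner], tolerance = 1e-12)
})

test_that("translating forth and back is the identity within interpolation error", {
  # smooth canopy: heavy optical blur keeps bilinear round-trip error low
  sc <- reg_scene(seed = 10, noise_sd = 0, psf_sigma = 2.5)
  img <- sc$stack$channels$nir
  fwd <- translate_image(img, 2.5, -1.25, fill = 0.05)
  back <- translate_image(fwd, -2.5, 1.25, fill = 0.05)
  inner <- 8:120
  expect_lt(max(abs((back - img)[inner, inner])), 0.02)
})

test_that("out-of-frame pixels are zeroed, flagged, and excluded from indices", {
  sc <- reg_scene(seed = 12, nir_shift = c(30, 0), noise_sd = 0)
  st <- apply_transform(sc$stack,
                        registration_transform(dy = 30, dx = 0))
  expect_true(all(st$channels$nir[99:128, ] == 0))
  expect_true(all(st$oob$nir[99:128, ]))
  mask <- mask_from_matrix(matrix(TRUE, 128, 128))
  map <- compute_ndvi(st, mask)
  expect_false(any(map$valid[99:128, ]))
})
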