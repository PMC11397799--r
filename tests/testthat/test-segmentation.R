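seg_scene <- function(..., noise_sd = 0, psf_sigma = 0, seed = 1) {
  generate_scene(scene_spec(..., noise_sd = noise_sd,
                            psf_sigma = psf_sigma, seed = seed))
}

test_that("Otsu segmentation of a clean fluorescent disk matches ground truth", {
  sc <- seg_scene(height = 128, width = 128,
                  canopy = list(ellipse(63.5, 63.5, 40, 40)),
                  psf_sigma = 0.7)
  m <- compute_mask(sc$stack)
  iou <- sum(m$mask & sc$truth$mask) / sum(m$mask | sc$truth$mask)
  expect_gte(iou, 0.99)
  expect_equal(m$n_components, 1L)
  expect_gt(m$threshold_used, 0.05)
  expect_lt(m$threshold_used, 0.7)
})

test_that("an all-background image yields an empty, flagged mask", {
  st <- spectral_stack(list(chlf = matrix(0.05, 32, 32)))
  m <- compute_mask(st, segmentation_params(method = "fixed",
                                            fixed_threshold = 0.2))
  expect_equal(sum(m$mask), 0)
  expect_equal(m$n_components, 0L)
  # Otsu on the same constant image is degenerate
  expect_error(compute_mask(st), class = "canopyspec_degenerate_histogram_error")
  # missing chlf channel
  expect_error(compute_mask(spectral_stack(list(red = matrix(0.5, 8, 8)))),
               class = "canopyspec_missing_channel_error")
})

test_that("small components are removed; counts match a brute-force oracle", {
  # ~600 px disk (r = 13.8) and ~40 px disk (r = 3.57)
  sc <- seg_scene(height = 96, width = 96,
                  canopy = list(ellipse(40, 40, 13.8, 13.8),
                                ellipse(80, 80, 3.57, 3.57)))
  params <- segmentation_params(method = "fixed", fixed_threshold = 0.375,
                                min_component_px = 50)
  m <- compute_mask(sc$stack, params)
  expect_equal(m$n_components, 1L)
  expect_equal(oracle_component_count(m$mask), 1L)
  # only the big disk survives: no foreground near the small one
  expect_false(any(m$mask[70:96, 70:96]))
  # with the filter off, both disks and the oracle agree on 2 components
  m2 <- compute_mask(sc$stack,
                     segmentation_params(method = "fixed",
                                         fixed_threshold = 0.375,
                                         min_component_px = 0))
  expect_equal(m2$n_components, 2L)
  expect_equal(oracle_component_count(m2$mask), 2L)
  # largest_only keeps the big disk
  m3 <- compute_mask(sc$stack,
                     segmentation_params(method = "fixed",
                                         fixed_threshold = 0.375,
                                         min_component_px = 0,
                                         keep = "largest_only"))
  expect_equal(m3$n_components, 1L)
  expect_lt(mask_pixel_count(m3), mask_pixel_count(m2))
})

test_that("mask pixel counting is exact and matches a double-loop oracle", {
  expect_equal(mask_pixel_count(mask_from_matrix(matrix(FALSE, 10, 10))), 0L)
  expect_equal(mask_pixel_count(mask_from_matrix(matrix(TRUE, 100, 100))),
               10000L)
  set.seed(42)
  for (k in 1:5) {
    m <- matrix(runif(400) > 0.6, 20, 20)
    naive <- 0L
    for (i in 1:20) for (j in 1:20) if (m[i, j]) naive <- naive + 1L
    expect_identical(mask_pixel_count(mask_from_matrix(m)), naive)
  }
})

test_that("a radius-50 disk count matches the analytic area and the rasterization oracle", {
  sc <- seg_scene(height = 128, width = 128,
                  canopy = list(ellipse(63.5, 63.5, 50, 50)))
  m <- compute_mask(sc$stack, segmentation_params(method = "fixed",
                                                  fixed_threshold = 0.375))
  count <- mask_pixel_count(m)
  expect_identical(count, sc$truth$canopy_size_px)
  expect_lt(abs(count - pi * 50^2) / (pi * 50^2), 0.01)
})

test_that("fixed-threshold masks are monotone in the threshold", {
  sc <- seg_scene(height = 64, width = 64,
                  canopy = list(ellipse(31.5, 31.5, 20, 14, 0.3)),
                  noise_sd = 0.05, psf_sigma = 0.7, seed = 5)
  thresholds <- c(0.1, 0.25, 0.4, 0.6, 0.8)
  prev <- NULL
  for (t in thresholds) {
    m <- compute_mask(sc$stack,
                      segmentation_params(method = "fixed",
                                          fixed_threshold = t,
                                          min_component_px = 0))
    if (!is.null(prev)) expect_true(all(prev | !m$mask))  # m subset of prev
    prev <- m$mask
  }
})

test_that("Otsu masks are invariant to affine rescaling of the fluorescence channel", {
  sc <- seg_scene(height = 64, width = 64,
                  canopy = list(ellipse(31.5, 31.5, 18, 18)),
                  noise_sd = 0.01, psf_sigma = 0.7, seed = 8)
  chlf <- sc$stack$channels$chlf
  st1 <- spectral_stack(list(chlf = chlf))
  st2 <- spectral_stack(list(chlf = 0.5 * chlf + 0.2))
  m1 <- compute_mask(st1)
  m2 <- compute_mask(st2)
  expect_identical(m1$mask, m2$mask)
  expect_equal(m2$threshold_used, 0.5 * m1$threshold_used + 0.2,
               tolerance = 0.01)
})

test_that("opening/closing with radius 0 is the identity on the thresholded mask", {
  sc <- seg_scene(height = 64, width = 64,
                  canopy = list(ellipse(31.5, 31.5, 18, 12, 0.7)),
                  noise_sd = 0.02, psf_sigma = 0, seed = 3)
  m <- compute_mask(sc$stack,
                    segmentation_params(method = "fixed",
                                        fixed_threshold = 0.375,
                                        open_radius = 0, close_radius = 0,
                                        min_component_px = 0))
  expect_identical(m$mask, sc$stack$channels$chlf > 0.375)
  # strictly-above rule at the threshold
  st <- spectral_stack(list(chlf = matrix(c(0.2, 0.2001), 1, 2)))
  mm <- compute_mask(st, segmentation_params(method = "fixed",
                                             fixed_threshold = 0.2,
                                             min_component_px = 0))
  expect_identical(as.vector(mm$mask), c(FALSE, TRUE))
})

test_that("morphological opening removes speckle smaller than the brush", {
  sc <- seg_scene(height = 64, width = 64,
                  canopy = list(ellipse(31.5, 31.5, 15, 15)),
                  noise_sd = 0.15, psf_sigma = 0, seed = 12)
  noisy <- compute_mask(sc$stack,
                        segmentation_params(method = "fixed",
                                            fixed_threshold = 0.375,
                                            min_component_px = 0))
  cleaned <- compute_mask(sc$stack,
                          segmentation_params(method = "fixed",
                                              fixed_threshold = 0.375,
                                              open_radius = 1,
                                              close_radius = 1,
                                              min_component_px = 0))
  expect_lt(cleaned$n_components, noisy$n_components)
  iou <- sum(cleaned$mask & sc$truth$mask) /
    sum(cleaned$mask | sc$truth$mask)
  expect_gte(iou, 0.9)
})
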