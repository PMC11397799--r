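# shared fixture builders -- everything is generated in code at test time

# a float stack built directly from matrices (no quantization, no files)
make_float_stack <- function(nir = 0.8, red = 0.2, green = 0.45,
                             chlf = 0.7, n = 20) {
  mk <- function(v) matrix(v, n, n)
  spectral_stack(list(red = mk(red), green = mk(green), nir = mk(nir),
                      chlf = mk(chlf)))
}

# full-mask plant_mask for an n x n raster
full_mask <- function(n = 20) {
  structure(list(mask = matrix(TRUE, n, n), threshold_used = 0.5,
                 n_components = 1L, source = "chlf"),
            class = "plant_mask")
}

mask_from_matrix <- function(m) {
  structure(list(mask = m, threshold_used = 0.5,
                 n_components = NA_integer_, source = "chlf"),
            class = "plant_mask")
}

# an index_map wrapping given values (valid where not NA)
map_from_values <- function(values, name = "NDVI") {
  structure(list(name = name, values = values, valid = !is.na(values),
                 formula_id = "test"), class = "index_map")
}

# independent double-loop rasterization oracle: count of pixel-coverage
# fractions (ss x ss subsamples) strictly above 1/2 for a disk
oracle_disk_count <- function(n, r0, c0, rad, ss = 8) {
  count <- 0L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    hits <- 0L
    for (or in off) for (oc in off)
      if ((i + or - r0)^2 + (j + oc - c0)^2 <= rad^2) hits <- hits + 1L
    if (hits / ss^2 > 0.5) count <- count + 1L
  }
  count
}

# independent 8-connectivity component counter (BFS, no package code)
oracle_component_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; cc <- p[2] + dj
        if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  n
}

# write a 5-channel manifest + images for one simple scene; returns the
# manifest path
write_test_scene_files <- function(dir, seed = 7, nir_shift = c(0, 0),
                                   plant_id = "p1", timepoint = "t1",
                                   treatment = 1, bit_depth = 8L,
                                   noise_sd = 0, psf_sigma = 0) {
  sp <- scene_spec(height = 64, width = 64,
                   canopy = list(ellipse(31.5, 31.5, 18, 18)),
                   noise_sd = noise_sd, psf_sigma = psf_sigma,
                   nir_shift = nir_shift, bit_depth = bit_depth,
                   seed = seed, plant_id = plant_id, timepoint = timepoint,
                   treatment = treatment)
  scene <- generate_scene(sp)
  rows <- write_scene(scene, dir)
  path <- file.path(dir, "manifest.csv")
  write.csv(rows, path, row.names = FALSE)
  list(manifest = path, scene = scene)
}
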