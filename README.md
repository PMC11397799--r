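# canopyspec

Multispectral image analysis for top-view plant phenotyping.

Single-wavelength LED imaging systems photograph one potted plant from
above under sequential illuminations — red, green, blue, near-infrared
(NIR), and blue excitation behind a long-pass filter for chlorophyll
fluorescence.  From such a stack, `canopyspec` extracts the canopy
metrics used in greenhouse dose-response trials and fits the associated
treatment-response statistics:

1. **Registration.**  The NIR frame of this hardware class is typically
   shifted (and mildly warped) against the visible channels.  The package
   estimates the misalignment by phase correlation with subpixel
   refinement (`estimate_shift`), or a tile-based affine fit with
   normalized-cross-correlation polish (`estimate_affine`), and resamples
   NIR into the red channel's frame (`apply_transform`).
2. **Segmentation.**  Only chlorophyll-containing tissue fluoresces, so
   thresholding the fluorescence channel (Otsu by default) isolates the
   photosynthetically active canopy (`compute_mask`).
3. **Per-pixel indices over the mask.**  `NDVI = (NIR − red)/(NIR + red)`
   and an anthocyanin index (default red/green ratio; the formula used is
   recorded in the output), with mean and population SD over valid pixels
   (`compute_ndvi`, `compute_aci`, `index_statistics`).
4. **Canopy metrics.**  Projected canopy size = mask pixel count, a 2-D
   biomass proxy (`mask_pixel_count`, `summarize_plant`); false-color maps
   and histograms (`render_false_color`, `compute_histogram`).
5. **Treatment statistics.**  Quadratic OLS of any metric on the
   treatment level, `y = b0 + b1 x + b2 x²`, with `R²` and the overall
   F-test p-value, plus group means ± SE (`fit_quadratic`, `group_means`).

Because no public imagery exists for this hardware class, the package
ships a synthetic-scene generator with exact analytic ground truth
(ellipse-union canopies, per-band reflectances, sensor PSF/noise/
quantization, and exactly injected NIR misalignment) so that every stage
is testable end to end (`scene_spec`, `generate_scene`,
`generate_experiment`).

## Worked example

```r
library(canopyspec)

# a 192x192 synthetic plant whose NIR channel is shifted by (3, -5) px
scene <- generate_scene(scene_spec(nir_shift = c(3, -5), seed = 42))
analysis <- analyze_stack(scene$stack)

analysis$transform
#> <registration_transform> translation (dy, dx) = (3, -5), confidence 0.173
analysis$summary
#> <canopy_summary> synthetic @ t0: 7857 px, NDVI 0.5990 +/- 0.0180, ChlF 0.6921
scene$truth$canopy_size_px   # ground truth: 7860 px, true NDVI 0.6
#> [1] 7860
```

The injected shift is recovered exactly, the canopy size is within 3 px
of the rasterized truth (sensor noise at the disk edge), and the masked
NDVI mean is within 0.001 of the generating value 0.6.

A full dose-response experiment (6 fertilizer rates × 8 replicates, NDVI
rising quadratically with rate, each scene with its own random NIR
shift):

```r
ex  <- generate_experiment(seed = 1)
res <- analyze_experiment(ex, metric = "ndvi_mean")
res$fit
#> <quadratic_fit> ndvi_mean ~ treatment + treatment^2 (synthetic, n = 48)
#>   y = 0.3501 + 0.05929 x + -0.003706 x^2
#>   R^2 = 0.9581, F-test p = 1.001e-31
```

The generating curve was `0.35 + 0.06 x − 0.00375 x²`.

## Command line

A thin wrapper over the same functions lives in `exec/canopyspec`:

```sh
canopyspec simulate --spec scenes.yaml --out scenes/
canopyspec analyze  --manifest scenes/manifest.csv --plant p1 --timepoint t1 --out out/
canopyspec batch    --manifest scenes/manifest.csv --out out/
canopyspec regress  --summaries out/summaries.csv --metric ndvi_mean --out fits.csv
```

Images are single-channel 8/16-bit PNG or TIFF, indexed by a CSV manifest
with columns `plant_id,timepoint,treatment,channel,file`.

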