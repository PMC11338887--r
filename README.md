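# myelometry

Morphometry of myelinated axons in two-dimensional cortical
electron-microscopy (EM) images, for neuroscientists quantifying myelin
integrity across experimental groups — for example asking whether an
anaesthetic exposure changed myelin sheath thickness, g-ratio or axon
diameter in prefrontal cortex.

In osmium-stained EM cross-sections, each myelinated axon appears as a
dark ring (the myelin sheath) around a brighter lumen (the axon). Given a
grey image and a binary myelin mask — produced either by the built-in
reference thresholding segmenter or externally, e.g. by a trained
segmentation network — the package:

1. **Curates** the mask into measurable sheaths: 8-connected foreground
   components with exactly one 4-connected enclosed hole (ring topology)
   that do not touch the image border; every rejection is logged.
2. **Measures** each sheath:
   - *thickness*: from the centre of the ellipse fitted to the inner
     (axonal) border, rays at 10 equally spaced angles cross the inner
     and outer contours; thickness is the per-ray contour separation,
     `t(θ) = d_out(θ) − d_in(θ)`;
   - *g-ratio*: `g = mean_i( d_axon_i / d_fiber_i )` over the 5 diameters
     formed by opposite-ray pairs through the centre (healthy white
     matter has g ≈ 0.7; g > 0.8 flags acute demyelination);
   - *axon diameter*: the full short axis `2b` of the direct
     least-squares ellipse fit to the inner border;
   - converted to nanometres via the pixel size (default 12 nm/px).
3. **Stratifies** sheaths into cortical layer 1 and layer 2/3 by depth,
   with the layer-2/3 band three times as deep as layer 1.
4. **Compares** two groups per layer and metric: Shapiro–Wilk normality
   screen, then an unpaired (Student, pooled-variance) t-test, reporting
   means ± SD, n at sheath and image level, and raw two-sided p-values
   at α = 0.05.

Because raw cortical EM volumes are rarely shareable, the package also
ships a **synthetic scene generator** that renders densely packed
elliptical axon cross-sections with exact ground truth (true g-ratio,
ring width, inner diameter, layer), so the whole pipeline is testable
and its calibration can be demonstrated without tissue data.

## Worked example

```r
library(myelometry)

# a synthetic field: 15 axons, healthy g ~ N(0.7, 0.05), 12 nm/px
spec  <- scene_spec(c(600, 500), n_axons = 15, seed = 7)
scene <- render_scene(sample_axon_population(spec), spec)

res <- measure_image(scene$image, layer1_depth_px = 150)
dplyr::select(res$sheaths, sheath_id, thickness_mean_px, g_ratio,
              axon_diameter_px, layer, qc)
#> # A tibble: 15 x 6
#>    sheath_id thickness_mean_px g_ratio axon_diameter_px layer qc
#>  1         1              6.28   0.815             53.9 L2_3  ok
#>  2         2              6.25   0.795             47.7 L2_3  ok
#>  3         3             10.7    0.736             56.0 L2_3  ok
#>  # ... 12 more rows
```

Each row is one accepted sheath: mean myelin thickness over the 10 ray
positions (pixels; multiply by 12 for nm), its g-ratio, the inner-ellipse
short-axis diameter, the cortical layer of its centre, and its QC state.
Here sheath 1 has g = 0.815 — above the 0.8 boundary, so its
`demyelination_flag` is set.

A full two-group study is one call:

```r
cfg <- run_config(
  control = list(image_shape = c(1200, 900), n_axons = 40),
  treated = list(g_mean = 0.8),       # simulated demyelinating shift
  n_images_per_group = 2, seed = 1,
  out_dir = "run1")
run <- run_all(cfg)
tidy(run)      # 6 comparisons: 3 metrics x 2 layers, means +/- SD, t, df, p
glance(run)    # image/sheath/QC counts
autoplot(run)  # per-sheath values by group, metric and layer
```

`run1/` then contains the cohort images and truth tables, the label maps
and rejection logs, `sheaths.csv`, `report.json`, `run.log` and a
`config.yaml` copy from which the run can be reproduced byte-for-byte.

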