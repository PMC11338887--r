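---
title: "Myelin morphometry from segmentation masks: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin morphometry from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelometry)
```

## The measurement problem

In osmium-stained electron micrographs of cortex, myelin retains its
phospholipids and images as a dark annulus wrapped around the brighter
axonal lumen. Three quantities summarise myelin integrity per fibre:

- **sheath thickness** — the radial width of the dark ring;
- **g-ratio** — the ratio of inner (axonal) to outer (fibre) diameter.
  In healthy primate white matter the g-ratio sits near 0.7; values
  above 0.8 are read as acute demyelination;
- **myelinated-axon diameter** — the calibre of the axon inside the
  sheath.

The package assumes segmentation has already happened (or uses its own
reference thresholder) and concentrates on turning a *binary myelin
mask* into per-sheath measurements and per-layer group statistics. The
native resolution convention is 12 nm per pixel, the acquisition scale
the defaults are built around; all pixel quantities are also reported in
nanometres via this single calibration factor.

## From mask to measurable sheaths

A mask pixel is either myelin or not. Measurable sheaths are defined by
*ring topology*:

- foreground components are 8-connected; enclosed holes are 4-connected.
  This complementary pairing is the standard way to avoid topological
  paradoxes on a square grid (a diagonal foreground chain would
  otherwise both enclose and leak);
- a component is accepted iff it encloses exactly one hole (the lumen)
  and does not touch the image border. Border-touching rings are not
  measurable (their geometry is censored); components with no hole are
  debris or compact organelles; components with two or more holes are
  fused sheaths, and splitting fused sheaths is a segmentation research
  problem this package deliberately does not attempt.

Every rejected component is logged with its reason and size, so sheath
counts are always auditable. These curation rules are this package's
definitions: upstream mask producers rarely state how their output
should be reduced to countable sheaths, so the convention must live
somewhere explicit.

## Sub-pixel boundaries, ellipse fits and the ray convention

Contours are traced as marching-squares iso-lines at level 0.5 of the
lightly smoothed (3×3 box) binary raster. On straight edges the
symmetric smoothing leaves the 0.5 crossing exactly on the half-pixel
midline between the last foreground and first background pixel; on
oblique edges it removes the orientation-dependent staircase bias
(~0.2 px) that contouring the raw binary field would carry. What
remains is the quantization of the mask boundary itself, about 0.15 px
rms per contour point, which is why the circular closed forms below
hold to well under half a pixel.

The inner border is summarised by a direct least-squares conic fit
constrained to an ellipse (Fitzgibbon's method in the numerically stable
Halir–Flusser partitioning), canonicalised to semi-axes `a >= b` and
orientation in `[0, pi)`. Fewer than six points, or a collinear set, is
an "underdetermined" error rather than a garbage fit.

Thickness is sampled at **10 positions**: rays from the fitted inner
centre at equally spaced angles starting from the image row axis. Ten
equally spaced rays is the package's reading of "measure at several
positions around the ring" — it gives unbiased angular coverage and is
exactly reproducible, where manual position choices are not. Per ray,
the thickness sample is the distance between the inner and the nearest
subsequent outer contour crossing. A ray that fails to cross the outer
contour marks a broken ring; such sheaths are flagged and excluded from
statistics, never imputed.

The g-ratio uses the same rays: opposite rays pair into 5 inner and 5
outer diameters through the centre, and `g` is the mean of the five
inner/outer ratios. "The" diameter ratio of a non-circular ring is
ambiguous; averaging all measured directions uses the whole ring and is
exact for circles. An alternative equivalent-diameter mode
(`g_mode = "area"`, the square root of the inner/outer fitted-ellipse
area ratio) is provided for sensitivity analysis. The axon diameter is
the full short axis `2b` of the inner fit — the short axis because
oblique sectioning stretches only the long axis, so the short axis is
the better calibre estimate.

The demyelination flag is strict: `g > 0.8` flags, `g = 0.8` does not.

## Cortical layering

Depth is measured in pixels from the cortical surface (the top image
edge). Given the layer-1 band depth `d1`, layer 1 is `[0, d1)` and layer
2/3 is `[d1, 4 d1)` — the combined second and third layers run three
times deeper than layer 1, per measured cortical proportions. Deeper
sheaths are "unassigned" and excluded from the per-layer statistics. A
sheath's layer is decided by its fitted inner centre, a single
unambiguous point even when a ring straddles a boundary. `d1` is a
per-image configuration value; no image-based laminar detection is
attempted.

## Group statistics

For each of the six metric-layer combinations (thickness, g-ratio,
diameter × layer 1, layer 2/3) the workflow is fixed: filter to the
layer, drop QC-excluded sheaths, screen each group with the Shapiro–Wilk
test, then an unpaired Student (pooled-variance) t-test, two-sided, at
α = 0.05, reported as means ± SD with group sizes. Design choices worth
stating:

- a Shapiro–Wilk failure *warns* but does not switch the test: the
  screen validates the workflow's assumption, it is not a decision rule;
- the default unit of analysis pools sheaths across images. Nested
  designs with very few animals per group cannot support animal-level
  t-tests, so the package defaults to transparency: sheath-level
  pooling, with per-image aggregation available (`unit = "image"`) and
  image counts always printed alongside sheath counts;
- Welch's correction is available (`mode = "welch"`) but Student's form
  is the default, matching the plain "unpaired t-test" convention;
- the six p-values are reported raw, with no multiplicity correction,
  and the report says so.

## The synthetic scene generator

Because raw cortical EM data are rarely deposited, validation runs on
generated scenes with exact ground truth. The image model is the
simplest one with tunable contrast: dark myelin (grey 60) on a lighter
background (170) with a brighter lumen (200) and additive Gaussian
sensor noise (sd 8), clipped to 8 bits. Per axon:

- the inner boundary is an ellipse; aspect ratio is uniform on
  `[1, 1.3]`, emulating cross-sections cut near-perpendicular to the
  fibre; orientation is uniform;
- true g-ratios are drawn from a normal centred at the healthy reference
  0.7 (sd 0.05), truncated to `[0.4, 0.95]` — inside the biologically
  meaningful range while avoiding degenerate rings;
- inner diameters are normal with mean 600 nm (sd 100 nm), truncated so
  the lumen stays resolvable (inner semi-minor axis >= 3 px). These
  defaults are plausible for cortical myelinated fibres but are not
  calibrated to any particular species' measured distribution;
- the ring width derives from the true g-ratio,
  `t = r̄ (1/g − 1)` with `r̄ = (a+b)/2`, and the outer boundary is the
  concentric ellipse `(a + t, b + t)`. For circles this makes
  `g = r/(r + t)` exact; for the mild eccentricities generated, the
  concentric-ellipse ring differs from a constant-normal-offset ring by
  far less than a pixel, and it keeps every ray-crossing oracle in
  closed form;
- placement is rejection sampling with a budget of 1000 tries per axon:
  outer ellipses never overlap and never touch the border (the
  morphometry contract assumes separable rings). Exhausting the budget
  raises a "density infeasible" error instead of silently rendering
  fewer axons;
- everything is a pure function of the scene specification including its
  seed; cohorts derive per-image seeds deterministically from a master
  seed.

What the generator does *not* emulate — nuclei, mitochondria,
unmyelinated axons, paranodal thickness variation, staining gradients,
segmentation-network error structure — bounds what passing tests can
claim: they demonstrate the measurement chain is correct and calibrated
on separable elliptical rings with known truth, not that any particular
segmenter is accurate on real tissue. Real-mask workflows enter through
`load_external_mask()`, and the curation, measurement and statistics
behave identically from there.

## Numerical choices and degenerate inputs

- Otsu's threshold drives the reference segmenter; since Otsu happily
  splits unimodal noise, a separation guard requires the two classes to
  differ by at least twice the overall intensity SD, otherwise the image
  is declared to have no dark phase (empty mask with a warning by
  default, an error under `strict = TRUE`). Constant images always
  error.
- `min_object_px` (default 30) removes sub-sheath speckle before
  topology curation.
- Ray-contour crossing uses exact segment intersection on the traced
  polyline; tie-breaks (crossing exactly at a vertex) resolve by the
  half-open segment convention `s in [0, 1)`.
- Opposite-ray pairing requires an even number of positions; odd counts
  fall back to doubling each ray distance (documented, non-default).
- The truncated-normal sampler resamples out-of-range draws, preserving
  determinism under the scene seed.

## Validation summary

The test suite validates, among other properties: exact mask recovery
and a pixelwise Jaccard ≥ 0.9 against truth under noise; circular
annulus closed forms (`t = r_out − r_in`, `g = r_in/r_out`) within half
a pixel for radii ≥ 20 px; per-ray thickness against the analytic
ray–ellipse oracle within 1 px; ground-truth recovery on a noiseless
200-axon cohort with g-ratio MAE < 0.02 and thickness/diameter mean
relative error < 2%; rotation (90°) invariance and scale equivariance
within 1%; and statistical calibration of the full image pipeline — the
type-I error of the end-to-end comparison inside the 99% binomial band
around 0.05 over 200 null cohorts, and ≥ 90% power over 100 replicates
for a +0.1 shift in mean g-ratio at 200 sheaths per group. The
calibration simulations run at reduced scene scale (20 axons per group
of ~300 nm axons for the null; the stated 200 sheaths per group for
power), sizes chosen to keep the suite fast while leaving the tested
properties unchanged.

## Known limitations

- No instance separation of touching sheaths; fused rings are rejected,
  which under-counts dense neuropil.
- No modelling of the periaxonal space: the inner mask border is taken
  as the axon boundary.
- Layering requires a user-supplied layer-1 depth; slices without a
  visible surface need external anatomical input.
- Sheath-level pooling understates animal-level variance in nested
  designs; the per-image unit is a partial remedy, not a mixed model.
- The generator's axon density and size distributions are plausible
  defaults, not calibrated to measured cortical data.
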