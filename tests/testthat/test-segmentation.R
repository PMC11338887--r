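test_that("noiseless scenes segment exactly and degenerate images are guarded", {
  spec <- scene_spec(c(400, 320), n_axons = 6, noise_sd = 0, seed = 4,
                     diameter_mean_nm = 300, diameter_sd_nm = 40)
  sc <- render_scene(sample_axon_population(spec), spec)
  m <- segment_myelin(sc$image)
  expect_identical(unclass(m)[, ], sc$truth_mask * 1L)
  expect_identical(attr(m, "provenance"), "reference-segmenter")

  expect_error(segment_myelin(matrix(100, 50, 50)), "no bimodal")

  # background-only noise has no dark phase: empty mask by default (with a
  # warning), an error in strict mode
  set.seed(1)
  blank <- matrix(170 + rnorm(100 * 100, 0, 8), 100, 100)
  expect_warning(mb <- segment_myelin(blank), "empty mask")
  expect_true(all(mb == 0L))
  expect_error(segment_myelin(blank, strict = TRUE), "no bimodal")
})

test_that("noisy scene segmentation overlaps the truth mask (Jaccard >= 0.9)", {
  spec <- scene_spec(c(900, 700), n_axons = 20, noise_sd = 8, seed = 6,
                     diameter_mean_nm = 400, diameter_sd_nm = 60)
  sc <- render_scene(sample_axon_population(spec), spec)
  m <- segment_myelin(sc$image)
  inter <- sum(m == 1L & sc$truth_mask == 1L)
  union <- sum(m == 1L | sc$truth_mask == 1L)
  expect_gte(inter / union, 0.9)
})

test_that("external mask ingestion validates shape and binarizes", {
  dir <- withr::local_tempdir()
  m0 <- circ_annulus_mask(c(80, 80), c(40, 40), 10, 18)

  # 8-bit 0/255 round trip
  p8 <- file.path(dir, "mask8.tif")
  tiff::writeTIFF(m0 * 1.0, p8, bits.per.sample = 8)
  m8 <- load_external_mask(p8, c(80, 80))
  expect_identical(unclass(m8)[, ], m0)
  expect_identical(attr(m8, "provenance"), "external")

  # 16-bit two-valued raster binarizes at half max
  p16 <- file.path(dir, "mask16.tif")
  tiff::writeTIFF(m0 * 1.0, p16, bits.per.sample = 16)
  expect_identical(unclass(load_external_mask(p16, c(80, 80)))[, ], m0)

  expect_error(load_external_mask(p8, c(80, 81)), "\\(80, 80\\).*\\(80, 81\\)")

  p3 <- file.path(dir, "tri.tif")
  tiff::writeTIFF(matrix(c(0, 0.5, 1), 30, 30), p3, bits.per.sample = 8)
  expect_error(load_external_mask(p3, c(30, 30)), "not binary")
})

test_that("ring-topology curation accepts annuli and logs each rejection reason", {
  # one clean annulus
  lab1 <- label_sheaths(circ_annulus_mask(c(60, 60), c(30, 30), 8, 14))
  expect_identical(sum(lab1$info$accepted), 1L)
  expect_identical(lab1$info$n_holes, 1L)

  # solid disk: no lumen
  disk <- circ_annulus_mask(c(60, 60), c(30, 30), -1, 14)
  lab2 <- label_sheaths(disk)
  expect_identical(sum(lab2$info$accepted), 0L)
  expect_identical(rejection_log(lab2)$reason, "no hole")

  # two annuli, one clipped by the border
  m <- circ_annulus_mask(c(100, 100), c(50, 40), 8, 14) |
    circ_annulus_mask(c(100, 100), c(4, 80), 8, 14)
  lab3 <- label_sheaths(m * 1L)
  expect_identical(sum(lab3$info$accepted), 1L)
  expect_identical(rejection_log(lab3)$reason, "touches border")

  # fused component with two lumens
  twin <- circ_annulus_mask(c(80, 120), c(40, 45), 8, 15) |
    circ_annulus_mask(c(80, 120), c(40, 72), 8, 15)
  lab4 <- label_sheaths(twin * 1L)
  expect_identical(sum(lab4$info$accepted), 0L)
  expect_identical(rejection_log(lab4)$reason, "multiple holes")
})

test_that("foreground is 8-connected and holes are 4-connected", {
  # checkerboard: all diagonal pixels form one 8-connected component,
  # but 2x2 alternating pixels are 4-disconnected
  cb <- matrix(0L, 4, 4)
  cb[cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))] <- 1L
  expect_identical(max(myelometry:::label_components(cb == 1L, 8L)), 1L)
  expect_identical(max(myelometry:::label_components(cb == 1L, 4L)), 4L)

  # minimal ring: 8 pixels around a single background pixel. The centre
  # touches the ring corners diagonally; with 4-connected holes it cannot
  # leak out, so this is a valid one-hole sheath.
  ring <- matrix(0L, 7, 7)
  ring[3:5, 3:5] <- 1L
  ring[4, 4] <- 0L
  lab <- label_sheaths(ring)
  expect_identical(sum(lab$info$accepted), 1L)
  expect_identical(lab$info$n_holes[1], 1L)

  # independent cross-check of 4-connectivity against EBImage::bwlabel
  set.seed(8)
  blob <- matrix(stats::rbinom(60 * 60, 1, 0.35), 60, 60)
  ours <- myelometry:::label_components(blob == 1L, 4L)
  ref <- EBImage::bwlabel(blob)
  expect_identical(max(ours), as.integer(max(ref)))
})

test_that("labeling is stable under relabeling/reflection of the input", {
  spec <- scene_spec(c(400, 320), n_axons = 8, noise_sd = 0, seed = 12,
                     diameter_mean_nm = 300, diameter_sd_nm = 40)
  sc <- render_scene(sample_axon_population(spec), spec)
  lab <- label_sheaths(sc$truth_mask)
  expect_identical(sum(lab$info$accepted), 8L)  # accepted == rendered

  flipped <- sc$truth_mask[nrow(sc$truth_mask):1, ncol(sc$truth_mask):1]
  lab_f <- label_sheaths(flipped)
  expect_identical(sum(lab_f$info$accepted), 8L)
  expect_identical(sort(lab_f$info$n_px), sort(lab$info$n_px))
})
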