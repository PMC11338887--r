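test_that("axon sampling is deterministic and follows the stated distributions", {
  spec0 <- scene_spec(c(400, 300), n_axons = 0, seed = 1)
  expect_identical(nrow(sample_axon_population(spec0)), 0L)

  spec <- scene_spec(c(1200, 1000), n_axons = 50, seed = 7,
                     diameter_mean_nm = 400, diameter_sd_nm = 60)
  a1 <- sample_axon_population(spec)
  a2 <- sample_axon_population(spec)
  expect_identical(a1, a2)
  expect_identical(nrow(a1), 50L)
  expect_true(all(a1$g_true > 0.4 & a1$g_true < 0.95))
  expect_true(all(a1$thickness_true_px > 0))
  expect_true(all(a1$b_in >= 3))
  expect_true(all(a1$a_in >= a1$b_in))
  expect_true(all(a1$orientation >= 0 & a1$orientation < pi))

  # truncated normal(0.7, 0.05) clipped to [0.4, 0.95]: truncation at
  # +-5/6 sd is negligible, so mean ~ 0.7, SE ~ sd/sqrt(n)
  spec_big <- scene_spec(c(2000, 1800), n_axons = 200, seed = 1,
                         g_mean = 0.7, g_sd = 0.05,
                         diameter_mean_nm = 400, diameter_sd_nm = 60)
  g <- sample_axon_population(spec_big)$g_true
  expect_lt(abs(mean(g) - 0.7), 3 * 0.05 / sqrt(200))
})

test_that("true g-ratio, ring width and inner radius are mutually consistent", {
  spec <- scene_spec(c(800, 700), n_axons = 30, seed = 3)
  ax <- sample_axon_population(spec)
  # definitional identity g = r_bar / (r_bar + t); exact for circles where
  # r_bar is the radius
  r_bar <- (ax$a_in + ax$b_in) / 2
  expect_equal(ax$g_true, r_bar / (r_bar + ax$thickness_true_px),
               tolerance = 1e-12)
})

test_that("placement is overlap-free, clears the border, and errors when infeasible", {
  spec <- scene_spec(c(900, 700), n_axons = 30, seed = 11)
  ax <- sample_axon_population(spec)
  r_out <- ax$a_in + ax$thickness_true_px
  expect_true(all(ax$center_row - r_out > 1 & ax$center_row + r_out < 900))
  expect_true(all(ax$center_col - r_out > 1 & ax$center_col + r_out < 700))
  d <- as.matrix(stats::dist(cbind(ax$center_row, ax$center_col)))
  lim <- outer(r_out, r_out, "+")
  off <- upper.tri(d)
  expect_true(all(d[off] > lim[off]))

  dense <- scene_spec(c(300, 300), n_axons = 60, seed = 1)
  expect_error(sample_axon_population(dense), "density infeasible")
})

test_that("rendering matches analytic geometry, grey model and determinism", {
  # single hand-placed circular axon, no noise: annulus area vs pi(R^2-r^2)
  spec <- scene_spec(c(256, 256), n_axons = 1, noise_sd = 0, seed = 1)
  ax <- tibble::tibble(
    axon_id = 1L, center_row = 128, center_col = 128,
    a_in = 70, b_in = 70, orientation = 0,
    g_true = 0.7, thickness_true_px = 30,
    depth_px = 127.5, layer_true = "L2_3")
  sc <- render_scene(ax, spec)
  analytic <- pi * (100^2 - 70^2)
  expect_lt(abs(sum(sc$truth_mask) - analytic) / analytic, 0.01)
  expect_setequal(unique(as.vector(sc$image)),
                  c(spec$myelin_gray, spec$background_gray, spec$lumen_gray))

  # zero axons: all-background image plus noise, empty truth mask
  spec0 <- scene_spec(c(64, 64), n_axons = 0, seed = 5)
  sc0 <- render_scene(sample_axon_population(spec0), spec0)
  expect_true(all(sc0$truth_mask == 0L))
  expect_lt(abs(mean(sc0$image) - spec0$background_gray), 3)

  # same spec, same seed: bit-identical noisy image
  spec2 <- scene_spec(c(300, 250), n_axons = 5, seed = 9)
  s1 <- render_scene(sample_axon_population(spec2), spec2)
  s2 <- render_scene(sample_axon_population(spec2), spec2)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
})

test_that("ground-truth table carries physical units and layer labels", {
  spec <- scene_spec(c(400, 350), n_axons = 8, seed = 2, px_size_nm = 12)
  ax <- sample_axon_population(spec)
  tr <- ground_truth_table(ax, spec)
  expect_identical(nrow(tr), 8L)
  expect_equal(tr$diameter_true_nm, 2 * ax$b_in * 12)
  expect_equal(tr$thickness_true_nm, ax$thickness_true_px * 12)
  expect_true(all(tr$layer_true %in% c("L1", "L2_3", "unassigned")))
})

test_that("cohort generation writes a complete deterministic two-group dataset", {
  dir1 <- withr::local_tempdir()
  ctrl <- scene_spec(c(320, 280), n_axons = 6, seed = 1,
                     diameter_mean_nm = 300, diameter_sd_nm = 40)
  trt <- ctrl; trt$g_mean <- 0.8
  generate_cohort(ctrl, trt, n_images_per_group = 2, seed = 123, dir = dir1)
  man <- read_cohort_manifest(dir1)
  expect_identical(nrow(man), 4L)
  expect_identical(as.vector(table(man$group)), c(2L, 2L))
  expect_true(all(file.exists(man$image), file.exists(man$truth_mask),
                  file.exists(man$truth_table)))

  # refusing to clobber unless told to
  expect_error(
    generate_cohort(ctrl, trt, 2, seed = 123, dir = dir1),
    "overwrite")

  # deterministic regeneration: identical truth tables byte for byte
  before <- readLines(man$truth_table[1])
  generate_cohort(ctrl, trt, 2, seed = 123, dir = dir1, overwrite = TRUE)
  expect_identical(readLines(man$truth_table[1]), before)

  # a +0.1 g_mean shift moves the true group means in the stated direction
  truths <- purrr::pmap_dfr(man, function(image_id, group, truth_table, ...) {
    dplyr::mutate(readr::read_csv(truth_table, show_col_types = FALSE),
                  group = group)
  })
  mg <- tapply(truths$g_true, truths$group, mean)
  expect_gt(mg[["treated"]], mg[["control"]])
})
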