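# Fixtures and independent geometric oracles used across the suite.
# Everything here is built in code at test time; no binary fixtures.

# binary mask of a circular annulus: myelin where r_in < d <= r_out,
# matching the renderer's convention (lumen = d <= r_in)
circ_annulus_mask <- function(shape, center, r_in, r_out) {
  d <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, "+"))
  m <- (d > r_in & d <= r_out) * 1L
  dim(m) <- shape
  m
}

# binary mask of a concentric elliptical annulus with ring width t_px
ell_annulus_mask <- function(shape, center, a_in, b_in, t_px, theta) {
  rr <- seq_len(shape[1]) - center[1]
  cc <- seq_len(shape[2]) - center[2]
  ct <- cos(theta); st <- sin(theta)
  u <- outer(rr * ct, cc * st, "+")
  v <- outer(-rr * st, cc * ct, "+")
  q_in <- (u / a_in)^2 + (v / b_in)^2
  q_out <- (u / (a_in + t_px))^2 + (v / (b_in + t_px))^2
  m <- (q_out <= 1 & q_in > 1) * 1L
  dim(m) <- shape
  m
}

# analytic centre-to-boundary distance of an ellipse along absolute angle
# `theta_abs` (independent closed form, not the package's internal helper)
oracle_ellipse_ray <- function(a, b, orientation, theta_abs) {
  psi <- theta_abs - orientation
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# approximate point-to-ellipse distance |Q| / |grad Q| for an axis-rotated
# ellipse, used as residual oracle for traced contours
oracle_ellipse_distance <- function(pts, center, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  dy <- pts[, 1] - center[1]; dx <- pts[, 2] - center[2]
  u <- dy * ct + dx * st
  v <- -dy * st + dx * ct
  q <- (u / a)^2 + (v / b)^2 - 1
  gu <- 2 * u / a^2; gv <- 2 * v / b^2
  # gradient back in (row, col) frame has the same norm (rotation)
  abs(q) / sqrt(gu^2 + gv^2)
}

# a small rendered scene plus its measurement, for end-to-end checks
measured_scene <- function(n_axons = 12, shape = c(480, 350), seed = 1,
                           noise_sd = 8, diameter_mean_nm = 300,
                           diameter_sd_nm = 40, g_mean = 0.7, g_sd = 0.05,
                           d1 = shape[1] / 4, ...) {
  sp <- scene_spec(shape, n_axons = n_axons, layer1_depth_px = d1,
                   g_mean = g_mean, g_sd = g_sd,
                   diameter_mean_nm = diameter_mean_nm,
                   diameter_sd_nm = diameter_sd_nm,
                   noise_sd = noise_sd, seed = seed, ...)
  scene <- render_scene(sample_axon_population(sp), sp)
  res <- measure_image(scene$image, layer1_depth_px = d1)
  list(spec = sp, scene = scene, sheaths = res$sheaths, labels = res$labels,
       mask = res$mask)
}

# match measured sheaths to ground-truth axons by nearest centre
match_truth <- function(sheaths, scene) {
  ax <- scene$truth
  ok <- sheaths$qc == "ok"
  idx <- vapply(which(ok), function(i) {
    which.min((ax$depth_px - (sheaths$center_row[i] - 0.5))^2 +
                (scene_axon_cols(scene) - sheaths$center_col[i])^2)
  }, integer(1))
  list(measured = sheaths[ok, ], truth = ax[idx, ])
}

# truth tables don't carry the column coordinate; recover it by re-sampling
# the same population (pure function of the spec)
scene_axon_cols <- function(scene) {
  sample_axon_population(scene$spec)$center_col
}

# two-group measured sheath table, full pipeline per image, in memory
measure_group_pair <- function(n_axons, shape, seed_control, seed_treated,
                               g_mean_control = 0.7, g_mean_treated = 0.7,
                               diameter_mean_nm = 300, diameter_sd_nm = 40,
                               noise_sd = 8) {
  one <- function(seed, g_mean, group) {
    sp <- scene_spec(shape, n_axons = n_axons, g_mean = g_mean,
                     diameter_mean_nm = diameter_mean_nm,
                     diameter_sd_nm = diameter_sd_nm,
                     noise_sd = noise_sd, seed = seed)
    sc <- render_scene(sample_axon_population(sp), sp)
    res <- measure_image(sc$image, layer1_depth_px = sp$layer1_depth_px)
    dplyr::mutate(res$sheaths, group = group,
                  image_id = paste0(group, "_", seed), .before = 1)
  }
  dplyr::bind_rows(one(seed_control, g_mean_control, "control"),
                   one(seed_treated, g_mean_treated, "treated"))
}

# hand-built sheath table for statistics tests (no imaging involved)
synthetic_sheath_table <- function(n_per_cell = 25, seed = 42,
                                   shift = list()) {
  set.seed(seed)
  grid <- expand.grid(group = c("control", "treated"),
                      layer = c("L1", "L2_3"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$group[i]; l <- grid$layer[i]
    delta <- shift[[paste(g, l, sep = ".")]]
    if (is.null(delta)) delta <- 0
    tibble::tibble(
      image_id = rep(paste0(g, "_", 1:2), length.out = n_per_cell),
      group = g, layer = l, qc = "ok",
      thickness_mean_nm = stats::rnorm(n_per_cell, 150 + delta, 15),
      g_ratio = pmin(pmax(stats::rnorm(n_per_cell, 0.7 + delta / 1000, 0.05),
                          0.05), 0.95),
      axon_diameter_nm = stats::rnorm(n_per_cell, 600 + delta, 60))
  })
  dplyr::bind_rows(out)
}
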