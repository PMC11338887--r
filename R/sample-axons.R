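#' Draw a ground-truth axon population for a synthetic scene
#'
#' Samples `spec$n_axons` myelinated-axon cross-sections: true g-ratio from
#' a truncated normal, inner diameter from a truncated normal (inner
#' semi-minor axis at least 3 px), aspect ratio uniform in
#' `[1, aspect_max]`, orientation uniform in `[0, pi)`. The myelin ring
#' width is derived from the true g-ratio and the mean inner semi-axis,
#' `thickness = r_bar * (1/g - 1)` with `r_bar = (a_in + b_in) / 2`, so
#' that for circular profiles `g = r_in / (r_in + thickness)` exactly.
#' Axons are placed by rejection sampling so that no two outer ellipses
#' overlap and none touches the image border; placement failure after the
#' retry budget (1000 tries per axon) raises a "density infeasible" error
#' rather than silently dropping axons.
#'
#' @param spec a [scene_spec()].
#' @return a tibble with one row per axon: `axon_id`, `center_row`,
#'   `center_col`, `a_in`, `b_in` (inner semi-axes, px), `orientation`
#'   (radians in `[0, pi)`), `g_true`, `thickness_true_px`, `depth_px`
#'   (pixels from the cortical surface) and `layer_true`.
#' @examples
#' axons <- sample_axon_population(scene_spec(c(400, 300), n_axons = 6, seed = 2))
#' axons
#' @export
sample_axon_population <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_axons
  empty <- tibble::tibble(
    axon_id = integer(), center_row = numeric(), center_col = numeric(),
    a_in = numeric(), b_in = numeric(), orientation = numeric(),
    g_true = numeric(), thickness_true_px = numeric(),
    depth_px = numeric(), layer_true = character())
  if (n == 0L) return(empty)

  with_local_seed(spec$seed, {
    g <- rtrunc_norm(n, spec$g_mean, spec$g_sd, G_TRUNC[1L], G_TRUNC[2L])
    d_lo <- max(spec$diameter_mean_nm - 3 * spec$diameter_sd_nm,
                2 * (B_IN_MIN_PX + 0.5) * spec$px_size_nm)
    d_hi <- max(spec$diameter_mean_nm + 3 * spec$diameter_sd_nm, d_lo + 1e-6)
    d_nm <- rtrunc_norm(n, spec$diameter_mean_nm, spec$diameter_sd_nm, d_lo, d_hi)
    b_in <- d_nm / (2 * spec$px_size_nm)
    aspect <- stats::runif(n, 1, spec$aspect_max)
    a_in <- aspect * b_in
    orientation <- stats::runif(n, 0, pi)
    thickness <- (a_in + b_in) / 2 * (1 / g - 1)

    rows <- spec$image_shape[1L]; cols <- spec$image_shape[2L]
    r_out <- a_in + thickness          # bounding radius of the outer ellipse
    margin <- 1.5                      # clearance between rings and to the border, px
    cr <- numeric(n); cc <- numeric(n)
    budget <- 1000L
    for (i in seq_len(n)) {
      lim <- r_out[i] + margin
      if (2 * lim >= rows || 2 * lim >= cols) {
        rlang::abort("density infeasible: an axon's outer ellipse does not fit in the image.")
      }
      placed <- FALSE
      for (try in seq_len(budget)) {
        y <- stats::runif(1, 1 + lim, rows - lim)
        x <- stats::runif(1, 1 + lim, cols - lim)
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          ok <- all((y - cr[j])^2 + (x - cc[j])^2 >
                      (r_out[i] + r_out[j] + margin)^2)
        }
        if (ok) { cr[i] <- y; cc[i] <- x; placed <- TRUE; break }
      }
      if (!placed) {
        rlang::abort(sprintf(
          "density infeasible: could not place axon %d of %d within %d tries.",
          i, n, budget))
      }
    }

    depth <- cr - 0.5                 # pixel row r has centre depth r - 0.5
    bands <- build_layer_bands(spec$layer1_depth_px)
    tibble::tibble(
      axon_id = seq_len(n),
      center_row = cr, center_col = cc,
      a_in = a_in, b_in = b_in, orientation = orientation,
      g_true = g, thickness_true_px = thickness,
      depth_px = depth,
      layer_true = as.character(assign_layer(depth, bands)))
  })
}

#' Ground-truth table for a sampled axon population
#'
#' Converts the per-axon geometric truth to the measurement units used by
#' the morphometry: thickness and diameter in nanometres, diameter defined
#' as twice the inner semi-minor axis.
#'
#' @param axons tibble from [sample_axon_population()].
#' @param spec the [scene_spec()] the axons were drawn from.
#' @return tibble: `axon_id`, `g_true`, `thickness_true_nm`,
#'   `diameter_true_nm`, `depth_px`, `layer_true`.
#' @export
ground_truth_table <- function(axons, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  tibble::tibble(
    axon_id = axons$axon_id,
    g_true = axons$g_true,
    thickness_true_nm = axons$thickness_true_px * spec$px_size_nm,
    diameter_true_nm = 2 * axons$b_in * spec$px_size_nm,
    depth_px = axons$depth_px,
    layer_true = axons$layer_true)
}
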