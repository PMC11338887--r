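#' Specify a synthetic cortical EM scene
#'
#' Describes one synthetic electron-microscopy field: image geometry, pixel
#' size, the population distributions of the myelinated axons to draw
#' (g-ratio and inner diameter), staining grey levels, sensor noise and the
#' random seed. The defaults emulate healthy cortex imaged at 12 nm/pixel:
#' g-ratios centred at 0.7 (sd 0.05, truncated to `[0.4, 0.95]`), axon
#' inner diameters around 600 nm, dark osmium-stained myelin on a lighter
#' background. Depth is measured in pixels from the cortical surface (the
#' top image edge); `layer1_depth_px` is the depth of the layer-1 /
#' layer-2-3 boundary, and the layer-2/3 band extends three times deeper
#' than layer 1, so the default image height is four times
#' `layer1_depth_px`.
#'
#' @param image_shape integer length 2, `(rows, cols)` in pixels.
#' @param px_size_nm physical pixel size in nanometres (default 12).
#' @param n_axons number of myelinated axons to place.
#' @param layer1_depth_px depth (px) of the layer-1 band; layer 2/3 spans
#'   `[layer1_depth_px, 4 * layer1_depth_px)`. Default `image_shape[1] / 4`.
#' @param g_mean,g_sd mean and sd of the true g-ratio distribution
#'   (normal, truncated to `[0.4, 0.95]`).
#' @param diameter_mean_nm,diameter_sd_nm mean and sd of the true inner
#'   (axonal) diameter in nm, defined as twice the inner semi-minor axis.
#' @param aspect_max maximum inner-ellipse aspect ratio `a/b`; aspect is
#'   drawn uniformly from `[1, aspect_max]`. Near-circular profiles
#'   emulate cross-sections cut near-perpendicular to the fibre.
#' @param myelin_gray,background_gray,lumen_gray 8-bit grey levels.
#' @param noise_sd additive Gaussian sensor noise sd (grey levels).
#' @param seed integer random seed; every output derived from the spec is
#'   a pure function of the spec including this seed.
#' @return an object of class `scene_spec` (a named list).
#' @examples
#' spec <- scene_spec(image_shape = c(400, 300), n_axons = 8, seed = 1)
#' spec
#' @export
scene_spec <- function(image_shape = c(1200, 900),
                       px_size_nm = 12,
                       n_axons = 50,
                       layer1_depth_px = NULL,
                       g_mean = 0.7,
                       g_sd = 0.05,
                       diameter_mean_nm = 600,
                       diameter_sd_nm = 100,
                       aspect_max = 1.3,
                       myelin_gray = 60,
                       background_gray = 170,
                       lumen_gray = 200,
                       noise_sd = 8,
                       seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0L)) {
    rlang::abort("`image_shape` must be two positive integers (rows, cols).")
  }
  if (is.null(layer1_depth_px)) layer1_depth_px <- image_shape[1L] / 4
  if (layer1_depth_px <= 0) rlang::abort("`layer1_depth_px` must be positive.")
  if (4 * layer1_depth_px > image_shape[1L] + 1e-9) {
    rlang::abort("`image_shape[1]` must leave room for layer 1 plus layer 2/3: need rows >= 4 * layer1_depth_px.")
  }
  if (px_size_nm <= 0) rlang::abort("`px_size_nm` must be positive.")
  if (g_mean <= 0 || g_mean >= 1 || g_sd <= 0) {
    rlang::abort("`g_mean` must be in (0,1) and `g_sd` positive.")
  }
  if (g_mean - 3 * g_sd >= G_TRUNC[2L] || g_mean + 3 * g_sd <= G_TRUNC[1L]) {
    rlang::abort(sprintf(
      "g-ratio distribution (g_mean +/- 3 g_sd) lies outside the truncation window [%.2f, %.2f].",
      G_TRUNC[1L], G_TRUNC[2L]))
  }
  if (diameter_mean_nm <= 0 || diameter_sd_nm < 0) {
    rlang::abort("diameter distribution parameters must be positive.")
  }
  if (aspect_max < 1) rlang::abort("`aspect_max` must be >= 1.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  structure(list(
    image_shape = image_shape, px_size_nm = px_size_nm,
    n_axons = as.integer(n_axons), layer1_depth_px = layer1_depth_px,
    g_mean = g_mean, g_sd = g_sd,
    diameter_mean_nm = diameter_mean_nm, diameter_sd_nm = diameter_sd_nm,
    aspect_max = aspect_max,
    myelin_gray = myelin_gray, background_gray = background_gray,
    lumen_gray = lumen_gray, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# fixed truncation window for true g-ratios: stays inside the biologically
# meaningful range (healthy ~0.7, >0.8 demyelinating) without degenerate rings
G_TRUNC <- c(0.4, 0.95)

# minimum resolvable inner semi-minor axis (px)
B_IN_MIN_PX <- 3

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<scene_spec> %d x %d px @ %g nm/px, %d axons, seed %d\n",
           "  g ~ truncnorm(%.2f, %.2f) on [%.2f, %.2f]; inner diameter ~ N(%g, %g) nm\n",
           "  layer-1 depth %g px (layer 2/3 to %g px); greys m/b/l = %g/%g/%g, noise sd %g\n"),
    x$image_shape[1L], x$image_shape[2L], x$px_size_nm, x$n_axons, x$seed,
    x$g_mean, x$g_sd, G_TRUNC[1L], G_TRUNC[2L],
    x$diameter_mean_nm, x$diameter_sd_nm,
    x$layer1_depth_px, 4 * x$layer1_depth_px,
    x$myelin_gray, x$background_gray, x$lumen_gray, x$noise_sd))
  invisible(x)
}

# evaluate code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# normal draws truncated to [lo, hi] by resampling
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 10000L) rlang::abort("truncated-normal sampling failed to terminate.")
  }
  x
}
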