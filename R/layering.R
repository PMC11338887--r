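#' Build cortical layer bands from the layer-1 depth
#'
#' Stratifies depth (pixels from the cortical surface, at the top image
#' edge) into layer 1 and layer 2/3. Measured cortical proportions put the
#' combined depth of layers 2 and 3 at three times that of layer 1, so the
#' bands are the half-open intervals `L1 = [0, d1)` and
#' `L2_3 = [d1, 4 d1)`; anything deeper is "unassigned" (layers 4-6 /
#' white matter, which the analysis does not report).
#'
#' @param d1 layer-1 depth in pixels (> 0).
#' @return an object of class `layer_bands`: list with `d1`, `l1`,
#'   `l2_3` (interval endpoints).
#' @examples
#' build_layer_bands(100)
#' @export
build_layer_bands <- function(d1) {
  if (!is.numeric(d1) || length(d1) != 1L || !is.finite(d1) || d1 <= 0) {
    rlang::abort("`d1` must be a single positive number of pixels.")
  }
  structure(list(d1 = d1, l1 = c(0, d1), l2_3 = c(d1, 4 * d1)),
            class = "layer_bands")
}

#' @export
print.layer_bands <- function(x, ...) {
  cat(sprintf("<layer_bands> L1 = [0, %g), L2/3 = [%g, %g), deeper unassigned\n",
              x$d1, x$d1, 4 * x$d1))
  invisible(x)
}

#' Assign depths to cortical layers
#'
#' Band membership by half-open interval: a depth exactly at the layer-1 /
#' layer-2-3 boundary belongs to layer 2/3. Depth is conventionally taken
#' at the sheath's fitted inner-ellipse centre.
#'
#' @param depth_px non-negative depth(s) in pixels from the cortical
#'   surface.
#' @param bands a [build_layer_bands()] result, or a numeric `d1`.
#' @return factor with levels `L1`, `L2_3`, `unassigned`.
#' @examples
#' assign_layer(c(50, 100, 450), build_layer_bands(100))
#' @export
assign_layer <- function(depth_px, bands) {
  if (is.numeric(bands)) bands <- build_layer_bands(bands)
  stopifnot(inherits(bands, "layer_bands"))
  if (any(!is.finite(depth_px)) || any(depth_px < 0)) {
    rlang::abort("`depth_px` must be non-negative and finite.")
  }
  lab <- ifelse(depth_px < bands$l1[2L], "L1",
                ifelse(depth_px < bands$l2_3[2L], "L2_3", "unassigned"))
  factor(lab, levels = c("L1", "L2_3", "unassigned"))
}

#' Append layer labels to a sheath measurement table
#'
#' @param sheaths tibble from [measure_sheaths()] (needs `center_row`).
#' @param bands [build_layer_bands()] result or numeric `d1`.
#' @return the tibble with a `layer` factor column; sheaths whose centre
#'   could not be determined get `NA`.
#' @export
add_layer <- function(sheaths, bands) {
  depth <- sheaths$center_row - 0.5
  layer <- factor(rep(NA_character_, nrow(sheaths)),
                  levels = c("L1", "L2_3", "unassigned"))
  ok <- is.finite(depth) & depth >= 0
  layer[ok] <- assign_layer(depth[ok], bands)
  dplyr::mutate(sheaths, layer = layer)
}
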