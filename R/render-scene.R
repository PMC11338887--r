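#' Render a synthetic EM image from an axon population
#'
#' Paints each axon as a dark elliptical myelin annulus around a bright
#' lumen on a mid-grey background, then adds Gaussian sensor noise and
#' clips to 8-bit range. The outer myelin boundary is the concentric
#' ellipse with semi-axes `(a_in + t, b_in + t)`, i.e. the ring width
#' equals the true thickness along both principal axes. The returned truth
#' mask is the noiseless binary myelin raster.
#'
#' @param axons tibble from [sample_axon_population()].
#' @param spec the [scene_spec()] used to draw them.
#' @return an object of class `myelin_scene`: list with `image` (numeric
#'   matrix, integer grey values 0-255), `truth_mask` (integer matrix,
#'   0/1), `truth` (the [ground_truth_table()]) and `spec`.
#' @examples
#' spec <- scene_spec(c(400, 300), n_axons = 5, seed = 3)
#' sc <- sample_axon_population(spec) |> render_scene(spec)
#' range(sc$image)
#' @export
render_scene <- function(axons, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  rows <- spec$image_shape[1L]; cols <- spec$image_shape[2L]
  img <- matrix(spec$background_gray, rows, cols)
  mask <- matrix(0L, rows, cols)

  for (i in seq_len(nrow(axons))) {
    a_in <- axons$a_in[i]; b_in <- axons$b_in[i]
    t_px <- axons$thickness_true_px[i]
    a_out <- a_in + t_px; b_out <- b_in + t_px
    cr <- axons$center_row[i]; cc <- axons$center_col[i]
    lim <- a_out + 1
    r0 <- max(1L, floor(cr - lim)); r1 <- min(rows, ceiling(cr + lim))
    c0 <- max(1L, floor(cc - lim)); c1 <- min(cols, ceiling(cc + lim))
    if (cr - lim < 0.5 || cr + lim > rows + 0.5 ||
        cc - lim < 0.5 || cc + lim > cols + 0.5) {
      rlang::abort(sprintf("axon %d extends outside the image.", axons$axon_id[i]))
    }
    rr <- r0:r1; ccv <- c0:c1
    dy <- rr - cr; dx <- ccv - cc
    ct <- cos(axons$orientation[i]); st <- sin(axons$orientation[i])
    # rotated coordinates of every pixel centre in the bounding box
    u <- outer(dy * ct, dx * st, "+")            # dy*ct + dx*st
    v <- outer(-dy * st, dx * ct, "+")           # -dy*st + dx*ct
    q_in <- (u / a_in)^2 + (v / b_in)^2
    q_out <- (u / a_out)^2 + (v / b_out)^2
    lumen <- q_in <= 1
    ring <- q_out <= 1 & !lumen
    sub_img <- img[rr, ccv]
    sub_img[lumen] <- spec$lumen_gray
    sub_img[ring] <- spec$myelin_gray
    img[rr, ccv] <- sub_img
    sub_m <- mask[rr, ccv]
    sub_m[ring] <- 1L
    mask[rr, ccv] <- sub_m
  }

  if (spec$noise_sd > 0) {
    img <- with_local_seed(spec$seed + 10007L, {
      img + matrix(stats::rnorm(rows * cols, 0, spec$noise_sd), rows, cols)
    })
  }
  img <- round(pmin(pmax(img, 0), 255))

  structure(list(image = img, truth_mask = mask,
                 truth = ground_truth_table(axons, spec), spec = spec),
            class = "myelin_scene")
}

#' @export
print.myelin_scene <- function(x, ...) {
  cat(sprintf("<myelin_scene> %d x %d px, %d axons, seed %d\n",
              nrow(x$image), ncol(x$image), nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Plot a synthetic scene
#'
#' Raster view of the rendered image, optionally with the truth-mask
#' outline overlaid.
#'
#' @param object a `myelin_scene`.
#' @param show_truth overlay the myelin truth mask in translucent red.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot myelin_scene
#' @export
autoplot.myelin_scene <- function(object, show_truth = FALSE, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$image)), times = ncol(object$image)),
    col = rep(seq_len(ncol(object$image)), each = nrow(object$image)),
    gray = as.vector(object$image),
    myelin = as.vector(object$truth_mask) == 1L)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "depth (px)", fill = "grey") +
    ggplot2::theme_minimal()
  if (show_truth) {
    p <- p + ggplot2::geom_raster(
      data = dplyr::filter(df, .data$myelin),
      fill = "red", alpha = 0.3)
  }
  p
}
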