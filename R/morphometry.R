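#' Trace the inner and outer boundaries of an accepted sheath
#'
#' Extracts ordered sub-pixel contours of one accepted sheath: the outer
#' contour of the filled component and the inner (lumen-facing) contour of
#' its hole. Contours are marching-squares iso-lines at level 0.5 of the
#' lightly smoothed (3x3 box) binary raster: on straight edges this is the
#' half-pixel midline between the last foreground and first background
#' pixel, and the smoothing removes the orientation-dependent staircase
#' bias of contouring the raw binary field. Coordinates are `(row, col)`
#' in the full-image frame, with pixel centres at integer coordinates.
#'
#' @param labels a `sheath_label_map` from [label_sheaths()].
#' @param sheath_id accepted sheath id.
#' @return list with `inner` and `outer`, each an ordered closed
#'   `n x 2` matrix of `(row, col)` points.
#' @export
trace_boundaries <- function(labels, sheath_id) {
  stopifnot(inherits(labels, "sheath_label_map"))
  row <- dplyr::filter(labels$info, .data$accepted, .data$label == sheath_id)
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("sheath id %s is not an accepted label.", toString(sheath_id)))
  }
  # work in the padded bounding box
  r0 <- row$rmin; r1 <- row$rmax; c0 <- row$cmin; c1 <- row$cmax
  sub <- labels$labels[r0:r1, c0:c1, drop = FALSE] == sheath_id
  pad <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub

  bg <- label_components(!pad, connectivity = 4L)
  outside <- bg[1L, 1L]
  hole_ids <- setdiff(unique(as.vector(bg)), c(0L, outside))
  # accepted sheaths have exactly one hole by construction
  hole <- bg == hole_ids[1L]
  filled <- pad | hole

  inner <- binary_contour(hole)
  outer <- binary_contour(filled)
  # map from padded-local to global coordinates: local (i, j) -> global
  # (i - 1 + r0 - 1, j - 1 + c0 - 1)
  shift <- c(r0 - 2L, c0 - 2L)
  list(inner = sweep(inner, 2L, -shift), outer = sweep(outer, 2L, -shift))
}

# longest level-0.5 contour of a logical matrix, closed, (row, col) points.
# the raster is box-smoothed (3x3) first: the 0.5 iso-line of the raw binary
# field sits on the half-pixel midline but carries an orientation-dependent
# staircase bias of ~0.2 px; smoothing removes the bias while leaving the
# midline crossing unchanged on straight edges.
binary_contour <- function(mask) {
  cl <- grDevices::contourLines(x = seq_len(nrow(mask)), y = seq_len(ncol(mask)),
                                z = box_blur3(mask * 1), levels = 0.5)
  if (length(cl) == 0L) rlang::abort("no contour found in binary raster.")
  lens <- vapply(cl, function(ct) length(ct$x), numeric(1))
  ct <- cl[[which.max(lens)]]
  pts <- cbind(ct$x, ct$y)
  if (any(pts[1L, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1L, ])
  pts
}

# 3x3 box filter with zero padding
box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1L)] + p[1:nr, 3:(nc + 2L)] +
     p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 2:(nc + 1L)] + p[2:(nr + 1L), 3:(nc + 2L)] +
     p[3:(nr + 2L), 1:nc] + p[3:(nr + 2L), 2:(nc + 1L)] + p[3:(nr + 2L), 3:(nc + 2L)]) / 9
}

# all positive ray-polygon crossing distances from `center` along unit
# direction `u`; polygon is a closed (row, col) point matrix
ray_crossings <- function(poly, center, u) {
  p1 <- poly[-nrow(poly), , drop = FALSE]
  p2 <- poly[-1L, , drop = FALSE]
  d1 <- p1[, 1L] - center[1L]; d2 <- p1[, 2L] - center[2L]
  e1 <- p2[, 1L] - p1[, 1L];   e2 <- p2[, 2L] - p1[, 2L]
  denom <- u[1L] * e2 - u[2L] * e1
  ok <- abs(denom) > 1e-12
  s <- (d1 * u[2L] - d2 * u[1L]) / denom        # position along the segment
  t <- (d1 * e2 - d2 * e1) / denom              # distance along the ray
  hit <- ok & s >= 0 & s < 1 & t > 1e-9
  sort(t[hit])
}

#' Sample myelin thickness along equally spaced rays
#'
#' From the fitted inner-ellipse centre, casts `n_positions` rays at
#' equally spaced angles starting at angle 0 (the image row axis). Each
#' ray records the distance to its inner-contour crossing and to the
#' nearest outer-contour crossing beyond it; the thickness sample is
#' their difference. Inner and outer diameters pair each ray with its
#' opposite (`i` with `i + n/2` for even `n`), giving `n/2` diameters
#' measured through the centre point.
#'
#' @param inner_fit `ellipse_fit` of the inner boundary (its centre is
#'   the ray origin).
#' @param inner_points,outer_points contours from [trace_boundaries()].
#' @param n_positions number of rays (default 10).
#' @return list: `thickness` (length `n_positions`), `d_in`, `d_out`
#'   (per-ray crossing distances), `inner_diameters`, `outer_diameters`
#'   (length `n_positions / 2` for even `n`), and `ok` (FALSE with
#'   `reason` when a ray misses the outer contour, i.e. a broken ring).
#' @export
measure_thickness <- function(inner_fit, inner_points, outer_points,
                              n_positions = 10L) {
  stopifnot(inherits(inner_fit, "ellipse_fit"), n_positions >= 2L)
  center <- inner_fit$center
  theta <- (seq_len(n_positions) - 1L) * 2 * pi / n_positions
  d_in <- d_out <- rep(NA_real_, n_positions)
  for (i in seq_len(n_positions)) {
    u <- c(cos(theta[i]), sin(theta[i]))
    tin <- ray_crossings(inner_points, center, u)
    if (length(tin) == 0L) {
      return(list(ok = FALSE, reason = sprintf("ray %d misses inner contour", i)))
    }
    d_in[i] <- tin[1L]
    tout <- ray_crossings(outer_points, center, u)
    tout <- tout[tout > d_in[i] + 1e-9]
    if (length(tout) == 0L) {
      return(list(ok = FALSE, reason = sprintf("ray %d misses outer contour (broken ring)", i)))
    }
    d_out[i] <- tout[1L]
  }
  if (n_positions %% 2L == 0L) {
    half <- n_positions %/% 2L
    i1 <- seq_len(half); i2 <- i1 + half
    inner_d <- d_in[i1] + d_in[i2]
    outer_d <- d_out[i1] + d_out[i2]
  } else {
    inner_d <- 2 * d_in
    outer_d <- 2 * d_out
  }
  list(ok = TRUE, thickness = d_out - d_in, d_in = d_in, d_out = d_out,
       inner_diameters = inner_d, outer_diameters = outer_d)
}

#' Compute the g-ratio from paired inner and outer diameters
#'
#' The g-ratio of a myelinated axon is the ratio of its inner (axonal)
#' diameter to its outer (fibre) diameter, here averaged over the paired
#' diameters measured through the centre point. Healthy white matter sits
#' near 0.7; values above 0.8 indicate acute demyelination.
#'
#' @param inner_diameters,outer_diameters equal-length positive vectors
#'   of diameters through the centre (px).
#' @return the g-ratio, strictly within (0, 1).
#' @examples
#' compute_g_ratio(140, 200)
#' @export
compute_g_ratio <- function(inner_diameters, outer_diameters) {
  if (length(inner_diameters) != length(outer_diameters) ||
      length(inner_diameters) == 0L) {
    rlang::abort("`inner_diameters` and `outer_diameters` must be equal-length, non-empty.")
  }
  if (any(!is.finite(inner_diameters)) || any(!is.finite(outer_diameters)) ||
      any(inner_diameters <= 0) || any(outer_diameters <= 0)) {
    rlang::abort("diameters must be finite and positive.")
  }
  if (any(outer_diameters <= inner_diameters)) {
    rlang::abort("inverted ring geometry: an outer diameter is <= its inner diameter.")
  }
  g <- mean(inner_diameters / outer_diameters)
  stopifnot(g > 0, g < 1)
  g
}

#' Axon diameter from the inner-border ellipse
#'
#' The myelinated-axon diameter is the full short-axis length of the
#' ellipse fitted to the inner myelin border: `2 * b`.
#'
#' @param inner_fit an `ellipse_fit` of the inner boundary, or a point
#'   matrix to fit first.
#' @return diameter in pixels.
#' @export
measure_axon_diameter <- function(inner_fit) {
  if (!inherits(inner_fit, "ellipse_fit")) inner_fit <- fit_ellipse(inner_fit)
  2 * inner_fit$b
}

#' Convert pixel lengths to physical units
#'
#' @param value_px length(s) in pixels.
#' @param px_size_nm physical pixel size, nm per pixel (default 12).
#' @return length(s) in nanometres.
#' @examples
#' px_to_nm(100, 12)
#' @export
px_to_nm <- function(value_px, px_size_nm = 12) {
  if (!is.numeric(px_size_nm) || length(px_size_nm) != 1L || px_size_nm <= 0) {
    rlang::abort("`px_size_nm` must be a single positive number.")
  }
  value_px * px_size_nm
}

#' Flag acute demyelination by g-ratio
#'
#' G-ratios strictly above the threshold (default 0.8) are flagged as
#' indicative of acute demyelination; a g-ratio of exactly 0.8 is not
#' flagged (strict inequality).
#'
#' @param g g-ratio(s) in (0, 1).
#' @param threshold flag threshold (default 0.8).
#' @return logical vector.
#' @examples
#' flag_demyelination(c(0.70, 0.80, 0.85))
#' @export
flag_demyelination <- function(g, threshold = 0.8) {
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1)) {
    rlang::abort("`g` must lie strictly within (0, 1).")
  }
  g > threshold
}

#' Measure every accepted sheath in a label map
#'
#' Runs the full per-sheath morphometry: boundary tracing, inner-border
#' ellipse fit, thickness at `n_positions` ray positions, g-ratio from the
#' paired centre-point diameters (or, with `g_mode = "area"`, from the
#' square root of the inner/outer fitted-ellipse area ratio), axon
#' diameter as the inner short axis, and unit conversion. Sheaths whose
#' rings are broken under ray casting, or whose boundaries cannot be fit,
#' are kept in the table with `qc` set to the reason and `NA` metrics, so
#' they are excluded from statistics but never silently dropped.
#'
#' @param labels a `sheath_label_map`.
#' @param px_size_nm nm per pixel (default 12).
#' @param n_positions thickness positions per sheath (default 10).
#' @param g_mode `"ray"` (mean of paired diameter ratios, default) or
#'   `"area"` (equivalent-diameter ratio of the fitted ellipses).
#' @param demyelination_threshold g-ratio flag threshold (default 0.8).
#' @return a tibble, one row per accepted sheath: `sheath_id`,
#'   `center_row`, `center_col`, `thickness_samples` (list column of
#'   length-`n_positions` vectors, px), `thickness_mean_px`,
#'   `thickness_mean_nm`, `g_ratio`, `axon_diameter_px`,
#'   `axon_diameter_nm`, `inner_a`, `inner_b`, `orientation`,
#'   `demyelination_flag`, `qc` (`"ok"` or the exclusion reason).
#' @export
measure_sheaths <- function(labels, px_size_nm = 12, n_positions = 10L,
                            g_mode = c("ray", "area"),
                            demyelination_threshold = 0.8) {
  stopifnot(inherits(labels, "sheath_label_map"))
  g_mode <- match.arg(g_mode)
  ids <- sort(labels$info$label[labels$info$accepted])
  rows <- lapply(ids, function(id) {
    tryCatch(
      measure_one_sheath(labels, id, px_size_nm, n_positions, g_mode,
                         demyelination_threshold),
      error = function(e) sheath_na_row(id, n_positions, conditionMessage(e)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- sheath_na_row(integer(0), n_positions, character(0))[0L, ]
  out
}

measure_one_sheath <- function(labels, id, px_size_nm, n_positions, g_mode,
                               demyelination_threshold) {
  b <- trace_boundaries(labels, id)
  fit_in <- fit_ellipse(b$inner)
  mt <- measure_thickness(fit_in, b$inner, b$outer, n_positions)
  if (!mt$ok) return(sheath_na_row(id, n_positions, mt$reason))
  g <- if (g_mode == "area") {
    fit_out <- fit_ellipse(b$outer)
    sqrt((fit_in$a * fit_in$b) / (fit_out$a * fit_out$b))
  } else {
    compute_g_ratio(mt$inner_diameters, mt$outer_diameters)
  }
  tibble::tibble(
    sheath_id = id,
    center_row = fit_in$center[1L], center_col = fit_in$center[2L],
    thickness_samples = list(mt$thickness),
    thickness_mean_px = mean(mt$thickness),
    thickness_mean_nm = px_to_nm(mean(mt$thickness), px_size_nm),
    g_ratio = g,
    axon_diameter_px = 2 * fit_in$b,
    axon_diameter_nm = px_to_nm(2 * fit_in$b, px_size_nm),
    inner_a = fit_in$a, inner_b = fit_in$b, orientation = fit_in$orientation,
    demyelination_flag = flag_demyelination(g, demyelination_threshold),
    qc = "ok")
}

sheath_na_row <- function(id, n_positions, reason) {
  tibble::tibble(
    sheath_id = id,
    center_row = NA_real_, center_col = NA_real_,
    thickness_samples = list(rep(NA_real_, n_positions)),
    thickness_mean_px = NA_real_, thickness_mean_nm = NA_real_,
    g_ratio = NA_real_,
    axon_diameter_px = NA_real_, axon_diameter_nm = NA_real_,
    inner_a = NA_real_, inner_b = NA_real_, orientation = NA_real_,
    demyelination_flag = NA,
    qc = if (length(reason)) reason else character(0))
}
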