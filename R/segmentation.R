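#' Reference myelin segmentation by global thresholding
#'
#' Classifies every pixel as myelin or non-myelin. Myelin is the dark
#' (osmium-stained) phase, so pixels strictly darker than the threshold
#' are myelin candidates; objects smaller than `min_object_px` are then
#' removed. The default threshold is Otsu's, computed on the 8-bit
#' histogram; a fixed numeric threshold can be supplied instead. This is
#' the package's classical stand-in for an externally produced mask (see
#' [load_external_mask()] to ingest one).
#'
#' A constant image has no foreground/background intensity structure and
#' always raises an error. With automatic thresholding, an image whose two
#' Otsu classes are separated by less than twice the overall intensity SD
#' (e.g. pure background noise, which Otsu would otherwise split in half)
#' is treated as having no dark phase: by default it yields an empty mask
#' with a warning; with `strict = TRUE` it raises the same
#' "no bimodal intensity structure" error as a constant image.
#'
#' @param image numeric matrix of grey values in `[0, 255]`.
#' @param threshold `"otsu"` (default) or a numeric grey level; pixels
#'   with `image < threshold` become myelin candidates.
#' @param min_object_px minimum connected-object size kept (8-connected).
#' @param strict error (rather than warn and return an empty mask) when
#'   the automatic threshold finds no real intensity separation.
#' @return an integer 0/1 matrix of class `myelin_mask` with attribute
#'   `provenance = "reference-segmenter"`.
#' @examples
#' spec <- scene_spec(c(300, 300), n_axons = 3, seed = 1, noise_sd = 0)
#' sc <- sample_axon_population(spec) |> render_scene(spec)
#' m <- segment_myelin(sc$image)
#' identical(unclass(m)[, ], sc$truth_mask)
#' @export
segment_myelin <- function(image, threshold = "otsu", min_object_px = 30L,
                           strict = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (diff(range(image)) == 0) {
    rlang::abort("no bimodal intensity structure: image is constant.")
  }
  auto <- identical(threshold, "otsu")
  thr <- if (auto) {
    255 * EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1), levels = 256L)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    rlang::abort("`threshold` must be \"otsu\" or a single grey level.")
  }
  if (auto) {
    # Otsu splits even unimodal noise; demand genuine class separation
    lo <- image[image < thr]; hi <- image[image >= thr]
    sep <- if (length(lo) && length(hi)) mean(hi) - mean(lo) else 0
    if (sep < 2 * stats::sd(image)) {
      if (strict) rlang::abort("no bimodal intensity structure: Otsu classes are not separated.")
      rlang::warn("no bimodal intensity structure found; returning an empty mask.")
      return(new_myelin_mask(matrix(0L, nrow(image), ncol(image)),
                             "reference-segmenter"))
    }
  }
  mask <- (image < thr) * 1L
  dim(mask) <- dim(image)
  if (min_object_px > 0L && any(mask == 1L)) {
    lab <- label_components(mask == 1L, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    mask <- (lab %in% keep) * 1L
    dim(mask) <- dim(image)
  }
  if (!any(mask == 1L)) {
    rlang::warn("segmentation produced an empty mask (no objects above min_object_px).")
  }
  new_myelin_mask(mask, "reference-segmenter")
}

new_myelin_mask <- function(mask, provenance) {
  structure(mask, provenance = provenance, class = c("myelin_mask", "matrix", "array"))
}

#' @export
print.myelin_mask <- function(x, ...) {
  cat(sprintf("<myelin_mask> %d x %d px, %d foreground px (%.1f%%), provenance: %s\n",
              nrow(x), ncol(x), sum(x == 1L), 100 * mean(x == 1L),
              attr(x, "provenance")))
  invisible(x)
}

#' Load an externally produced myelin mask
#'
#' Ingests a binary mask raster produced elsewhere (e.g. by a trained
#' segmentation network), validating its shape against the image it
#' describes and binarizing two-valued rasters at 50% of their maximum.
#'
#' @param path TIFF or PNG file.
#' @param image_shape integer length 2, expected `(rows, cols)`.
#' @return an integer 0/1 `myelin_mask` with `provenance = "external"`.
#' @export
load_external_mask <- function(path, image_shape) {
  raw <- read_gray_image(path)
  if (!all(dim(raw) == image_shape)) {
    rlang::abort(sprintf(
      "mask shape (%d, %d) does not match image shape (%d, %d).",
      nrow(raw), ncol(raw), image_shape[1L], image_shape[2L]))
  }
  u <- unique(as.vector(raw))
  if (length(u) > 2L) {
    rlang::abort(sprintf("mask is not binary: %d distinct values found.", length(u)))
  }
  mask <- (raw >= max(raw) / 2 & max(raw) > 0) * 1L
  dim(mask) <- dim(raw)
  new_myelin_mask(mask, "external")
}

#' Label and curate ring-shaped myelin sheaths
#'
#' Labels the 8-connected foreground components of a binary myelin mask
#' and accepts those with ring topology: exactly one enclosed hole (the
#' axon lumen; holes are 4-connected background regions not reaching the
#' component's surroundings) and no contact with the image border.
#' Rejected components are excluded from the label raster but logged with
#' a reason, so every exclusion is traceable.
#'
#' @param mask a `myelin_mask` or plain 0/1 matrix.
#' @return an object of class `sheath_label_map`: list with `labels`
#'   (integer matrix; 0 background, `k >= 1` the k-th accepted sheath) and
#'   `info`, a tibble with one row per original component: `label`
#'   (accepted id or `NA`), `accepted`, `reason`, `n_px`, `n_holes`,
#'   `touches_border`, bounding box (`rmin`, `rmax`, `cmin`, `cmax`).
#' @examples
#' m <- matrix(0L, 40, 40)
#' d <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, "+"))
#' m[d >= 8 & d <= 14] <- 1L
#' label_sheaths(m)$info
#' @export
label_sheaths <- function(mask) {
  mask <- (unclass(mask) == 1L)
  lab_all <- label_components(mask, connectivity = 8L)
  n_comp <- max(lab_all, 0L)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (n_comp == 0L) {
    return(new_sheath_label_map(labels, empty_sheath_info()))
  }

  idx <- which(lab_all > 0L)
  rc <- arrayInd(idx, dim(mask))
  comp <- lab_all[idx]
  n_px <- tabulate(comp, n_comp)
  ord <- order(comp)
  ends <- cumsum(n_px)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rmin <- rmax <- cmin <- cmax <- integer(n_comp)
  r_ord <- rc[ord, 1L]; c_ord <- rc[ord, 2L]
  for (k in seq_len(n_comp)) {
    sl <- starts[k]:ends[k]
    rmin[k] <- min(r_ord[sl]); rmax[k] <- max(r_ord[sl])
    cmin[k] <- min(c_ord[sl]); cmax[k] <- max(c_ord[sl])
  }
  touches <- (rmin == 1L) | (cmin == 1L) |
    (rmax == nrow(mask)) | (cmax == ncol(mask))

  n_holes <- integer(n_comp)
  for (k in seq_len(n_comp)) {
    n_holes[k] <- count_holes(lab_all, k, rmin[k], rmax[k], cmin[k], cmax[k])
  }

  accepted <- !touches & n_holes == 1L
  reason <- dplyr::case_when(
    accepted ~ NA_character_,
    touches ~ "touches border",
    n_holes == 0L ~ "no hole",
    TRUE ~ "multiple holes")
  new_id <- integer(n_comp)
  new_id[accepted] <- seq_len(sum(accepted))
  labels[idx] <- new_id[comp]

  info <- tibble::tibble(
    label = ifelse(accepted, new_id, NA_integer_),
    accepted = accepted, reason = reason,
    n_px = as.integer(n_px), n_holes = n_holes,
    touches_border = as.logical(touches),
    rmin = as.integer(rmin), rmax = as.integer(rmax),
    cmin = as.integer(cmin), cmax = as.integer(cmax))
  new_sheath_label_map(labels, info)
}

empty_sheath_info <- function() {
  tibble::tibble(label = integer(), accepted = logical(), reason = character(),
                 n_px = integer(), n_holes = integer(), touches_border = logical(),
                 rmin = integer(), rmax = integer(), cmin = integer(), cmax = integer())
}

new_sheath_label_map <- function(labels, info) {
  structure(list(labels = labels, info = info), class = "sheath_label_map")
}

#' @export
print.sheath_label_map <- function(x, ...) {
  n_acc <- sum(x$info$accepted)
  cat(sprintf("<sheath_label_map> %d x %d px: %d accepted sheath(s), %d rejected\n",
              nrow(x$labels), ncol(x$labels), n_acc, nrow(x$info) - n_acc))
  rej <- dplyr::filter(x$info, !.data$accepted)
  if (nrow(rej) > 0L) {
    tab <- table(rej$reason)
    cat("  rejections:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rejection log of a sheath label map
#'
#' @param labels a `sheath_label_map`.
#' @return tibble of rejected components: `reason`, `n_px`, bounding box.
#' @export
rejection_log <- function(labels) {
  stopifnot(inherits(labels, "sheath_label_map"))
  dplyr::select(dplyr::filter(labels$info, !.data$accepted),
                "reason", "n_px", "rmin", "rmax", "cmin", "cmax")
}

# connected-component labeling of a logical matrix.
# connectivity 8 for foreground, 4 for holes (complementary pairing).
label_components <- function(fg, connectivity = 8L) {
  stopifnot(is.logical(fg), is.matrix(fg), connectivity %in% c(4L, 8L))
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  m <- length(idx)
  out <- matrix(0L, nr, nc)
  if (m == 0L) return(out)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_len(m)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1L]; dc <- offsets[[k]][2L]
    r_src <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    c_src <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    both <- fg[r_src, c_src, drop = FALSE] & fg[r_src + dr, c_src + dc, drop = FALSE]
    if (!any(both)) next
    a <- id[r_src, c_src, drop = FALSE][both]
    b <- id[r_src + dr, c_src + dc, drop = FALSE][both]
    edges[[k]] <- cbind(a, b)
  }
  e <- do.call(rbind, edges)
  memb <- if (is.null(e) || nrow(e) == 0L) {
    seq_len(m)
  } else {
    g <- igraph::make_graph(as.vector(t(e)), n = m, directed = FALSE)
    igraph::components(g)$membership
  }
  # renumber components in first-pixel (column-major scan) order so ids are
  # stable under any input relabeling
  f <- memb[!duplicated(memb)]
  remap <- integer(max(memb))
  remap[f] <- seq_along(f)
  out[idx] <- remap[memb]
  out
}

# number of holes of component k: 4-connected background regions inside the
# padded bounding box that do not reach the pad frame
count_holes <- function(lab_all, k, rmin, rmax, cmin, cmax) {
  sub <- lab_all[rmin:rmax, cmin:cmax, drop = FALSE] == k
  pad <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  bg <- label_components(!pad, connectivity = 4L)
  outside <- bg[1L, 1L]  # pad frame is all background and 4-connected
  length(setdiff(unique(as.vector(bg)), c(0L, outside)))
}
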