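#' Generate a two-group synthetic cohort on disk
#'
#' Renders `n_images_per_group` scenes per group from a control and a
#' treated scene specification (which should differ only in the effect
#' parameters under study), writing for each image the 8-bit grey TIFF,
#' the binary truth-mask TIFF (0/255), and the ground-truth CSV, plus a
#' machine-readable JSON manifest naming every file and its group.
#' Per-image seeds are derived deterministically from the master seed, so
#' the whole cohort is a pure function of its arguments.
#'
#' @param control_spec,treated_spec [scene_spec()]s for the two groups.
#' @param n_images_per_group images per group.
#' @param seed master seed for the cohort.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) the manifest as a list; the manifest is also
#'   written to `file.path(dir, "manifest.json")`.
#' @export
generate_cohort <- function(control_spec, treated_spec,
                            n_images_per_group, seed, dir,
                            overwrite = FALSE) {
  stopifnot(inherits(control_spec, "scene_spec"),
            inherits(treated_spec, "scene_spec"),
            n_images_per_group >= 1L)
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE, no.. = TRUE)) > 0L) {
    if (!overwrite) {
      rlang::abort(sprintf("output directory '%s' exists and is not empty; set overwrite = TRUE to replace.", dir))
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  specs <- list(control = control_spec, treated = treated_spec)
  entries <- list()
  k <- 0L
  for (gi in seq_along(specs)) {
    grp <- names(specs)[gi]
    for (i in seq_len(n_images_per_group)) {
      k <- k + 1L
      img_seed <- derive_seed(seed, gi, i)
      sp <- specs[[grp]]
      sp$seed <- img_seed
      scene <- render_scene(sample_axon_population(sp), sp)
      image_id <- sprintf("%s_%02d", grp, i)
      f_img <- sprintf("%s_image.tif", image_id)
      f_msk <- sprintf("%s_truth_mask.tif", image_id)
      f_tbl <- sprintf("%s_truth.csv", image_id)
      write_gray_tiff(scene$image, file.path(dir, f_img))
      write_gray_tiff(scene$truth_mask * 255, file.path(dir, f_msk))
      readr::write_csv(scene$truth, file.path(dir, f_tbl))
      entries[[k]] <- list(
        image_id = image_id, group = grp, seed = img_seed,
        image = f_img, truth_mask = f_msk, truth_table = f_tbl,
        px_size_nm = sp$px_size_nm, layer1_depth_px = sp$layer1_depth_px)
    }
  }
  manifest <- list(
    generator = "myelometry synthetic cohort",
    master_seed = as.integer(seed),
    n_images_per_group = as.integer(n_images_per_group),
    groups = names(specs),
    images = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# deterministic 31-bit per-image seed from the master seed
derive_seed <- function(seed, group_index, image_index) {
  as.integer((as.numeric(seed) + 7919 * group_index + 104729 * image_index) %% 2147483647)
}

#' Read a cohort manifest
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a tibble with one row per image: `image_id`, `group`, `seed`,
#'   absolute `image`, `truth_mask`, `truth_table` paths, `px_size_nm`,
#'   `layer1_depth_px`.
#' @export
read_cohort_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) rlang::abort(sprintf("no manifest.json in '%s'.", dir))
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(m$images, function(e) {
    tibble::tibble(
      image_id = e$image_id, group = e$group, seed = e$seed,
      image = file.path(dir, e$image),
      truth_mask = file.path(dir, e$truth_mask),
      truth_table = file.path(dir, e$truth_table),
      px_size_nm = e$px_size_nm, layer1_depth_px = e$layer1_depth_px)
  })
}

# single-channel 8-bit TIFF writers/readers (values stored 0-255)
write_gray_tiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 255) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a grey-scale image
#'
#' Reads a single-channel TIFF or PNG into a numeric matrix of 8-bit grey
#' values (0-255). Multi-channel rasters are averaged to grey.
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @return numeric matrix, grey values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("image file '%s' not found.", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      rlang::abort("reading PNG requires the 'png' package.")
    }
    png::readPNG(path)
  } else {
    rlang::abort(sprintf("unsupported image extension '%s' (use TIFF or PNG).", ext))
  }
  if (length(dim(raw)) == 3L) raw <- apply(raw, c(1L, 2L), mean)
  raw * 255
}
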