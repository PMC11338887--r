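#' Configure an end-to-end morphometry run
#'
#' Bundles every tunable of the simulate - segment - measure - stratify -
#' compare pipeline into one serializable list. The defaults are the
#' workflow's standard constants: 12 nm/pixel, 10 thickness positions per
#' sheath, a layer-2/3 band three times as deep as layer 1, alpha = 0.05,
#' and a g-ratio demyelination flag above 0.8.
#'
#' @param control,treated named lists of [scene_spec()] argument
#'   overrides for the two groups (`treated` on top of `control`).
#' @param n_images_per_group images simulated per group.
#' @param seed master seed; all per-image seeds derive from it.
#' @param px_size_nm nm per pixel.
#' @param n_positions thickness ray positions per sheath.
#' @param g_mode `"ray"` or `"area"` g-ratio convention.
#' @param demyelination_threshold g-ratio QC flag threshold.
#' @param segmentation list: `threshold` (`"otsu"` or grey level),
#'   `min_object_px`.
#' @param stats list: `unit` (`"sheath"`/`"image"`), `mode`
#'   (`"student"`/`"welch"`), `alpha`.
#' @param out_dir run output directory.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(control = list(),
                       treated = list(),
                       n_images_per_group = 2L,
                       seed = 1L,
                       px_size_nm = 12,
                       n_positions = 10L,
                       g_mode = "ray",
                       demyelination_threshold = 0.8,
                       segmentation = list(threshold = "otsu", min_object_px = 30L),
                       stats = list(unit = "sheath", mode = "student", alpha = 0.05),
                       out_dir = tempfile("myelometry_run_")) {
  control$px_size_nm <- control$px_size_nm %||% px_size_nm
  treated_full <- utils::modifyList(control, treated)
  structure(list(
    control = control, treated = treated_full,
    n_images_per_group = as.integer(n_images_per_group),
    seed = as.integer(seed), px_size_nm = px_size_nm,
    n_positions = as.integer(n_positions), g_mode = g_mode,
    demyelination_threshold = demyelination_threshold,
    segmentation = segmentation, stats = stats,
    out_dir = out_dir), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure one image end to end
#'
#' Segment (or ingest) the myelin mask, curate ring-shaped sheaths,
#' measure them, and stratify by cortical layer.
#'
#' @param image grey matrix, or a path readable by [read_gray_image()].
#' @param mask optional pre-made mask (a `myelin_mask`, a 0/1 matrix, or
#'   a mask file path); when `NULL` the reference segmenter is used.
#' @param layer1_depth_px layer-1 band depth (px) for stratification.
#' @param threshold,min_object_px reference-segmenter parameters.
#' @inheritParams measure_sheaths
#' @return list with `sheaths` (measurement tibble incl. `layer`),
#'   `labels` (the `sheath_label_map`) and `mask`.
#' @export
measure_image <- function(image, mask = NULL, layer1_depth_px = nrow(image) / 4,
                          px_size_nm = 12, n_positions = 10L,
                          g_mode = c("ray", "area"),
                          demyelination_threshold = 0.8,
                          threshold = "otsu", min_object_px = 30L) {
  if (is.character(image)) image <- read_gray_image(image)
  if (is.null(mask)) {
    mask <- segment_myelin(image, threshold = threshold,
                           min_object_px = min_object_px)
  } else if (is.character(mask)) {
    mask <- load_external_mask(mask, dim(image))
  }
  labels <- label_sheaths(mask)
  sheaths <- measure_sheaths(labels, px_size_nm = px_size_nm,
                             n_positions = n_positions, g_mode = g_mode,
                             demyelination_threshold = demyelination_threshold) |>
    add_layer(build_layer_bands(layer1_depth_px))
  list(sheaths = sheaths, labels = labels, mask = mask)
}

#' Run the whole pipeline from a configuration
#'
#' Simulates the two-group cohort, measures every image with the
#' reference segmenter, stratifies sheaths by layer, writes the
#' per-sheath CSV, the six-comparison report (JSON), a structured log, a
#' copy of the configuration (YAML) next to the outputs, and returns the
#' results. Outputs are a pure function of the configuration: re-running
#' from the emitted config copy reproduces the CSV and report
#' byte-for-byte.
#'
#' @param config a [run_config()].
#' @return an object of class `myelin_run`: list with `sheaths` (tibble,
#'   all images), `comparisons` (`myelin_comparisons`), `manifest`,
#'   `config` and `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(stage, event) {
    cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, event), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line(name, "start")
    out <- tryCatch(expr, error = function(e) {
      log_line(name, paste("error:", conditionMessage(e)))
      rlang::abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
    log_line(name, "done")
    out
  }

  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

  manifest <- stage("simulate", {
    ctrl <- do.call(scene_spec, config$control)
    trt <- do.call(scene_spec, config$treated)
    generate_cohort(ctrl, trt, config$n_images_per_group, config$seed,
                    file.path(config$out_dir, "cohort"), overwrite = TRUE)
  })
  images <- read_cohort_manifest(file.path(config$out_dir, "cohort"))

  labels_dir <- file.path(config$out_dir, "labels")
  dir.create(labels_dir, showWarnings = FALSE)
  sheaths <- stage("measure", {
    purrr::pmap_dfr(images, function(image_id, group, seed, image, truth_mask,
                                     truth_table, px_size_nm, layer1_depth_px) {
      res <- measure_image(
        image, layer1_depth_px = layer1_depth_px, px_size_nm = px_size_nm,
        n_positions = config$n_positions, g_mode = config$g_mode,
        demyelination_threshold = config$demyelination_threshold,
        threshold = config$segmentation$threshold,
        min_object_px = config$segmentation$min_object_px)
      tiff::writeTIFF(res$labels$labels / 65535,
                      file.path(labels_dir, paste0(image_id, "_labels.tif")),
                      bits.per.sample = 16L, compression = "none")
      rej <- rejection_log(res$labels)
      readr::write_csv(dplyr::mutate(rej, image_id = image_id, .before = 1L),
                       file.path(labels_dir, paste0(image_id, "_rejections.csv")))
      for (i in seq_len(nrow(rej))) {
        log_line("measure", sprintf("%s: component rejected (%s, %d px)",
                                    image_id, rej$reason[i], rej$n_px[i]))
      }
      for (i in which(res$sheaths$qc != "ok")) {
        log_line("measure", sprintf("%s: sheath %d QC-excluded (%s)",
                                    image_id, res$sheaths$sheath_id[i],
                                    res$sheaths$qc[i]))
      }
      dplyr::mutate(res$sheaths, image_id = image_id, group = group,
                    .before = 1L)
    })
  })
  write_sheath_csv(sheaths, file.path(config$out_dir, "sheaths.csv"))

  comparisons <- stage("compare", {
    compare_all_groups(sheaths, unit = config$stats$unit,
                       mode = config$stats$mode, alpha = config$stats$alpha)
  })
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    list(comparisons = tibble::as_tibble(comparisons),
         alpha = config$stats$alpha,
         note = "raw two-sided p-values; no multiple-testing correction"),
    report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(sheaths = sheaths, comparisons = comparisons,
                 manifest = manifest, config = config,
                 paths = list(out_dir = config$out_dir,
                              sheaths = file.path(config$out_dir, "sheaths.csv"),
                              report = report_path, log = log_path)),
            class = "myelin_run")
}

#' Write the per-sheath measurement CSV
#'
#' Flattens the thickness-sample list column to `t1..tN` columns.
#'
#' @param sheaths measurement tibble (with or without `image_id`/`group`).
#' @param path output CSV path.
#' @export
write_sheath_csv <- function(sheaths, path) {
  n_pos <- if (nrow(sheaths) > 0L) length(sheaths$thickness_samples[[1L]]) else 0L
  flat <- sheaths
  if (n_pos > 0L) {
    tmat <- do.call(rbind, flat$thickness_samples)
    colnames(tmat) <- paste0("t", seq_len(n_pos))
    flat <- dplyr::bind_cols(
      dplyr::select(flat, -"thickness_samples"),
      tibble::as_tibble(tmat))
  }
  readr::write_csv(flat, path)
  invisible(path)
}

#' @export
print.myelin_run <- function(x, ...) {
  cat(sprintf("<myelin_run> %d image(s), %d sheath(s) (%d QC-ok) -> %s\n",
              length(x$manifest$images), nrow(x$sheaths),
              sum(x$sheaths$qc == "ok"), x$paths$out_dir))
  print(x$comparisons)
  invisible(x)
}

#' @rdname run_all
#' @param x,object a `myelin_run`.
#' @param ... ignored.
#' @method tidy myelin_run
#' @export
tidy.myelin_run <- function(x, ...) tibble::as_tibble(x$comparisons)

#' @rdname run_all
#' @method glance myelin_run
#' @export
glance.myelin_run <- function(x, ...) {
  tibble::tibble(
    n_images = length(x$manifest$images),
    n_sheaths = nrow(x$sheaths),
    n_qc_ok = sum(x$sheaths$qc == "ok"),
    n_demyelination_flagged = sum(x$sheaths$demyelination_flag, na.rm = TRUE),
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    alpha = attr(x$comparisons, "alpha"))
}

#' @rdname run_all
#' @method autoplot myelin_run
#' @export
autoplot.myelin_run <- function(object, ...) {
  long <- object$sheaths |>
    dplyr::filter(.data$qc == "ok", .data$layer %in% c("L1", "L2_3")) |>
    tidyr::pivot_longer(cols = c("thickness_mean_nm", "g_ratio", "axon_diameter_nm"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", colour = "black") +
    ggplot2::facet_grid(metric ~ layer, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
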