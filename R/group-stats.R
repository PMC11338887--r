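#' Shapiro-Wilk normality screen
#'
#' Thin, guarded interface to the Shapiro-Wilk test used to screen each
#' group's values before the two-group comparison.
#'
#' @param values numeric vector, `3 <= n <= 5000`, not all identical.
#' @return list with `W` and `p`.
#' @examples
#' shapiro_wilk(rnorm(30))
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    rlang::abort("Shapiro-Wilk requires 3 <= n <= 5000 finite values.")
  }
  if (stats::sd(values) == 0) {
    rlang::abort("zero variance: all values identical.")
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance unpaired t-test by default; Welch's
#' unequal-variance form by `mode = "welch"`. Two groups that are both
#' constant and equal are reported as `t = 0, p = 1` (no evidence of
#' difference), not as an error; constant but unequal groups give
#' `|t| = Inf, p = 0`.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @param mode `"student"` (default) or `"welch"`.
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' unpaired_t_test(c(0, 1), c(2, 3))
#' @export
unpaired_t_test <- function(a, b, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    rlang::abort("each group needs at least 2 finite values.")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = (mode == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Compare one metric between two groups within one layer
#'
#' Implements the fixed statistical workflow: filter the per-sheath table
#' to one layer, drop QC-excluded sheaths and missing values, optionally
#' aggregate to per-image means, screen each group with the Shapiro-Wilk
#' test (a warning is raised if either group departs from normality at
#' p < 0.05, but the t-test is still reported), then run the unpaired
#' t-test and report group means +/- SD.
#'
#' @param sheaths tibble with columns `group` (two levels), `layer`,
#'   `qc`, `image_id`, and the metric column.
#' @param metric metric column name (e.g. `"g_ratio"`,
#'   `"thickness_mean_nm"`, `"axon_diameter_nm"`).
#' @param layer layer to filter to (`"L1"` or `"L2_3"`).
#' @param unit unit of analysis: `"sheath"` (pool sheaths, default) or
#'   `"image"` (per-image means).
#' @param mode t-test mode, `"student"` or `"welch"`.
#' @param alpha significance level (default 0.05).
#' @return a one-row tibble: metric, layer, unit, per-group n (and
#'   n_images), mean, sd, Shapiro-Wilk W and p, then `t`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(sheaths, metric, layer,
                           unit = c("sheath", "image"),
                           mode = c("student", "welch"),
                           alpha = 0.05) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  stopifnot(metric %in% names(sheaths))
  if (!"image_id" %in% names(sheaths)) sheaths$image_id <- "image_1"

  dat <- sheaths |>
    dplyr::filter(.data$layer == !!layer, .data$qc == "ok",
                  is.finite(.data[[metric]]))
  grps <- sort(unique(as.character(dat$group)))
  if (length(grps) != 2L || any(table(dat$group) < 2L)) {
    rlang::abort(sprintf(
      "empty or degenerate group for metric '%s' after filtering to layer %s and dropping QC-excluded sheaths.",
      metric, layer))
  }
  n_img <- dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_images = dplyr::n_distinct(.data$image_id))
  if (unit == "image") {
    dat <- dat |>
      dplyr::group_by(.data$group, .data$image_id) |>
      dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  } else {
    dat <- dplyr::transmute(dat, group = .data$group, value = .data[[metric]])
  }
  va <- dat$value[dat$group == grps[1L]]
  vb <- dat$value[dat$group == grps[2L]]
  if (length(va) < 2L || length(vb) < 2L) {
    rlang::abort(sprintf(
      "fewer than 2 observations per group for metric '%s' in layer %s at unit '%s'.",
      metric, layer, unit))
  }

  sw <- lapply(list(va, vb), function(v) {
    tryCatch(shapiro_wilk(v), error = function(e) list(W = NA_real_, p = NA_real_))
  })
  low <- which(vapply(sw, function(s) isTRUE(s$p < alpha), logical(1)))
  if (length(low) > 0L) {
    rlang::warn(sprintf(
      "Shapiro-Wilk p < %.2g for group(s) %s on %s (%s); t-test reported regardless.",
      alpha, paste(grps[low], collapse = ", "), metric, layer))
  }
  tt <- unpaired_t_test(va, vb, mode = mode)

  tibble::tibble(
    metric = metric, layer = layer, unit = unit, mode = mode,
    group1 = grps[1L], group2 = grps[2L],
    n1 = length(va), n2 = length(vb),
    n_images1 = n_img$n_images[n_img$group == grps[1L]],
    n_images2 = n_img$n_images[n_img$group == grps[2L]],
    mean1 = mean(va), sd1 = stats::sd(va),
    mean2 = mean(vb), sd2 = stats::sd(vb),
    shapiro_W1 = sw[[1L]]$W, shapiro_p1 = sw[[1L]]$p,
    shapiro_W2 = sw[[2L]]$W, shapiro_p2 = sw[[2L]]$p,
    t = tt$t, df = tt$df, p_value = tt$p,
    significant = tt$p < alpha)
}

#' Full per-layer, per-metric comparison report
#'
#' Runs [compare_groups()] for every combination of the three headline
#' metrics (myelin thickness, g-ratio, axon diameter) and the two
#' reported layers, mirroring the six raw comparisons of the standard
#' workflow. No multiple-testing correction is applied; the six p-values
#' are reported raw.
#'
#' @inheritParams compare_groups
#' @param metrics,layers character vectors of metric column names and
#'   layer labels.
#' @return tibble of class `myelin_comparisons` with one row per
#'   metric-layer pair.
#' @export
compare_all_groups <- function(sheaths,
                               metrics = c("thickness_mean_nm", "g_ratio",
                                           "axon_diameter_nm"),
                               layers = c("L1", "L2_3"),
                               unit = c("sheath", "image"),
                               mode = c("student", "welch"),
                               alpha = 0.05) {
  unit <- match.arg(unit); mode <- match.arg(mode)
  grid <- tidyr::expand_grid(metric = metrics, layer = layers)
  out <- purrr::pmap_dfr(grid, function(metric, layer) {
    compare_groups(sheaths, metric, layer, unit = unit, mode = mode,
                   alpha = alpha)
  })
  structure(out, class = c("myelin_comparisons", class(out)), alpha = alpha)
}

#' @export
print.myelin_comparisons <- function(x, ...) {
  cat(sprintf("Two-group morphometry comparisons (alpha = %.2g, raw p-values, no multiplicity correction)\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-18s %-5s %s %.4g +/- %.4g (n=%d) vs %s %.4g +/- %.4g (n=%d)  t=%.3f df=%.4g p=%.4g%s\n",
      df$metric[i], df$layer[i],
      df$group1[i], df$mean1[i], df$sd1[i], df$n1[i],
      df$group2[i], df$mean2[i], df$sd2[i], df$n2[i],
      df$t[i], df$df[i], df$p_value[i],
      ifelse(df$significant[i], " *", "")))
  }
  invisible(x)
}

#' Plot a comparison report
#'
#' Mean +/- SD per group, faceted by metric and layer.
#'
#' @param object a `myelin_comparisons` tibble.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot myelin_comparisons
#' @export
autoplot.myelin_comparisons <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("mean1", "mean2"), names_to = "which", values_to = "mean") |>
    dplyr::mutate(
      group = ifelse(.data$which == "mean1", .data$group1, .data$group2),
      sd = ifelse(.data$which == "mean1", .data$sd1, .data$sd2))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2) +
    ggplot2::facet_wrap(~ .data$metric + .data$layer, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- SD") +
    ggplot2::theme_minimal()
}
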