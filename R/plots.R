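# ggplot2 visual summaries for the main result types.

#' Plot spectra as overlaid reflectance curves
#'
#' @param spectra Wide spectra tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.3) {
  spectra_long(spectra) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavelength, .data$value,
                                 group = .data$sample)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.2) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}

#' Stacked per-wavelength variance partition
#'
#' Cumulative percent sum of squares per term across the spectrum, stacked
#' in the declared adjustment order.
#'
#' @param variance Tibble from [fit_adjust()] (`wavelength`, `term`,
#'   `percent`).
#' @return A ggplot object.
#' @export
plot_variance_partition <- function(variance) {
  lev <- c(setdiff(unique(variance$term), "residual"), "residual")
  variance |>
    dplyr::mutate(term = factor(.data$term, levels = lev)) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavelength, .data$percent,
                                 fill = .data$term)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Percent of total SS",
                  fill = "Term") +
    ggplot2::theme_minimal()
}

#' Terminal segments of a segment tree along the wavelength axis
#'
#' @param object A `segment_tree`.
#' @param ... Unused.
#' @return A ggplot object: one colored tile run per terminal segment.
#' @method autoplot segment_tree
#' @export
autoplot.segment_tree <- function(object, ...) {
  terms <- dplyr::filter(object$nodes, .data$terminal)
  df <- purrr::map_dfr(seq_len(nrow(terms)), function(i) {
    tibble(wavelength = terms$bands[[i]],
           segment = paste0("seg", terms$id[i]),
           level = terms$level[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$level,
                                   fill = .data$segment)) +
    ggplot2::geom_tile(height = 0.9) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Tree level",
                  fill = "Terminal segment") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of association results
#'
#' @param results Association tibble (snp, chrom, pos, p, ...), optionally
#'   filtered to one phenotype first.
#' @param threshold Optional p-value threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  df <- results |>
    dplyr::filter(is.finite(.data$p)) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(rel = .data$pos / max(.data$pos)) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = match(.data$chrom, unique(.data$chrom)) - 1 + .data$rel)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, -log10(.data$p),
                                         color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "Chromosome", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed")
  }
  gg
}

#' Quantile-quantile plot of association p values
#'
#' @param results Association tibble with a `p` column (grouped by `model`
#'   color if present).
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  df <- results |>
    dplyr::filter(is.finite(.data$p)) |>
    dplyr::group_by(dplyr::across(dplyr::any_of("model"))) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(expected = -log10(stats::ppoints(dplyr::n())),
                  observed = -log10(.data$p)) |>
    dplyr::ungroup()
  aes <- if ("model" %in% names(df)) {
    ggplot2::aes(.data$expected, .data$observed, color = .data$model)
  } else {
    ggplot2::aes(.data$expected, .data$observed)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Expected - log[10](italic(p))),
                  y = expression(Observed - log[10](italic(p)))) +
    ggplot2::theme_minimal()
}
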